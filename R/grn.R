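#' Infer a TF -> target regulatory network with random-forest importances
#'
#' Tree-ensemble regulatory-network inference in the GENIE3 style: the
#' expression of each gene (the output variable) is regressed on the
#' expression of all transcription factors except itself (the predictors)
#' with a random forest, and the importance of a TF for a target is the
#' variance-reduction (impurity) importance of that predictor, averaged
#' over trees. By default the bias-corrected form of the impurity
#' importance (Nembrini et al. 2018, as implemented by
#' [ranger::ranger()]'s `"impurity_corrected"`) is used: raw impurity
#' importance systematically credits uninformative predictors through
#' in-sample overfitting in fully grown trees, which inflates every TF's
#' network size by a noise floor of roughly (1 - true share)/(#TFs); the
#' corrected measure is centred at zero for uninformative predictors, so
#' a fixed importance threshold separates regulators from noise. Negative
#' corrected importances are clamped to zero, importances are normalized
#' per target so each modelled target's importances sum to 1, and edges
#' above `importance_threshold` constitute the directed network. The
#' number of candidate predictors per split is `floor(sqrt(#TFs))`.
#'
#' Genes with zero variance across samples cannot be modelled (nor carry
#' information as predictors) and are dropped with a message. A TF is
#' never allowed to predict itself, so the network has no self-edges.
#'
#' @param expr numeric expression matrix, genes x samples (assumed
#'   normalized; see `log2_transform`).
#' @param tf_list character vector of TF gene ids; must be rows of `expr`.
#' @param n_trees trees per forest (default 1000).
#' @param importance_threshold minimum normalized importance for an edge
#'   to count towards a TF's network (default 0.1: an edge must carry at
#'   least a tenth of its target's attributable variance, well above both
#'   the uniform share 1/#TFs and the noise tail for TF panels of a few
#'   dozen factors). All positive-
#'   importance edges are retained internally so the threshold can be
#'   swept without refitting; [network_size()] and exports apply it.
#' @param seed integer seed; forests for successive targets use
#'   successive sub-seeds, so results are reproducible.
#' @param condition_label free-text label stored with the network.
#' @param log2_transform apply `log2(x + 1)` to `expr` first.
#' @param mtry candidate predictors per split; default
#'   `floor(sqrt(#TFs))`. With impurity importance and `mtry` below the
#'   number of predictors, fully grown trees attribute part of each
#'   target's variance to uninformative predictors, so even a perfect
#'   single regulator's normalized share plateaus well below 1 (around
#'   0.4-0.6); it approaches 1 only with `mtry` equal to the number of
#'   predictors. Rankings are much less affected than absolute shares.
#' @return An object of class `regulatory_network`: `edges` (data.frame
#'   `tf`, `target`, `importance`, all positive-importance edges),
#'   `tf_list`, `importance_threshold`, `condition_label`, `n_trees`,
#'   `seed`, `dropped` (zero-variance gene ids).
#' @examples
#' d <- synthetic_design(n_genes = 30, n_tfs = 5, n_samples_per_condition = 20,
#'                       tf_out_degree_range = c(1, 3), seed = 5)
#' rt <- generate_regulatory_truth(d, gainer_targets = c(1, 5))
#' net <- infer_grn(rt$expr_a, rt$tf_ids, n_trees = 50, seed = 1)
#' head(net$edges[order(-net$edges$importance), ])
#' @export
infer_grn <- function(expr, tf_list, n_trees = 1000,
                      importance_threshold = 0.1, seed = 1,
                      condition_label = "", log2_transform = FALSE,
                      mtry = NULL,
                      importance_measure = c("impurity_corrected",
                                             "impurity", "permutation")) {
  importance_measure <- match.arg(importance_measure)
  if (!is.matrix(expr) || is.null(rownames(expr)))
    data_error("infer_grn: 'expr' must be a matrix with gene-id rownames")
  if (ncol(expr) < 3)
    data_error("infer_grn: at least 3 samples are required; pool conditions or add replicates")
  tf_list <- unique(as.character(tf_list))
  if (!length(tf_list)) data_error("infer_grn: empty TF list")
  missing <- setdiff(tf_list, rownames(expr))
  if (length(missing))
    data_error("infer_grn: TF(s) absent from the expression matrix: %s",
               paste(utils::head(missing, 10), collapse = ", "))
  if (log2_transform) expr <- log2(expr + 1)

  v <- apply(expr, 1, stats::var)
  dropped <- rownames(expr)[v == 0 | !is.finite(v)]
  if (length(dropped)) {
    message(sprintf("infer_grn: dropped %d zero-variance gene(s)", length(dropped)))
    expr <- expr[!(rownames(expr) %in% dropped), , drop = FALSE]
    tf_list <- setdiff(tf_list, dropped)
    if (!length(tf_list)) data_error("infer_grn: all TFs have zero variance")
  }

  targets <- rownames(expr)
  tf_expr <- t(expr[tf_list, , drop = FALSE])  # samples x TFs
  edges <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    tg <- targets[i]
    preds <- setdiff(tf_list, tg)
    if (!length(preds)) next
    x <- tf_expr[, preds, drop = FALSE]
    dat <- data.frame(..y = expr[tg, ], x, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = "..y", data = dat,
      num.trees = n_trees,
      mtry = min(length(preds), mtry %||% max(1L, floor(sqrt(length(preds))))),
      importance = importance_measure,
      seed = stage_seed(seed, i),
      num.threads = 1L)
    imp <- fit$variable.importance
    imp[imp < 0] <- 0
    tot <- sum(imp)
    if (tot <= 0) next
    imp <- imp / tot
    keep <- imp > 0
    if (any(keep))
      edges[[i]] <- data.frame(tf = names(imp)[keep], target = tg,
                               importance = unname(imp[keep]),
                               stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges))
    edges <- data.frame(tf = character(), target = character(),
                        importance = numeric())
  rownames(edges) <- NULL
  structure(list(edges = edges, tf_list = tf_list,
                 importance_threshold = importance_threshold,
                 condition_label = condition_label,
                 n_trees = n_trees, seed = seed, dropped = dropped),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  sup <- sum(x$edges$importance > x$importance_threshold)
  cat(sprintf("regulatory network%s: %d TFs, %d edge(s) above importance %.3g (n_trees = %d)\n",
              if (nzchar(x$condition_label)) paste0(" [", x$condition_label, "]") else "",
              length(x$tf_list), sup, x$importance_threshold, x$n_trees))
  invisible(x)
}

#' Network size of a transcription factor
#'
#' The number of distinct targets whose edge from `tf` exceeds the
#' network's importance threshold (overridable via `threshold`).
#'
#' @param net a [infer_grn()] result.
#' @param tf a TF id in `net$tf_list`.
#' @param threshold importance cutoff; defaults to the network's own.
#' @return Integer count.
#' @export
network_size <- function(net, tf, threshold = NULL) {
  stopifnot(inherits(net, "regulatory_network"))
  if (!tf %in% net$tf_list)
    data_error("network_size: unknown TF '%s'", tf)
  threshold <- threshold %||% net$importance_threshold
  e <- net$edges
  length(unique(e$target[e$tf == tf & e$importance > threshold]))
}

#' Sweep the importance threshold
#'
#' Recomputes every TF's network size over a grid of importance
#' thresholds without refitting, for sensitivity analysis of the
#' continuous-importance-to-discrete-network cut.
#'
#' @param net a [infer_grn()] result.
#' @param thresholds numeric vector of cutoffs.
#' @return data.frame `threshold`, `tf`, `network_size`.
#' @export
network_size_sweep <- function(net, thresholds = c(0.01, 0.02, 0.05, 0.1)) {
  stopifnot(inherits(net, "regulatory_network"))
  do.call(rbind, lapply(thresholds, function(th) {
    data.frame(threshold = th, tf = net$tf_list,
               network_size = vapply(net$tf_list, network_size, 0L,
                                     net = net, threshold = th),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Increased-influence table between two conditions
#'
#' For each TF, the inferred network size before and after the condition
#' change and their difference ("increased influence" = after - before).
#' Rows are sorted by increased influence, largest first (ties broken by
#' TF id), and truncated to `top_k` — the usual way of reporting the
#' strongest broad-scale gains of regulatory targets.
#'
#' @param net_before,net_after [infer_grn()] results sharing a TF list.
#' @param tf_subset optional subset of TFs to tabulate (default: all TFs
#'   common to both networks).
#' @param top_k keep the top `top_k` rows (default all).
#' @return data.frame of class `influence_shift`: `tf`,
#'   `network_size_before`, `network_size_after`, `increased_influence`.
#' @export
influence_shift <- function(net_before, net_after, tf_subset = NULL,
                            top_k = Inf) {
  stopifnot(inherits(net_before, "regulatory_network"),
            inherits(net_after, "regulatory_network"))
  shared <- intersect(net_before$tf_list, net_after$tf_list)
  tf_subset <- tf_subset %||% shared
  missing <- setdiff(tf_subset, shared)
  if (length(missing))
    data_error("influence_shift: TF(s) not in both networks: %s",
               paste(missing, collapse = ", "))
  before <- vapply(tf_subset, network_size, 0L, net = net_before)
  after <- vapply(tf_subset, network_size, 0L, net = net_after)
  rank_influence(data.frame(tf = tf_subset,
                            network_size_before = unname(before),
                            network_size_after = unname(after),
                            stringsAsFactors = FALSE),
                 top_k = top_k)
}

#' Rank an influence-shift table from before/after network sizes
#'
#' The arithmetic/ranking core of [influence_shift()], usable directly on
#' a table of published or precomputed per-TF network sizes: computes
#' `increased_influence = network_size_after - network_size_before`,
#' sorts by it (descending, ties by TF id), and truncates to `top_k`.
#'
#' @param sizes data.frame with columns `tf`, `network_size_before`,
#'   `network_size_after` (extra columns are preserved).
#' @param top_k keep the top `top_k` rows.
#' @return data.frame of class `influence_shift`.
#' @examples
#' rank_influence(data.frame(tf = c("PGR", "ESR2"),
#'                           network_size_before = c(28, 29),
#'                           network_size_after = c(114, 67)))
#' @export
rank_influence <- function(sizes, top_k = Inf) {
  need <- c("tf", "network_size_before", "network_size_after")
  missing <- setdiff(need, names(sizes))
  if (length(missing))
    data_error("rank_influence: missing column(s): %s",
               paste(missing, collapse = ", "))
  sizes$increased_influence <-
    sizes$network_size_after - sizes$network_size_before
  ord <- order(-sizes$increased_influence, sizes$tf)
  out <- sizes[ord, , drop = FALSE]
  if (is.finite(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  class(out) <- c("influence_shift", "data.frame")
  out
}

#' Edge-recovery AUROC against a ground-truth edge set
#'
#' Area under the ROC curve for ranking all candidate TF -> target pairs
#' by inferred importance, scored against a set of true edges; computed
#' with the rank (Mann-Whitney) formula. Pairs absent from the inferred
#' edge list score importance 0.
#'
#' @param net a [infer_grn()] result.
#' @param true_edges data.frame with columns `tf`, `target` giving the
#'   true edges (inactive rows, e.g. zero-weight, should be excluded by
#'   the caller).
#' @param targets candidate target ids (default: all targets/genes that
#'   appear in either the inferred or true edges).
#' @return AUROC in [0, 1].
#' @export
edge_recovery_auroc <- function(net, true_edges, targets = NULL) {
  stopifnot(inherits(net, "regulatory_network"))
  targets <- targets %||% sort(unique(c(net$edges$target, true_edges$target)))
  tfs <- net$tf_list
  pairs <- expand.grid(tf = tfs, target = targets, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tf != pairs$target, ]
  key <- function(a, b) paste(a, b, sep = "\r")
  imp <- stats::setNames(net$edges$importance,
                         key(net$edges$tf, net$edges$target))
  score <- imp[key(pairs$tf, pairs$target)]
  score[is.na(score)] <- 0
  lab <- key(pairs$tf, pairs$target) %in% key(true_edges$tf, true_edges$target)
  if (!any(lab) || all(lab))
    data_error("edge_recovery_auroc: need both positive and negative pairs")
  r <- rank(score)
  (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) / (sum(lab) * sum(!lab))
}

#' Write a regulatory network / influence table to TSV
#'
#' @param net a [infer_grn()] result; only edges above the network's
#'   importance threshold are written.
#' @param shift an [influence_shift()] / [rank_influence()] table.
#' @param path output path.
#' @param prov named character vector for the provenance comment line.
#' @return `path`, invisibly.
#' @name grn-writers
NULL

#' @rdname grn-writers
#' @export
write_grn_tsv <- function(net, path, prov = character()) {
  e <- net$edges[net$edges$importance > net$importance_threshold, ]
  e <- e[order(-e$importance, e$tf, e$target), ]
  rownames(e) <- NULL
  write_tsv_prov(e, path, prov)
}

#' @rdname grn-writers
#' @export
write_influence_tsv <- function(shift, path, prov = character()) {
  write_tsv_prov(as.data.frame(shift), path, prov)
}

#' Bundled nuclear-receptor TF list
#'
#' The 48 human nuclear-receptor transcription factors (HGNC symbols), the
#' usual TF universe when asking which hormone receptors gain regulatory
#' influence under androgen deprivation. Shipped as an editable text
#' fixture (`inst/extdata/nuclear_receptors.tsv`), not hard-coded truth.
#'
#' @return Character vector of 48 gene symbols.
#' @export
nuclear_receptors <- function() {
  path <- system.file("extdata", "nuclear_receptors.tsv", package = "netshift")
  read_tsv_prov(path)$symbol
}
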