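#' Generate a paired-condition negative-binomial count matrix
#'
#' Simulates one "dataset" of the two-dataset comparison: an integer count
#' matrix (genes x samples) with `n_samples_per_condition` samples per
#' condition, negative-binomial noise (variance mu + phi mu^2), and a
#' designated set of differentially expressed genes whose condition-B mean
#' is shifted by a per-gene log2 fold-change. Genes shared between the two
#' datasets' DE sets change in the same direction in both; dataset-private
#' DE genes get an independent random direction. Baseline means are
#' log-normal with a floor of 5 counts so rows used downstream are not
#' all-zero; should a row still come out all-zero it receives one count in
#' the first sample of each condition (reported via a message).
#'
#' @param design a [synthetic_design()].
#' @param dataset_index which of the two datasets to generate (1 or 2).
#' @return A list with elements `counts` (integer matrix, rownames = gene
#'   ids, colnames = sample ids), `condition` (factor `"A"`/`"B"` per
#'   column), and `truth` (list: `de_genes`, `shared_de`, `log_fc` named
#'   per-gene signed log2 fold-changes).
#' @examples
#' d <- synthetic_design(n_genes = 50, n_tfs = 5, n_samples_per_condition = 3,
#'                       seed = 7)
#' x <- generate_counts(d, 1)
#' dim(x$counts)
#' @export
generate_counts <- function(design, dataset_index) {
  stopifnot(inherits(design, "synthetic_design"))
  if (!dataset_index %in% c(1L, 2L))
    config_error("invalid design: 'dataset_index' must be 1 or 2")
  truth <- de_truth(design)
  de <- if (dataset_index == 1) truth$de_genes_1 else truth$de_genes_2
  sgn <- if (dataset_index == 1) truth$sign_1 else truth$sign_2
  n <- design$n_genes
  m <- design$n_samples_per_condition
  ids <- design$gene_ids[seq_len(n)]
  lfc <- stats::setNames(numeric(n), ids)
  lfc[de] <- sgn[de] * truth$lfc_magnitude[de]

  counts <- with_seed(stage_seed(design$seed, dataset_index), {
    base_mean <- pmax(5, exp(stats::rnorm(n, mean = log(100), sd = 1)))
    mu_a <- base_mean
    mu_b <- base_mean * 2^lfc
    size <- 1 / design$nb_dispersion
    a <- matrix(stats::rnbinom(n * m, mu = rep(mu_a, m), size = size), nrow = n)
    b <- matrix(stats::rnbinom(n * m, mu = rep(mu_b, m), size = size), nrow = n)
    cbind(a, b)
  })
  rownames(counts) <- ids
  colnames(counts) <- c(sprintf("A%02d", seq_len(m)), sprintf("B%02d", seq_len(m)))
  condition <- factor(rep(c("A", "B"), each = m), levels = c("A", "B"))

  zero <- rowSums(counts) == 0
  if (any(zero)) {
    counts[zero, 1] <- 1L
    counts[zero, m + 1] <- 1L
    message(sprintf("generate_counts: %d all-zero row(s) received a pseudo-count",
                    sum(zero)))
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, condition = condition,
       truth = list(de_genes = de, shared_de = truth$shared_de, log_fc = lfc))
}

#' Generate a scale-free interactome with a mega-hub
#'
#' Grows an undirected simple graph by preferential attachment
#' (`interactome_attachment` edges per incoming node), then wires one
#' designated node up to degree at least `hub_degree`. This emulates the
#' extreme-degree ubiquitin-C-like hub found in curated human interactomes,
#' which downstream loading removes by a degree cutoff. Node ids share the
#' gene-id namespace of [generate_counts()].
#'
#' @param design a [synthetic_design()].
#' @return A list with `edges` (data.frame `protein_a`, `protein_b`, one
#'   unordered edge per row), `hub_id`, and `graph` (the igraph object).
#' @examples
#' d <- synthetic_design(interactome_nodes = 100, hub_degree = 50, seed = 3)
#' g <- generate_interactome(d)
#' max(igraph::degree(g$graph)) >= 50
#' @export
generate_interactome <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  n <- design$interactome_nodes
  g <- with_seed(stage_seed(design$seed, 3), {
    g <- igraph::sample_pa(n, power = 1, m = design$interactome_attachment,
                           directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- design$gene_ids[seq_len(n)]
    ## top up the busiest node to mega-hub degree
    hub <- igraph::V(g)$name[which.max(igraph::degree(g))]
    need <- design$hub_degree - igraph::degree(g, hub)
    if (need > 0) {
      non_nb <- setdiff(igraph::V(g)$name,
                        c(hub, igraph::neighbors(g, hub)$name))
      extra <- sample(non_nb, min(need, length(non_nb)))
      g <- igraph::add_edges(g, c(rbind(rep(hub, length(extra)), extra)))
    }
    g$hub_id <- hub
    g
  })
  el <- igraph::as_edgelist(g)
  edges <- data.frame(protein_a = el[, 1], protein_b = el[, 2],
                      stringsAsFactors = FALSE)
  list(edges = edges, hub_id = g$hub_id, graph = g)
}

#' Generate ground-truth regulatory structure and expression
#'
#' Realizes the regression structure the regulatory-network inference
#' assumes: TF expression is i.i.d. standard normal across samples, and
#' each target gene is a linear combination of its regulator TFs plus
#' Gaussian noise (`regulatory_noise_sd`). Wiring is condition-specific
#' only for one designated "gainer" TF, which regulates `gainer_targets[1]`
#' targets in condition A and `gainer_targets[2]` (a superset) in
#' condition B — the ground truth for a TF whose regulatory influence
#' expands after treatment. All other TF->target edges and weights are
#' identical in the two conditions, and every target is guaranteed at
#' least one such condition-invariant background regulator (no target is
#' pure noise in either condition).
#'
#' @param design a [synthetic_design()].
#' @param gainer_targets length-2 integer vector: number of targets the
#'   gainer TF regulates in conditions A and B.
#' @return A list with `expr_a`, `expr_b` (genes x samples matrices, TFs
#'   included as rows), `true_edges` (data.frame `tf`, `target`,
#'   `weight_a`, `weight_b`; an edge is active in a condition iff its
#'   weight there is nonzero), `gainer_tf`, and `tf_ids`.
#' @examples
#' d <- synthetic_design(n_genes = 60, n_tfs = 5, n_samples_per_condition = 10,
#'                       tf_out_degree_range = c(2, 5), seed = 11)
#' rt <- generate_regulatory_truth(d, gainer_targets = c(2, 10))
#' sum(rt$true_edges$tf == rt$gainer_tf & rt$true_edges$weight_b != 0)
#' @export
generate_regulatory_truth <- function(design, gainer_targets = c(2L, 40L)) {
  stopifnot(inherits(design, "synthetic_design"))
  n_tf <- design$n_tfs
  targets <- design$gene_ids[(n_tf + 1):design$n_genes]
  n_targets <- length(targets)
  if (design$tf_out_degree_range[2] > n_targets)
    config_error("invalid design: max of 'tf_out_degree_range' (%d) exceeds the number of non-TF genes (%d)",
                 design$tf_out_degree_range[2], n_targets)
  if (max(gainer_targets) > n_targets)
    config_error("invalid design: 'gainer_targets' exceeds the number of non-TF genes (%d)",
                 n_targets)
  tfs <- design$tf_ids
  gainer <- tfs[1]
  m <- design$n_samples_per_condition

  with_seed(stage_seed(design$seed, 4), {
    edges <- list()
    ## background wiring, shared across conditions
    for (tf in tfs[-1]) {
      k <- sample(seq(design$tf_out_degree_range[1],
                      design$tf_out_degree_range[2]), 1)
      tg <- sample(targets, k)
      w <- stats::runif(k, 0.75, 1.25) * sample(c(-1, 1), k, replace = TRUE)
      edges[[tf]] <- data.frame(tf = tf, target = tg, weight_a = w, weight_b = w,
                                stringsAsFactors = FALSE)
    }
    ## every target gets at least one condition-invariant background
    ## regulator, so no target is pure noise in either condition (a pure-
    ## noise target spreads importance uniformly over all TFs during
    ## inference, which would swamp any importance threshold)
    covered <- unique(unlist(lapply(edges, `[[`, "target")))
    uncovered <- setdiff(targets, covered)
    if (length(uncovered)) {
      tf_extra <- sample(tfs[-1], length(uncovered), replace = TRUE)
      w <- stats::runif(length(uncovered), 0.75, 1.25) *
        sample(c(-1, 1), length(uncovered), replace = TRUE)
      edges[["coverage"]] <- data.frame(tf = tf_extra, target = uncovered,
                                        weight_a = w, weight_b = w,
                                        stringsAsFactors = FALSE)
    }
    ## gainer: small target set in A, much larger superset in B
    tg_b <- sample(targets, gainer_targets[2])
    tg_a <- tg_b[seq_len(gainer_targets[1])]
    w_b <- stats::runif(gainer_targets[2], 0.75, 1.25) *
      sample(c(-1, 1), gainer_targets[2], replace = TRUE)
    edges[[gainer]] <- data.frame(
      tf = gainer, target = tg_b,
      weight_a = ifelse(tg_b %in% tg_a, w_b, 0),
      weight_b = w_b, stringsAsFactors = FALSE)
    true_edges <- do.call(rbind, unname(edges))
    rownames(true_edges) <- NULL

    sim_condition <- function(weight_col) {
      tf_expr <- matrix(stats::rnorm(n_tf * m), nrow = n_tf,
                        dimnames = list(tfs, sprintf("s%02d", seq_len(m))))
      tg_expr <- matrix(0, nrow = n_targets, ncol = m,
                        dimnames = list(targets, colnames(tf_expr)))
      for (i in seq_len(nrow(true_edges))) {
        w <- true_edges[[weight_col]][i]
        if (w != 0)
          tg_expr[true_edges$target[i], ] <-
            tg_expr[true_edges$target[i], ] + w * tf_expr[true_edges$tf[i], ]
      }
      if (design$regulatory_noise_sd > 0)
        tg_expr <- tg_expr + matrix(stats::rnorm(n_targets * m,
                                                 sd = design$regulatory_noise_sd),
                                    nrow = n_targets)
      rbind(tf_expr, tg_expr)
    }
    expr_a <- sim_condition("weight_a")
    expr_b <- sim_condition("weight_b")
    list(expr_a = expr_a, expr_b = expr_b, true_edges = true_edges,
         gainer_tf = gainer, tf_ids = tfs)
  })
}

#' Write synthetic inputs to disk
#'
#' Writers for the three synthetic artifacts. Each TSV carries a leading
#' comment line with the design hash and seed so downstream runs can detect
#' mismatched re-use; readers in this package skip `#` lines.
#'
#' @param x the object to write (`counts` matrix, interactome `edges`
#'   data.frame, or a truth list).
#' @param design the [synthetic_design()] the object came from.
#' @param path output file path.
#' @return `path`, invisibly.
#' @name synthetic-writers
NULL

#' @rdname synthetic-writers
#' @export
write_counts_tsv <- function(x, design, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_prov(df, path, c(design_hash = design_hash(design),
                             seed = design$seed))
}

#' @rdname synthetic-writers
#' @export
write_interactome_tsv <- function(x, design, path) {
  write_tsv_prov(x, path, c(design_hash = design_hash(design),
                            seed = design$seed))
}

#' @rdname synthetic-writers
#' @export
write_truth_json <- function(x, design, path) {
  x$design_hash <- design_hash(design)
  x$seed <- design$seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a counts TSV written by [write_counts_tsv()]
#'
#' @param path TSV with a `gene` id column followed by one column per sample.
#' @return An integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv_prov(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
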