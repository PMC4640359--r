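#' Read a differential-expression table
#'
#' Expects a TSV with a header and at least the columns `gene`, `logFC`,
#' `PValue`, `FDR` (extra columns are ignored; `#` comment lines are
#' skipped). This is the column layout written by common count-based DE
#' tools and by [call_de_standin()].
#'
#' @param path path to the TSV.
#' @return A data.frame with columns `gene`, `logFC`, `PValue`, `FDR`.
#' @export
read_de_table <- function(path) {
  df <- read_tsv_prov(path)
  need <- c("gene", "logFC", "PValue", "FDR")
  missing <- setdiff(need, names(df))
  if (length(missing))
    data_error("DE table '%s' lacks required column(s): %s",
               path, paste(missing, collapse = ", "))
  df <- df[need]
  df$gene <- as.character(df$gene)
  for (col in c("logFC", "PValue", "FDR")) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Minimal stand-in differential-expression caller
#'
#' A deliberately simple DE caller used for synthetic end-to-end runs (it
#' does not replace a count-model DE tool on real data): counts are
#' normalized to counts-per-million, log2(CPM + 1) transformed, each gene
#' is tested with a Welch two-sample t-test between conditions, and
#' p-values are Benjamini-Hochberg adjusted. Genes with zero counts in all
#' samples are dropped before testing (the number dropped is reported via
#' a message and an attribute).
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param condition factor/vector with two levels giving each sample's
#'   condition; the log fold-change is level 2 minus level 1.
#' @param fdr_threshold unused by the caller itself; recorded for
#'   provenance (significance is decided downstream).
#' @return A data.frame `gene`, `logFC`, `PValue`, `FDR`, one row per
#'   retained gene, in input gene order; attribute `dropped` holds the ids
#'   of all-zero genes.
#' @examples
#' d <- synthetic_design(n_genes = 50, n_tfs = 5, n_samples_per_condition = 4,
#'                       seed = 2)
#' x <- generate_counts(d, 1)
#' de <- call_de_standin(x$counts, x$condition)
#' head(de)
#' @export
call_de_standin <- function(counts, condition, fdr_threshold = 0.05) {
  if (any(counts < 0) || any(counts != floor(counts)))
    data_error("counts must be non-negative integers")
  condition <- factor(condition)
  if (nlevels(condition) != 2)
    data_error("exactly two conditions are required")
  if (any(table(condition) < 2))
    data_error("each condition needs >= 2 samples; with a single replicate use a precomputed DE table instead")

  dropped <- rownames(counts)[rowSums(counts) == 0]
  if (length(dropped)) {
    message(sprintf("call_de_standin: dropped %d gene(s) with zero counts in all samples",
                    length(dropped)))
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  }
  lib <- colSums(counts)
  logcpm <- log2(t(t(counts) / lib) * 1e6 + 1)
  g1 <- condition == levels(condition)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(logcpm[, g1, drop = FALSE])
  m2 <- rowMeans(logcpm[, g2, drop = FALSE])
  v1 <- apply(logcpm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(logcpm[, g2, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  ## Welch-Satterthwaite degrees of freedom
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(tstat)] <- 1  # zero-variance genes: no evidence either way
  out <- data.frame(gene = rownames(counts), logFC = m2 - m1, PValue = p,
                    FDR = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dropped") <- dropped
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' Commonly differentially expressed genes across two datasets
#'
#' Intersects the significant genes of two DE tables: a gene is "commonly
#' DE" when its FDR is below `fdr_threshold` in both tables, and — when
#' `require_concordant_sign` — its log fold-change has the same sign in
#' both. The operation is symmetric in its two tables.
#'
#' @param table1,table2 DE tables as returned by [read_de_table()] or
#'   [call_de_standin()], sharing one gene-id namespace.
#' @param fdr_threshold FDR significance cutoff (default 0.05).
#' @param require_concordant_sign also require agreement in direction of
#'   change (default `FALSE`).
#' @return Sorted character vector of commonly DE gene ids.
#' @export
common_de <- function(table1, table2, fdr_threshold = 0.05,
                      require_concordant_sign = FALSE) {
  sig <- function(tb) tb$gene[!is.na(tb$FDR) & tb$FDR < fdr_threshold]
  if (nrow(table1) == 0 || nrow(table2) == 0) {
    warning("common_de: empty DE table; returning the empty set")
    return(character())
  }
  out <- intersect(sig(table1), sig(table2))
  if (require_concordant_sign && length(out)) {
    s1 <- sign(table1$logFC[match(out, table1$gene)])
    s2 <- sign(table2$logFC[match(out, table2$gene)])
    out <- out[s1 == s2]
  }
  sort(out)
}

#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether the overlap of two gene sets drawn from a finite universe
#' is larger than chance, with the inclusive upper-tail hypergeometric
#' probability P(X >= k) for X ~ Hypergeometric(N = universe size,
#' K = |set1|, n = |set2|) and k the observed overlap.
#'
#' @param universe either the universe size (a single count) or the
#'   character vector of universe gene ids; in the latter case both sets
#'   are checked to be subsets of it.
#' @param set1,set2 character vectors of gene ids (deduplicated
#'   internally).
#' @return A list of class `overlap_result`: `universe_size`, `set1_size`,
#'   `set2_size`, `overlap_size`, `p_hypergeometric`, `overlap_genes`.
#' @examples
#' overlap_test(20, paste0("g", 1:8), paste0("g", 5:12))
#' @export
overlap_test <- function(universe, set1, set2) {
  set1 <- unique(as.character(set1))
  set2 <- unique(as.character(set2))
  if (is.character(universe)) {
    universe <- unique(universe)
    bad <- setdiff(c(set1, set2), universe)
    if (length(bad))
      data_error("overlap_test: ids not in the universe: %s",
                 paste(utils::head(bad, 10), collapse = ", "))
    n_univ <- length(universe)
  } else {
    n_univ <- as.integer(universe)
    if (length(n_univ) != 1 || is.na(n_univ) || n_univ < length(union(set1, set2)))
      data_error("overlap_test: universe size %s is smaller than |set1 U set2| = %d",
                 paste(universe, collapse = ","), length(union(set1, set2)))
  }
  k <- length(intersect(set1, set2))
  p <- stats::phyper(k - 1, length(set1), n_univ - length(set1),
                     length(set2), lower.tail = FALSE)
  structure(list(universe_size = n_univ,
                 set1_size = length(set1),
                 set2_size = length(set2),
                 overlap_size = k,
                 p_hypergeometric = p,
                 overlap_genes = sort(intersect(set1, set2))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d of (%d, %d) in a universe of %d; P(X >= %d) = %.4g\n",
              x$overlap_size, x$set1_size, x$set2_size, x$universe_size,
              x$overlap_size, x$p_hypergeometric))
  invisible(x)
}
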