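#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Parsing is delegated to [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @param source free-text provenance label.
#' @return A list of class `gene_set_collection`: `sets` (named list of
#'   character vectors), `source`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' Build a gene-set collection from a named list
#'
#' @param sets named list of character vectors.
#' @param source free-text provenance label.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "in-memory") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    data_error("gene_set_collection: every set needs a name")
  structure(list(sets = lapply(sets, unique), source = source),
            class = "gene_set_collection")
}

#' Write a collection to GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, collection$source, collection$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment
#'
#' For each set in the collection, tests over-representation of the query
#' in the set with the inclusive upper-tail hypergeometric probability
#' (the same test as [overlap_test()]), restricted to a stated universe,
#' then adjusts across sets for multiple testing. Query genes outside the
#' universe are dropped with a message; sets are intersected with the
#' universe and empty sets removed.
#'
#' @param query character vector of gene ids.
#' @param collection a [read_gmt()] / [gene_set_collection()] object.
#' @param universe character vector of background gene ids (e.g. all
#'   genes tested for differential expression).
#' @param correction `"BH"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`.
#' @return data.frame with one row per tested set: `set_name`,
#'   `overlap_count`, `set_size_in_universe`, `query_size`,
#'   `universe_size`, `p_raw`, `p_adjusted`; sorted by `p_adjusted`, then
#'   `p_raw`, then set name.
#' @examples
#' coll <- gene_set_collection(list(s1 = c("a", "b", "c"), s2 = c("d", "e")))
#' enrich(c("a", "b", "c"), coll, universe = letters[1:6])
#' @export
enrich <- function(query, collection, universe,
                   correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) data_error("enrich: empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(sprintf("enrich: dropped %d query gene(s) outside the universe",
                    length(outside)))
    query <- intersect(query, universe)
  }
  if (!length(query)) data_error("enrich: empty query after universe filtering")
  sets <- lapply(collection$sets, intersect, universe)
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) data_error("enrich: no gene set overlaps the universe")

  n_univ <- length(universe)
  rows <- lapply(sort(names(sets)), function(nm) {
    s <- sets[[nm]]
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, length(s), n_univ - length(s), length(query),
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k,
               set_size_in_universe = length(s),
               query_size = length(query), universe_size = n_univ,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(
    out$p_raw, method = if (correction == "BH") "BH" else "bonferroni")
  out <- out[order(out$p_adjusted, out$p_raw, out$set_name), ]
  rownames(out) <- NULL
  out
}

#' Per-pathway counts of significant DE genes
#'
#' The raw-count companion of [enrich()]: for each set, the number of
#' genes significant at `fdr_threshold` in the DE table that the set
#' contains (no p-value; this is descriptive reporting, e.g. "pathway X
#' contains 42 DE genes").
#'
#' @param de_table a DE table ([read_de_table()] / [call_de_standin()]).
#' @param collection a `gene_set_collection`.
#' @param fdr_threshold FDR cutoff for significance (default 0.05).
#' @return Named integer vector, one count per set.
#' @export
pathway_hit_counts <- function(de_table, collection, fdr_threshold = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sig <- de_table$gene[!is.na(de_table$FDR) & de_table$FDR < fdr_threshold]
  vapply(collection$sets, function(s) length(intersect(s, sig)), 0L)
}
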