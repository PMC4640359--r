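#' Load a protein interactome from a two-column edge list
#'
#' Reads a TSV of unordered protein-id pairs (one interaction per line,
#' `#` comment lines skipped), removes mega-hubs, and returns a simple
#' undirected graph. Hub removal uses the *raw* degree — the number of
#' times an id appears across edge lines as the partner of a distinct
#' line, counted before self-loop/duplicate cleaning — so an
#' extreme-degree node such as ubiquitin C is excluded exactly as it
#' appears in the source file. Self-loops and duplicate (unordered) edges
#' are then dropped, with counts reported.
#'
#' @param path edge-list TSV (no header required; a header line whose two
#'   fields are non-identifiers is tolerated as a comment only if it
#'   starts with `#`).
#' @param hub_degree_cutoff nodes with raw degree above this are removed
#'   together with their incident edges (default 5000).
#' @return An object of class `interactome`: list with `graph` (igraph),
#'   `removed_hubs`, `n_self_loops`, `n_duplicates`.
#' @export
load_interactome <- function(path, hub_degree_cutoff = 5000) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    data_error("malformed interactome line %d: expected two tab-separated ids, got '%s'",
               lineno[bad[1]], lines[bad[1]])
  a <- vapply(parts, `[[`, "", 1)
  b <- vapply(parts, `[[`, "", 2)
  ## drop a header row if present
  if (length(a) && identical(tolower(a[1]), "protein_a")) {
    a <- a[-1]; b <- b[-1]
  }

  raw_degree <- table(c(a[a != b], b[a != b], a[a == b]))
  hubs <- names(raw_degree)[raw_degree > hub_degree_cutoff]
  if (length(hubs))
    message(sprintf("load_interactome: removed %d hub(s) with raw degree > %d: %s",
                    length(hubs), hub_degree_cutoff, paste(hubs, collapse = ", ")))
  keep_edge <- !(a %in% hubs) & !(b %in% hubs)
  a <- a[keep_edge]; b <- b[keep_edge]

  n_self <- sum(a == b)
  a2 <- pmin(a, b)[a != b]
  b2 <- pmax(a, b)[a != b]
  key <- paste(a2, b2, sep = "\r")
  n_dup <- sum(duplicated(key))
  if (n_self || n_dup)
    message(sprintf("load_interactome: dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_self, n_dup))
  uniq <- !duplicated(key)
  if (!any(uniq))
    data_error("interactome '%s' is empty after filtering", path)
  g <- igraph::graph_from_data_frame(
    data.frame(from = a2[uniq], to = b2[uniq], stringsAsFactors = FALSE),
    directed = FALSE)
  structure(list(graph = g, removed_hubs = hubs,
                 n_self_loops = n_self, n_duplicates = n_dup),
            class = "interactome")
}

#' Build an interactome object directly from an edge data.frame
#'
#' Convenience equivalent of [load_interactome()] for in-memory edges
#' (e.g. the output of [generate_interactome()]); applies the same hub
#' removal and simple-graph cleaning.
#'
#' @param edges data.frame whose first two columns are protein ids.
#' @param hub_degree_cutoff as in [load_interactome()].
#' @return An `interactome` object.
#' @export
as_interactome <- function(edges, hub_degree_cutoff = 5000) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  utils::write.table(edges[, 1:2], tf, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  load_interactome(tf, hub_degree_cutoff)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d proteins, %d interactions (%d hub(s) removed)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$removed_hubs)))
  invisible(x)
}

#' Build the disrupted subnetwork around a query gene set
#'
#' Extracts from the interactome the subnetwork through which the
#' functional effects of a query set (typically the commonly
#' differentially expressed genes) are most likely to propagate:
#'
#' 1. candidate nodes = query plus all interaction partners of the query;
#' 2. take the induced subgraph on the candidates;
#' 3. remove every non-query node that interacts with fewer than two
#'    query proteins;
#' 4. remove non-query nodes of degree < 2, and query nodes of degree 0;
#'
#' with rules 3-4 re-applied until nothing changes (the fixpoint of these
#' monotone removals is unique, so the result does not depend on node
#' order). `single_pass = TRUE` instead applies rule 3 once and then
#' rule 4 once, for comparison. Query proteins are retained as long as
#' they keep at least one interaction.
#'
#' Nodes are labelled `"query"`, `"de_one_dataset"` (present in
#' `de_either`, the genes DE in at least one dataset, but not in the
#' query), or `"partner"`.
#'
#' @param interactome an [load_interactome()] object.
#' @param query character vector of query gene ids; ids absent from the
#'   interactome are reported and skipped (some query genes lack known
#'   interactions).
#' @param de_either optional character vector of genes DE in either
#'   dataset, used only for labelling and the DE-fraction statistic.
#' @param force_include optional ids (e.g. a reference receptor) added to
#'   the final network with their query-connecting edges, after pruning.
#' @param single_pass apply each pruning rule once instead of iterating.
#' @return An object of class `disrupted_network`: `graph` (igraph with a
#'   `label` vertex attribute), `node_label` (named character vector),
#'   and `stats` (list: `n_nodes`, `n_edges`, `n_query_with_interactions`,
#'   `n_de_either`, `frac_de`).
#' @examples
#' tri <- as_interactome(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
#' net <- build_disrupted(tri, query = c("A", "B"))
#' net$stats$n_nodes
#' @export
build_disrupted <- function(interactome, query, de_either = NULL,
                            force_include = NULL, single_pass = FALSE) {
  stopifnot(inherits(interactome, "interactome"))
  query <- unique(as.character(query))
  if (!length(query)) data_error("build_disrupted: empty query set")
  g0 <- interactome$graph
  present <- intersect(query, igraph::V(g0)$name)
  if (!length(present))
    data_error("build_disrupted: no query id is present in the interactome")
  if (length(present) < length(query))
    message(sprintf("build_disrupted: %d of %d query id(s) have no known interactions",
                    length(query) - length(present), length(query)))

  candidates <- union(present, unique(
    igraph::V(g0)$name[unlist(igraph::ego(g0, 1, present))]))
  g <- igraph::induced_subgraph(g0, candidates)

  prune_once <- function(g) {
    nodes <- igraph::V(g)$name
    is_q <- nodes %in% present
    deg <- igraph::degree(g)
    qn <- vapply(seq_along(nodes), function(i) {
      nb <- igraph::neighbors(g, nodes[i])$name
      sum(nb %in% present)
    }, 0L)
    drop <- (!is_q & (qn < 2 | deg < 2)) | (is_q & deg == 0)
    igraph::delete_vertices(g, nodes[drop])
  }
  if (single_pass) {
    ## rule 3 then rule 4, each once
    nodes <- igraph::V(g)$name
    is_q <- nodes %in% present
    qn <- vapply(seq_along(nodes), function(i)
      sum(igraph::neighbors(g, nodes[i])$name %in% present), 0L)
    g <- igraph::delete_vertices(g, nodes[!is_q & qn < 2])
    nodes <- igraph::V(g)$name
    is_q <- nodes %in% present
    deg <- igraph::degree(g)
    g <- igraph::delete_vertices(g, nodes[(!is_q & deg < 2) | (is_q & deg == 0)])
  } else {
    repeat {
      n_before <- igraph::vcount(g)
      g <- prune_once(g)
      if (igraph::vcount(g) == n_before) break
    }
  }
  if (igraph::vcount(g) == 0)
    warning("build_disrupted: pruning removed every node; the network is empty")

  if (length(force_include)) {
    extra <- setdiff(intersect(force_include, igraph::V(g0)$name),
                     igraph::V(g)$name)
    if (length(extra)) {
      keep <- union(igraph::V(g)$name, extra)
      g <- igraph::induced_subgraph(g0, keep)
    }
  }

  nodes <- igraph::V(g)$name
  label <- ifelse(nodes %in% present, "query",
                  ifelse(nodes %in% (de_either %||% character()),
                         "de_one_dataset", "partner"))
  names(label) <- nodes
  igraph::V(g)$label <- unname(label)
  n_query <- sum(label == "query")
  n_de <- sum(label == "de_one_dataset")
  stats <- list(n_nodes = length(nodes),
                n_edges = as.integer(igraph::ecount(g)),
                n_query_with_interactions = n_query,
                n_de_either = n_de,
                frac_de = if (length(nodes)) (n_query + n_de) / length(nodes) else NA_real_)
  structure(list(graph = g, node_label = label, stats = stats),
            class = "disrupted_network")
}

#' @export
print.disrupted_network <- function(x, ...) {
  s <- x$stats
  cat(sprintf("disrupted network: %d proteins, %d interactions\n",
              s$n_nodes, s$n_edges))
  cat(sprintf("  query with interactions: %d; DE in one dataset: %d; DE fraction: %.1f%%\n",
              s$n_query_with_interactions, s$n_de_either, 100 * s$frac_de))
  invisible(x)
}

#' Apply a two-column identifier mapping
#'
#' Translates gene ids into the interactome's protein-id namespace (e.g.
#' symbols to Uniprot accessions) using a two-column mapping, applied
#' verbatim: ids without a mapping are dropped with a message, and no
#' normalization of any kind is attempted.
#'
#' @param ids character vector of ids to translate.
#' @param mapping either a data.frame whose first two columns are
#'   (from, to), or the path of a two-column TSV (`#` comments allowed,
#'   no header required unless the first line's fields are `from`/`to`).
#' @return Character vector of translated ids (deduplicated, mapped order).
#' @export
apply_id_mapping <- function(ids, mapping) {
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- utils::read.table(mapping, sep = "\t", header = FALSE,
                                 comment.char = "#", stringsAsFactors = FALSE)
    if (identical(tolower(mapping[1, 1]), "from")) mapping <- mapping[-1, ]
  }
  from <- as.character(mapping[[1]]); to <- as.character(mapping[[2]])
  hit <- ids %in% from
  if (any(!hit))
    message(sprintf("apply_id_mapping: %d id(s) have no mapping and were dropped",
                    sum(!hit)))
  unique(to[match(ids[hit], from)])
}

#' Write a disrupted network to disk
#'
#' Writes the edge list as TSV, the graph as GraphML (with the
#' `label` node attribute), and the composition statistics as JSON.
#'
#' @param net a [build_disrupted()] result.
#' @param prefix path prefix; files `<prefix>_edges.tsv`,
#'   `<prefix>.graphml`, `<prefix>_stats.json` are written.
#' @param prov named character vector for the TSV provenance comment.
#' @return The three paths, invisibly.
#' @export
write_disrupted <- function(net, prefix, prov = character()) {
  stopifnot(inherits(net, "disrupted_network"))
  el <- igraph::as_edgelist(net$graph)
  edges <- data.frame(protein_a = el[, 1], protein_b = el[, 2],
                      stringsAsFactors = FALSE)
  p1 <- paste0(prefix, "_edges.tsv")
  write_tsv_prov(edges, p1, prov)
  p2 <- paste0(prefix, ".graphml")
  igraph::write_graph(net$graph, p2, format = "graphml")
  p3 <- paste0(prefix, "_stats.json")
  jsonlite::write_json(net$stats, p3, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(edges = p1, graphml = p2, stats = p3))
}
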