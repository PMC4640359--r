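## Independent oracles used across the suite. These deliberately avoid the
## implementation's code paths (no igraph, no phyper) so agreement between
## the two routes is informative.

## Exhaustive upper-tail hypergeometric probability by enumerating every
## possible draw of size n from a universe of size N: P(|draw ∩ set1| >= k).
enum_hyper_p <- function(N, K, n, k) {
  universe <- seq_len(N)
  set1 <- seq_len(K)
  draws <- utils::combn(universe, n)
  hits <- apply(draws, 2, function(d) sum(d %in% set1))
  mean(hits >= k)
}

## Brute-force disrupted-network construction on a plain edge data.frame,
## using only vectors and set operations: candidate expansion, induced
## subgraph, then iterated removal of non-query nodes with < 2 query
## neighbours or degree < 2, and of isolated query nodes.
brute_disrupted <- function(edges, query) {
  a0 <- as.character(edges[[1]]); b0 <- as.character(edges[[2]])
  keep <- a0 != b0
  lo <- pmin(a0[keep], b0[keep]); hi <- pmax(a0[keep], b0[keep])
  uniq <- !duplicated(paste(lo, hi))
  a <- lo[uniq]; b <- hi[uniq]
  nodes <- union(a, b)
  present <- intersect(query, nodes)
  nb_of <- function(v, ea, eb) union(eb[ea %in% v], ea[eb %in% v])
  cand <- union(present, nb_of(present, a, b))
  in_cand <- a %in% cand & b %in% cand
  ea <- a[in_cand]; eb <- b[in_cand]
  repeat {
    nodes <- union(ea, eb)
    if (!length(nodes)) break
    deg <- table(c(ea, eb))[nodes]
    qn <- vapply(nodes, function(v)
      length(intersect(nb_of(v, ea, eb), present)), 0L)
    is_q <- nodes %in% present
    drop <- nodes[(!is_q & (qn < 2 | deg < 2))]
    ## query nodes with no remaining edges disappear implicitly (edge-set
    ## representation); removing `drop` and recomputing suffices
    if (!length(drop)) break
    keep_e <- !(ea %in% drop) & !(eb %in% drop)
    ea <- ea[keep_e]; eb <- eb[keep_e]
  }
  list(nodes = sort(union(ea, eb)),
       edges = sort(paste(pmin(ea, eb), pmax(ea, eb))))
}

## Canonical sorted edge strings of a disrupted_network, for comparison.
net_edge_strings <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

read_tsv_prov_test <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

## Small deterministic DE table for threshold tests.
make_de_table <- function(genes, fdr, logfc = rep(1, length(genes))) {
  data.frame(gene = genes, logFC = logfc, PValue = fdr, FDR = fdr,
             stringsAsFactors = FALSE)
}

size_table_path <- function(which) {
  system.file("extdata", sprintf("nr_network_sizes_%s.tsv", which),
              package = "netshift")
}
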