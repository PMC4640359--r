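edge_file <- function(lines) {
  p <- tempfile(fileext = ".tsv")
  writeLines(lines, p)
  p
}

test_that("loader enforces simple-graph rules and reports drops", {
  p <- edge_file(c("A\tA", "A\tB", "B\tA", "B\tC", "A\tB"))
  expect_message(inter <- load_interactome(p), "1 self-loop")
  g <- inter$graph
  expect_equal(igraph::ecount(g), 2)  # A-B, B-C
  expect_true(igraph::is_simple(g))
  expect_identical(inter$n_self_loops, 1L)
  expect_identical(inter$n_duplicates, 2L)
  expect_true("A" %in% igraph::V(g)$name)  # retained via its other edge
})

test_that("loader errors carry the malformed line number", {
  p <- edge_file(c("A\tB", "oops-no-tab", "C\tD"))
  expect_error(load_interactome(p), "line 2", class = "netshift_data_error")
  expect_error(load_interactome(edge_file("A\tA")), "empty",
               class = "netshift_data_error")
})

test_that("mega-hubs are removed by raw degree before any other filtering", {
  d <- synthetic_design(interactome_nodes = 300, hub_degree = 200, seed = 13)
  g <- generate_interactome(d)
  p <- tempfile(fileext = ".tsv")
  write_interactome_tsv(g$edges, d, p)
  suppressMessages(inter <- load_interactome(p, hub_degree_cutoff = 100))
  expect_false(g$hub_id %in% igraph::V(inter$graph)$name)
  expect_identical(inter$removed_hubs, g$hub_id)
  ## with a high cutoff the hub survives
  inter2 <- load_interactome(p, hub_degree_cutoff = 1000)
  expect_true(g$hub_id %in% igraph::V(inter2$graph)$name)
})

test_that("star and triangle pruning behave per the construction rules", {
  ## star: every leaf has one query neighbour and degree 1 -> all pruned,
  ## then the isolated centre goes too
  star <- as_interactome(data.frame(a = rep("hub", 5), b = paste0("leaf", 1:5)))
  expect_warning(net <- build_disrupted(star, query = "hub"), "empty")
  expect_identical(net$stats$n_nodes, 0L)
  ## triangle with two query nodes: the third is a minimal passing partner
  tri <- as_interactome(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  net <- build_disrupted(tri, query = c("A", "B"))
  expect_setequal(igraph::V(net$graph)$name, c("A", "B", "C"))
  expect_identical(net$stats$n_edges, 3L)
  expect_identical(unname(net$node_label["C"]), "partner")
  expect_identical(unname(net$node_label["A"]), "query")
})

test_that("node labels and composition statistics are consistent", {
  tri <- as_interactome(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  net <- build_disrupted(tri, query = c("A", "B"), de_either = "C")
  expect_identical(unname(net$node_label["C"]), "de_one_dataset")
  s <- net$stats
  expect_identical(s$n_query_with_interactions, 2L)
  expect_identical(s$n_de_either, 1L)
  expect_equal(s$frac_de, (s$n_query_with_interactions + s$n_de_either) / s$n_nodes)
  expect_equal(s$frac_de, 1)
})

test_that("query ids missing from the interactome are tolerated, empty overlap is not", {
  tri <- as_interactome(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  expect_message(net <- build_disrupted(tri, query = c("A", "B", "nope")),
                 "no known interactions")
  expect_identical(net$stats$n_nodes, 3L)
  expect_error(build_disrupted(tri, query = "nope"),
               class = "netshift_data_error")
})

test_that("construction matches the brute-force oracle on seeded interactomes", {
  for (s in 1:4) {
    d <- synthetic_design(interactome_nodes = 400, hub_degree = 80,
                          n_genes = 400, n_tfs = 5,
                          n_samples_per_condition = 3, seed = 400 + s)
    g <- generate_interactome(d)
    query <- with_seed_local(s, sample(igraph::V(g$graph)$name, 40))
    inter <- as_interactome(g$edges, hub_degree_cutoff = 1e6)
    net <- build_disrupted(inter, query)
    oracle <- brute_disrupted(g$edges, query)
    expect_setequal(igraph::V(net$graph)$name, oracle$nodes)
    expect_identical(net_edge_strings(net), oracle$edges)
  }
})

test_that("pruning is idempotent and output is a subgraph of the input", {
  d <- synthetic_design(interactome_nodes = 500, hub_degree = 100, seed = 44)
  g <- generate_interactome(d)
  inter <- as_interactome(g$edges, hub_degree_cutoff = 1e6)
  query <- with_seed_local(7, sample(igraph::V(inter$graph)$name, 50))
  net <- build_disrupted(inter, query)
  ## subgraph of the input interactome
  expect_true(all(net_edge_strings(net) %in% {
    el <- igraph::as_edgelist(inter$graph)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }))
  ## re-running on its own output changes nothing
  inter2 <- structure(list(graph = net$graph, removed_hubs = character(),
                           n_self_loops = 0L, n_duplicates = 0L),
                      class = "interactome")
  net2 <- build_disrupted(inter2, query)
  expect_identical(net_edge_strings(net2), net_edge_strings(net))
  expect_setequal(igraph::V(net2$graph)$name, igraph::V(net$graph)$name)
})

test_that("force-included reference nodes are added after pruning", {
  ## D hangs off one query node only -> pruned; force_include restores it
  inter <- as_interactome(data.frame(a = c("A", "B", "C", "A"),
                                     b = c("B", "C", "A", "D")))
  net <- build_disrupted(inter, query = c("A", "B"))
  expect_false("D" %in% igraph::V(net$graph)$name)
  net2 <- build_disrupted(inter, query = c("A", "B"), force_include = "D")
  expect_true("D" %in% igraph::V(net2$graph)$name)
})

test_that("identifier mapping is applied verbatim and reports unmapped ids", {
  map <- data.frame(from = c("TP53", "PGR"), to = c("P04637", "P06401"))
  expect_message(out <- apply_id_mapping(c("TP53", "PGR", "NOVEL1"), map),
                 "1 id")
  expect_identical(out, c("P04637", "P06401"))
  p <- tempfile(fileext = ".tsv")
  write.table(map, p, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_identical(suppressMessages(apply_id_mapping("PGR", p)), "P06401")
})

test_that("disrupted network writers emit edge list, GraphML and stats", {
  tri <- as_interactome(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  net <- build_disrupted(tri, query = c("A", "B"))
  pre <- tempfile()
  write_disrupted(net, pre, prov = c(config = "abc"))
  expect_identical(nrow(read_tsv_prov_test(paste0(pre, "_edges.tsv"))), 3L)
  expect_match(readLines(paste0(pre, "_edges.tsv"), n = 1), "config=abc")
  st <- jsonlite::read_json(paste0(pre, "_stats.json"))
  expect_identical(st$n_nodes, 3L)
  g2 <- igraph::read_graph(paste0(pre, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g2), 3)
})
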