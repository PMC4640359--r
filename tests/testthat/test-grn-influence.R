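make_single_regulator_expr <- function(n_tfs = 20, n_samples = 50, seed = 1,
                                       weight = 3) {
  set.seed(seed)
  expr <- matrix(rnorm((n_tfs + 1) * n_samples), nrow = n_tfs + 1,
                 dimnames = list(c(paste0("tf", seq_len(n_tfs)), "y"), NULL))
  expr["y", ] <- weight * expr["tf1", ]
  expr
}

test_that("a noiseless single regulator dominates its target's importances", {
  expr <- make_single_regulator_expr()
  tfs <- paste0("tf", 1:20)
  ## default mtry = sqrt(#TFs): the true regulator is ranked first with a
  ## share far above the uniform level 1/19, but fully grown trees still
  ## credit part of the variance to uninformative predictors
  net <- infer_grn(expr, tfs, n_trees = 100, seed = 1)
  e <- net$edges[net$edges$target == "y", ]
  expect_identical(e$tf[which.max(e$importance)], "tf1")
  expect_gt(max(e$importance), 5 / 19)
  ## with every predictor available at every split the share approaches 1
  net_all <- infer_grn(expr, tfs, n_trees = 100, seed = 1, mtry = 19)
  e_all <- net_all$edges[net_all$edges$target == "y", ]
  expect_gt(e_all$importance[e_all$tf == "tf1"], 0.9)
})

test_that("networks have no self-edges and per-target importances sum to 1", {
  d <- synthetic_design(n_genes = 40, n_tfs = 8, n_samples_per_condition = 15,
                        tf_out_degree_range = c(1, 4), seed = 6)
  rt <- generate_regulatory_truth(d, gainer_targets = c(1, 6))
  net <- infer_grn(rt$expr_a, rt$tf_ids, n_trees = 100, seed = 2)
  expect_false(any(net$edges$tf == net$edges$target))
  sums <- tapply(net$edges$importance, net$edges$target, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  ## TFs appear as modelled targets too
  expect_true(any(net$edges$target %in% rt$tf_ids))
})

test_that("inference is deterministic under a fixed seed", {
  d <- synthetic_design(n_genes = 30, n_tfs = 5, n_samples_per_condition = 10,
                        tf_out_degree_range = c(1, 3), seed = 9)
  rt <- generate_regulatory_truth(d, gainer_targets = c(1, 5))
  n1 <- infer_grn(rt$expr_a, rt$tf_ids, n_trees = 50, seed = 5)
  n2 <- infer_grn(rt$expr_a, rt$tf_ids, n_trees = 50, seed = 5)
  expect_identical(n1$edges, n2$edges)
})

test_that("input validation: samples, TF membership, zero variance", {
  expr <- matrix(rnorm(20), nrow = 5,
                 dimnames = list(paste0("g", 1:5), NULL))
  expect_error(infer_grn(expr[, 1:2], "g1"), "3 samples",
               class = "netshift_data_error")
  expect_error(infer_grn(expr, character()), "empty",
               class = "netshift_data_error")
  expect_error(infer_grn(expr, "zzz"), "zzz", class = "netshift_data_error")
  expr2 <- rbind(expr, flat = 1)
  expect_message(net <- infer_grn(expr2, "g1", n_trees = 20, seed = 1),
                 "zero-variance")
  expect_identical(net$dropped, "flat")
})

test_that("network_size counts supra-threshold targets and validates the TF", {
  net <- structure(list(
    edges = data.frame(tf = c("t1", "t1", "t1", "t2"),
                       target = c("a", "b", "c", "a"),
                       importance = c(0.5, 0.15, 0.05, 0.3)),
    tf_list = c("t1", "t2"), importance_threshold = 0.1),
    class = "regulatory_network")
  expect_identical(network_size(net, "t1"), 2L)
  expect_identical(network_size(net, "t2"), 1L)
  expect_identical(network_size(net, "t1", threshold = 0), 3L)
  expect_identical(network_size(net, "t1", threshold = 0.9), 0L)
  expect_error(network_size(net, "t9"), "t9", class = "netshift_data_error")
  sweep <- network_size_sweep(net, thresholds = c(0, 0.1, 0.4))
  expect_identical(sweep$network_size[sweep$tf == "t1"], c(3L, 2L, 1L))
})

test_that("influence shift ranks by gain, negates on swap, zeroes on identity", {
  net_a <- structure(list(
    edges = data.frame(tf = c("t1", "t2", "t2"), target = c("a", "a", "b"),
                       importance = c(0.5, 0.5, 0.5)),
    tf_list = c("t1", "t2", "t3"), importance_threshold = 0.1),
    class = "regulatory_network")
  net_b <- structure(list(
    edges = data.frame(tf = c("t1", "t1", "t1"), target = c("a", "b", "c"),
                       importance = c(0.5, 0.5, 0.5)),
    tf_list = c("t1", "t2", "t3"), importance_threshold = 0.1),
    class = "regulatory_network")
  sh <- influence_shift(net_a, net_b)
  expect_identical(sh$tf, c("t1", "t3", "t2"))  # +2, 0, -2; tie broken by id
  expect_identical(sh$increased_influence, c(2L, 0L, -2L))
  expect_identical(sh$increased_influence,
                   sh$network_size_after - sh$network_size_before)
  ## swapping conditions negates the shift values
  sh_rev <- influence_shift(net_b, net_a)
  expect_identical(sort(sh_rev$increased_influence),
                   sort(-sh$increased_influence))
  ## identity
  sh0 <- influence_shift(net_a, net_a)
  expect_true(all(sh0$increased_influence == 0))
  ## unknown TF subset errors with the missing ids
  expect_error(influence_shift(net_a, net_b, tf_subset = c("t1", "t9")),
               "t9", class = "netshift_data_error")
  ## top_k truncation
  expect_identical(nrow(influence_shift(net_a, net_b, top_k = 2)), 2L)
})

test_that("published per-receptor size tables rank PGR first in both contrasts", {
  for (which in c("tumour", "cell_line")) {
    sizes <- read_tsv_prov_test(size_table_path(which))
    sh <- rank_influence(sizes, top_k = 10)
    expect_identical(sh$tf[1], "PGR")
    expect_identical(sh$increased_influence,
                     sh$network_size_after - sh$network_size_before)
  }
  tum <- rank_influence(read_tsv_prov_test(size_table_path("tumour")))
  expect_identical(tum$increased_influence[tum$tf == "PGR"], 86L)
  cl <- rank_influence(read_tsv_prov_test(size_table_path("cell_line")))
  expect_identical(cl$increased_influence[cl$tf == "PGR"], 52L)
})

test_that("edge-recovery AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  d <- synthetic_design(n_genes = 40, n_tfs = 8, n_samples_per_condition = 20,
                        tf_out_degree_range = c(1, 4), seed = 15)
  rt <- generate_regulatory_truth(d, gainer_targets = c(1, 6))
  net <- infer_grn(rt$expr_a, rt$tf_ids, n_trees = 100, seed = 3)
  truth <- rt$true_edges[rt$true_edges$weight_a != 0, ]
  targets <- setdiff(rownames(rt$expr_a), rt$tf_ids)
  mine <- edge_recovery_auroc(net, truth, targets = targets)
  ## rebuild the score/label vectors and hand them to pROC
  pairs <- expand.grid(tf = rt$tf_ids, target = targets,
                       stringsAsFactors = FALSE)
  key <- function(a, b) paste(a, b)
  imp <- stats::setNames(net$edges$importance, key(net$edges$tf, net$edges$target))
  score <- imp[key(pairs$tf, pairs$target)]
  score[is.na(score)] <- 0
  lab <- key(pairs$tf, pairs$target) %in% key(truth$tf, truth$target)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("the nuclear-receptor fixture lists the 48 human receptors", {
  nr <- nuclear_receptors()
  expect_length(nr, 48)
  expect_true(all(c("AR", "PGR", "ESR1", "NR3C1", "VDR") %in% nr))
  expect_false(any(duplicated(nr)))
  ## every receptor named in the bundled size tables is in the panel
  for (which in c("tumour", "cell_line"))
    expect_true(all(read_tsv_prov_test(size_table_path(which))$tf %in% nr))
})

test_that("GRN writers apply the threshold and stamp provenance", {
  net <- structure(list(
    edges = data.frame(tf = c("t1", "t2"), target = c("a", "b"),
                       importance = c(0.5, 0.05)),
    tf_list = c("t1", "t2"), importance_threshold = 0.1,
    condition_label = "before", n_trees = 10L, seed = 1L,
    dropped = character()), class = "regulatory_network")
  p <- tempfile(fileext = ".tsv")
  write_grn_tsv(net, p, prov = c(config = "xyz"))
  out <- read_tsv_prov_test(p)
  expect_identical(out$tf, "t1")  # sub-threshold edge not exported
  expect_match(readLines(p, n = 1), "config=xyz")
})
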