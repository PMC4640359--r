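#' Specify a synthetic study design
#'
#' A `synthetic_design` fixes every parameter of the synthetic inputs the
#' pipeline consumes: two paired-condition negative-binomial count
#' "datasets" with a controlled shared differential-expression (DE)
#' structure, a scale-free interactome containing one mega-hub, and a
#' ground-truth transcription-factor (TF) regulatory network whose wiring
#' differs between the two conditions. All generators draw from RNG
#' substreams derived from `seed` (counts for dataset 1, counts for
#' dataset 2, interactome, regulatory truth — in that order), so each
#' stage is reproducible when rerun independently.
#'
#' The defaults describe a small two-condition RNA-seq-like experiment:
#' 248 genes of which the first 48 are TFs — the size of the human
#' nuclear-receptor panel that is the usual TF universe for this
#' analysis — plus 200 regulated targets, 50 samples per condition
#' (enough for tree-ensemble regression), 10 % of genes DE per dataset
#' with half of them shared between datasets, a mean absolute log2
#' fold-change of 2, and gene-level negative-binomial dispersion 0.1
#' (variance mu + phi mu^2). The interactome has 1000 nodes grown by
#' preferential attachment plus one node wired up to degree >= 200,
#' a scaled-down analogue of the ubiquitin-C hub that dominates curated
#' human interactomes.
#'
#' @param n_genes total number of genes; gene ids are `g0001`, `g0002`, ...
#' @param n_tfs number of TFs (the first `n_tfs` gene ids); must be `< n_genes`.
#' @param n_samples_per_condition samples per condition in every matrix.
#' @param frac_de_dataset1,frac_de_dataset2 fraction of genes DE in each dataset.
#' @param frac_shared_de fraction of genes DE in *both* datasets; must not
#'   exceed either per-dataset fraction.
#' @param nb_dispersion negative-binomial dispersion phi (variance mu + phi mu^2).
#' @param mean_log_fc mean absolute log2 fold-change of DE genes.
#' @param interactome_nodes number of interactome nodes.
#' @param interactome_attachment edges added per node during preferential
#'   attachment (>= 1).
#' @param hub_degree minimum degree of the designated mega-hub node.
#' @param tf_out_degree_range length-2 integer vector, min/max targets per TF
#'   in the ground-truth regulatory network.
#' @param regulatory_noise_sd standard deviation of the additive Gaussian
#'   noise on each regulated target (0 gives noiseless, fully deterministic
#'   targets).
#' @param seed integer master seed.
#'
#' @return An object of class `synthetic_design` (a validated list).
#' @examples
#' d <- synthetic_design(n_genes = 100, n_tfs = 10, seed = 1)
#' d$gene_ids[1:3]
#' @export
synthetic_design <- function(n_genes = 248,
                             n_tfs = 48,
                             n_samples_per_condition = 50,
                             frac_de_dataset1 = 0.1,
                             frac_de_dataset2 = 0.1,
                             frac_shared_de = 0.05,
                             nb_dispersion = 0.1,
                             mean_log_fc = 2,
                             interactome_nodes = 1000,
                             interactome_attachment = 2,
                             hub_degree = 200,
                             tf_out_degree_range = c(2L, 10L),
                             regulatory_noise_sd = 0.5,
                             seed = 1L) {
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != floor(x))
      config_error("invalid design: '%s' must be a single integer >= %d (got %s)",
                   nm, min, paste(x, collapse = ","))
  }
  chk_frac <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      config_error("invalid design: '%s' must be a fraction in [0, 1] (got %s)",
                   nm, paste(x, collapse = ","))
  }
  chk_count(n_genes, "n_genes")
  chk_count(n_tfs, "n_tfs")
  chk_count(n_samples_per_condition, "n_samples_per_condition")
  chk_count(interactome_nodes, "interactome_nodes")
  chk_count(interactome_attachment, "interactome_attachment")
  chk_count(hub_degree, "hub_degree")
  chk_count(seed, "seed", min = 0)
  chk_frac(frac_de_dataset1, "frac_de_dataset1")
  chk_frac(frac_de_dataset2, "frac_de_dataset2")
  chk_frac(frac_shared_de, "frac_shared_de")
  if (frac_shared_de > min(frac_de_dataset1, frac_de_dataset2) + 1e-12)
    config_error("invalid design: 'frac_shared_de' (%g) exceeds min(frac_de_dataset1, frac_de_dataset2) (%g)",
                 frac_shared_de, min(frac_de_dataset1, frac_de_dataset2))
  if (n_tfs >= n_genes)
    config_error("invalid design: 'n_tfs' (%d) must be smaller than 'n_genes' (%d)",
                 n_tfs, n_genes)
  if (length(nb_dispersion) != 1 || !is.finite(nb_dispersion) || nb_dispersion <= 0)
    config_error("invalid design: 'nb_dispersion' must be a positive real")
  if (length(regulatory_noise_sd) != 1 || !is.finite(regulatory_noise_sd) ||
      regulatory_noise_sd < 0)
    config_error("invalid design: 'regulatory_noise_sd' must be a non-negative real")
  if (length(tf_out_degree_range) != 2 || any(tf_out_degree_range < 0) ||
      tf_out_degree_range[1] > tf_out_degree_range[2])
    config_error("invalid design: 'tf_out_degree_range' must be (min, max) with min <= max")
  if (interactome_nodes <= hub_degree)
    config_error("invalid design: 'interactome_nodes' (%d) must exceed 'hub_degree' (%d)",
                 interactome_nodes, hub_degree)
  if (!is.finite(mean_log_fc))
    config_error("invalid design: 'mean_log_fc' must be a real number")

  n_ids <- max(n_genes, interactome_nodes)
  design <- list(
    n_genes = as.integer(n_genes),
    n_tfs = as.integer(n_tfs),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    frac_de_dataset1 = frac_de_dataset1,
    frac_de_dataset2 = frac_de_dataset2,
    frac_shared_de = frac_shared_de,
    nb_dispersion = nb_dispersion,
    mean_log_fc = mean_log_fc,
    interactome_nodes = as.integer(interactome_nodes),
    interactome_attachment = as.integer(interactome_attachment),
    hub_degree = as.integer(hub_degree),
    tf_out_degree_range = as.integer(tf_out_degree_range),
    regulatory_noise_sd = regulatory_noise_sd,
    seed = as.integer(seed),
    gene_ids = sprintf("g%04d", seq_len(n_ids)),
    tf_ids = sprintf("g%04d", seq_len(n_tfs))
  )
  class(design) <- "synthetic_design"
  design
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("synthetic_design:",
      sprintf("%d genes (%d TFs), %d samples/condition, seed %d",
              x$n_genes, x$n_tfs, x$n_samples_per_condition, x$seed), "\n")
  cat(sprintf("  DE fractions: %.3g / %.3g (shared %.3g), |log2FC| ~ %.3g, NB dispersion %.3g\n",
              x$frac_de_dataset1, x$frac_de_dataset2, x$frac_shared_de,
              x$mean_log_fc, x$nb_dispersion))
  cat(sprintf("  interactome: %d nodes, attachment %d, hub degree >= %d\n",
              x$interactome_nodes, x$interactome_attachment, x$hub_degree))
  invisible(x)
}

## Stable hash of the design parameters (drops derived id vectors).
design_hash <- function(design) {
  keep <- setdiff(names(design), c("gene_ids", "tf_ids"))
  hash_string(paste(keep, vapply(design[keep], function(v)
    paste(format(v, digits = 15), collapse = ","), ""), collapse = ";"))
}

## The DE truth shared between the two datasets: which genes are DE in each,
## which are shared, and the per-gene log2 fold-changes. Shared genes get one
## sign used by both datasets (concordant direction); dataset-private genes
## get independent signs. Drawn from the design-level substream (offset 0) so
## generate_counts(d, 1) and generate_counts(d, 2) agree on the truth.
de_truth <- function(design) {
  n <- design$n_genes
  n1 <- round(design$frac_de_dataset1 * n)
  n2 <- round(design$frac_de_dataset2 * n)
  ns <- round(design$frac_shared_de * n)
  ns <- min(ns, n1, n2)
  with_seed(stage_seed(design$seed, 0), {
    ids <- design$gene_ids[seq_len(n)]
    pool <- sample(ids)
    shared <- sort(pool[seq_len(ns)])
    rest <- pool[seq_len(n - ns) + ns]
    only1 <- sort(rest[seq_len(n1 - ns)])
    only2 <- sort(rest[(n1 - ns) + seq_len(n2 - ns)])
    magnitude <- pmax(0.25, stats::rnorm(n, mean = abs(design$mean_log_fc), sd = 0.25))
    names(magnitude) <- ids
    shared_sign <- stats::setNames(sample(c(-1, 1), length(shared), replace = TRUE), shared)
    sign1 <- c(shared_sign,
               stats::setNames(sample(c(-1, 1), length(only1), replace = TRUE), only1))
    sign2 <- c(shared_sign,
               stats::setNames(sample(c(-1, 1), length(only2), replace = TRUE), only2))
    list(de_genes_1 = sort(c(shared, only1)),
         de_genes_2 = sort(c(shared, only2)),
         shared_de = shared,
         lfc_magnitude = magnitude,
         sign_1 = sign1, sign_2 = sign2)
  })
}
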