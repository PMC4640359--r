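#' Assemble and validate a pipeline configuration
#'
#' Collects every input path and tuning parameter of the four-stage
#' pipeline (DE overlap -> disrupted network -> regulatory influence
#' shift -> enrichment) into a validated object. Either two precomputed
#' DE tables (`de_table_1`, `de_table_2`) or two count matrices
#' (`counts_1`, `counts_2`, analysed with the stand-in caller) must be
#' supplied. The regulatory stage runs when `expr_before`, `expr_after`
#' and `tf_list` are given; enrichment when `gmt` is given.
#'
#' @param output_dir directory for artifacts (created if needed).
#' @param de_table_1,de_table_2 DE table TSVs (see [read_de_table()]).
#' @param counts_1,counts_2 counts TSVs (see [read_counts_tsv()]); each
#'   needs a matching `condition_1`/`condition_2` vector of sample
#'   conditions, or an A/B split on the sample-name prefix is used.
#' @param interactome edge-list TSV (required).
#' @param expr_before,expr_after expression TSVs for the two conditions.
#' @param tf_list file with one TF id per line (or a `symbol` column).
#' @param gmt GMT gene-set collection.
#' @param fdr_threshold,require_concordant_sign see [common_de()].
#' @param hub_degree_cutoff see [load_interactome()].
#' @param n_trees,importance_threshold see [infer_grn()].
#' @param top_k rows kept in the influence-shift table (default 10).
#' @param correction see [enrich()].
#' @param seed master seed for the regulatory stage.
#' @return A validated list of class `pipeline_config` with a `hash`
#'   field (md5 of the canonical parameter string).
#' @export
pipeline_config <- function(output_dir,
                            de_table_1 = NULL, de_table_2 = NULL,
                            counts_1 = NULL, counts_2 = NULL,
                            interactome = NULL,
                            expr_before = NULL, expr_after = NULL,
                            tf_list = NULL, gmt = NULL,
                            fdr_threshold = 0.05,
                            require_concordant_sign = FALSE,
                            hub_degree_cutoff = 5000,
                            n_trees = 1000,
                            importance_threshold = 0.1,
                            top_k = 10,
                            correction = "BH",
                            seed = 1L) {
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    config_error("fdr_threshold must be in (0, 1]")
  if (importance_threshold < 0)
    config_error("importance_threshold must be >= 0")
  if (n_trees < 1 || top_k < 1 || hub_degree_cutoff < 1)
    config_error("n_trees, top_k and hub_degree_cutoff must be positive")
  if (!correction %in% c("BH", "bonferroni"))
    config_error("correction must be 'BH' or 'bonferroni'")
  have_de <- !is.null(de_table_1) && !is.null(de_table_2)
  have_counts <- !is.null(counts_1) && !is.null(counts_2)
  if (!have_de && !have_counts)
    config_error("supply either two DE tables or two counts matrices")
  if (is.null(interactome))
    config_error("an interactome edge list is required")
  paths <- c(de_table_1 = de_table_1, de_table_2 = de_table_2,
             counts_1 = counts_1, counts_2 = counts_2,
             interactome = interactome, expr_before = expr_before,
             expr_after = expr_after, tf_list = tf_list, gmt = gmt)
  for (nm in names(paths))
    if (!file.exists(paths[[nm]]))
      data_error("input '%s' not found: %s", nm, paths[[nm]])

  cfg <- list(output_dir = output_dir,
              de_table_1 = de_table_1, de_table_2 = de_table_2,
              counts_1 = counts_1, counts_2 = counts_2,
              interactome = interactome,
              expr_before = expr_before, expr_after = expr_after,
              tf_list = tf_list, gmt = gmt,
              fdr_threshold = fdr_threshold,
              require_concordant_sign = require_concordant_sign,
              hub_degree_cutoff = hub_degree_cutoff,
              n_trees = as.integer(n_trees),
              importance_threshold = importance_threshold,
              top_k = as.integer(top_k),
              correction = correction,
              seed = as.integer(seed))
  ## hash the tuning parameters and input-file *names* (not their absolute
  ## locations), so identical runs materialized in different directories
  ## stamp identical provenance
  path_fields <- c("de_table_1", "de_table_2", "counts_1", "counts_2",
                   "interactome", "expr_before", "expr_after", "tf_list", "gmt")
  param <- cfg[setdiff(names(cfg), "output_dir")]
  param[path_fields] <- lapply(param[path_fields],
                               function(p) if (is.null(p)) NULL else basename(p))
  cfg$hash <- hash_string(paste(names(param), vapply(param, function(v)
    paste(format(v %||% "NULL", digits = 15), collapse = ","), ""),
    sep = "=", collapse = ";"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML mapping whose keys are the arguments of
#' [pipeline_config()]; `overrides` (e.g. parsed command-line flags)
#' replace file values.
#'
#' @param path YAML file.
#' @param overrides named list merged over the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

read_expression_tsv <- function(path) {
  df <- read_tsv_prov(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

read_tf_list <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^symbol\\b", first)) read_tsv_prov(path)$symbol
  else {
    x <- readLines(path)
    x <- trimws(x[!grepl("^\\s*#", x)])
    x[nzchar(x)]
  }
}

infer_condition <- function(counts) {
  pre <- substr(colnames(counts), 1, 1)
  if (length(unique(pre)) != 2)
    data_error("cannot infer two conditions from sample names; supply explicit labels")
  factor(pre)
}

#' Run the full pipeline
#'
#' Executes the stages in order — DE overlap, disrupted network,
#' regulatory influence shift, enrichment — writing per-stage artifacts
#' into `config$output_dir`, all stamped with the config hash, and a
#' combined `report.json` plus human-readable `summary.txt`. A failing
#' stage aborts with its name and cause and leaves a `FAILED` marker
#' file naming the stage; reruns with identical config and inputs
#' reproduce identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return The report, invisibly (a list; see `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(config = config$hash, seed = config$seed)
  report <- list(config_hash = config$hash, seed = config$seed,
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 package_version = as.character(utils::packageVersion("netshift")))
  out <- function(f) file.path(config$output_dir, f)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage, conditionMessage(e)),
               out("FAILED"))
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = class(e)[1]))
  }
  tryCatch({
    ## ---- stage 1: DE overlap -------------------------------------------
    stage <- "de_overlap"
    if (!is.null(config$de_table_1)) {
      de1 <- read_de_table(config$de_table_1)
      de2 <- read_de_table(config$de_table_2)
    } else {
      c1 <- read_counts_tsv(config$counts_1)
      c2 <- read_counts_tsv(config$counts_2)
      de1 <- call_de_standin(c1, infer_condition(c1), config$fdr_threshold)
      de2 <- call_de_standin(c2, infer_condition(c2), config$fdr_threshold)
    }
    common <- common_de(de1, de2, config$fdr_threshold,
                        config$require_concordant_sign)
    universe <- intersect(de1$gene, de2$gene)  # genes tested in both
    sig1 <- de1$gene[de1$FDR < config$fdr_threshold]
    sig2 <- de2$gene[de2$FDR < config$fdr_threshold]
    ov <- overlap_test(universe, intersect(sig1, universe),
                       intersect(sig2, universe))
    writeLines(common, out("common_de_genes.txt"))
    report$overlap <- ov[setdiff(names(ov), "overlap_genes")]
    report$n_common_de <- length(common)
    jsonlite::write_json(report$overlap, out("overlap.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    ## ---- stage 2: disrupted network ------------------------------------
    stage <- "disrupted_network"
    inter <- load_interactome(config$interactome, config$hub_degree_cutoff)
    net <- build_disrupted(inter, query = common,
                           de_either = union(sig1, sig2))
    write_disrupted(net, out("disrupted"), prov)
    report$disrupted_stats <- net$stats

    ## ---- stage 3: regulatory influence shift ---------------------------
    if (!is.null(config$expr_before) && !is.null(config$tf_list)) {
      stage <- "grn_influence"
      tfs <- read_tf_list(config$tf_list)
      eb <- read_expression_tsv(config$expr_before)
      ea <- read_expression_tsv(config$expr_after)
      gb <- infer_grn(eb, tfs, n_trees = config$n_trees,
                      importance_threshold = config$importance_threshold,
                      seed = config$seed, condition_label = "before")
      ga <- infer_grn(ea, tfs, n_trees = config$n_trees,
                      importance_threshold = config$importance_threshold,
                      seed = config$seed, condition_label = "after")
      shift <- influence_shift(gb, ga, top_k = config$top_k)
      write_grn_tsv(gb, out("grn_before.tsv"), prov)
      write_grn_tsv(ga, out("grn_after.tsv"), prov)
      write_influence_tsv(shift, out("influence_shift.tsv"), prov)
      report$influence_shift <- as.data.frame(shift)
    }

    ## ---- stage 4: enrichment -------------------------------------------
    if (!is.null(config$gmt)) {
      stage <- "enrichment"
      coll <- read_gmt(config$gmt)
      enr <- enrich(common, coll, universe, correction = config$correction)
      write_tsv_prov(enr, out("enrichment_common_de.tsv"), prov)
      hits1 <- pathway_hit_counts(de1, coll, config$fdr_threshold)
      hits2 <- pathway_hit_counts(de2, coll, config$fdr_threshold)
      hits <- data.frame(set_name = names(hits1), dataset1 = unname(hits1),
                         dataset2 = unname(hits2[names(hits1)]),
                         stringsAsFactors = FALSE)
      write_tsv_prov(hits, out("pathway_hit_counts.tsv"), prov)
      report$top_enrichment <- utils::head(enr, 5)
      report$pathway_hit_counts <- hits
    }

    ## ---- report ---------------------------------------------------------
    stage <- "report"
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    summ <- c(
      sprintf("netshift pipeline report (config %s, seed %d)",
              config$hash, config$seed),
      sprintf("Common DE genes: %d (overlap p = %.3g, universe %d)",
              report$n_common_de, report$overlap$p_hypergeometric,
              report$overlap$universe_size),
      sprintf("Disrupted network: %d proteins, %d interactions, %.1f%% DE",
              report$disrupted_stats$n_nodes, report$disrupted_stats$n_edges,
              100 * report$disrupted_stats$frac_de),
      if (!is.null(report$influence_shift))
        c("Top increased influence:",
          sprintf("  %s: %d -> %d (+%d)",
                  report$influence_shift$tf,
                  report$influence_shift$network_size_before,
                  report$influence_shift$network_size_after,
                  report$influence_shift$increased_influence)))
    writeLines(summ, out("summary.txt"))
    unlink(out("FAILED"))
    invisible(report)
  }, error = on_fail)
}

#' One-command synthetic demonstration
#'
#' Generates a complete synthetic study (two paired-condition count
#' datasets, an interactome with a mega-hub, condition-specific
#' regulatory expression, a small gene-set collection that plants the
#' shared DE genes in one set), writes the inputs to
#' `<out_dir>/inputs/`, and runs [run_pipeline()] on them.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param design optional [synthetic_design()] (default: the standard
#'   design with this seed).
#' @param n_trees forest size passed to the pipeline (default 200; the
#'   demo favours a short runtime).
#' @return The pipeline report, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L, design = NULL, n_trees = 200) {
  design <- design %||% synthetic_design(seed = seed)
  inp <- file.path(out_dir, "inputs")
  dir.create(inp, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(inp, f)

  d1 <- generate_counts(design, 1)
  d2 <- generate_counts(design, 2)
  write_counts_tsv(d1$counts, design, p("counts_dataset1.tsv"))
  write_counts_tsv(d2$counts, design, p("counts_dataset2.tsv"))
  inter <- generate_interactome(design)
  write_interactome_tsv(inter$edges, design, p("interactome.tsv"))
  rt <- generate_regulatory_truth(design)
  for (cond in c("a", "b")) {
    m <- rt[[paste0("expr_", cond)]]
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write_tsv_prov(df, p(sprintf("expression_%s.tsv", cond)),
                   c(design_hash = design_hash(design), seed = design$seed))
  }
  writeLines(c("symbol", rt$tf_ids), p("tf_list.tsv"))
  write_truth_json(list(de_genes_1 = d1$truth$de_genes,
                        de_genes_2 = d2$truth$de_genes,
                        shared_de = d1$truth$shared_de,
                        hub_id = inter$hub_id,
                        gainer_tf = rt$gainer_tf),
                   design, p("truth.json"))
  ## plant the shared DE genes in one "pathway"; add random decoys
  genes <- design$gene_ids[seq_len(design$n_genes)]
  decoys <- with_seed(stage_seed(design$seed, 5), list(
    s2 = sample(genes, 30), s3 = sample(genes, 25)))
  coll <- gene_set_collection(list(
    planted_shared_de = union(d1$truth$shared_de,
                              utils::head(setdiff(genes, d1$truth$shared_de), 10)),
    decoy_pathway_1 = decoys$s2,
    decoy_pathway_2 = decoys$s3), source = "synthetic")
  write_gmt(coll, p("genesets.gmt"))

  cfg <- pipeline_config(
    output_dir = out_dir,
    counts_1 = p("counts_dataset1.tsv"),
    counts_2 = p("counts_dataset2.tsv"),
    interactome = p("interactome.tsv"),
    expr_before = p("expression_a.tsv"),
    expr_after = p("expression_b.tsv"),
    tf_list = p("tf_list.tsv"),
    gmt = p("genesets.gmt"),
    hub_degree_cutoff = 100,
    n_trees = n_trees,
    seed = seed)
  run_pipeline(cfg)
}
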