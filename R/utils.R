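#' @keywords internal
"_PACKAGE"

## Condition constructors used across the pipeline: configuration problems
## (bad parameters, malformed config) vs data problems (malformed or
## inconsistent inputs). The command-line wrapper maps these to exit codes.

config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("netshift_config_error", "netshift_error")))
}

data_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("netshift_data_error", "netshift_error")))
}

## md5 of a canonical string, via a tempfile (tools::md5sum is file-based)
hash_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

## Derive a stage seed from a base seed; keeps results < 2^31 - 1.
stage_seed <- function(seed, offset) {
  (as.numeric(seed) * 7L + offset) %% 2147483647
}

## TSV writer that prefixes a provenance comment line ("# key=value ...");
## the matching reader skips '#' lines.
write_tsv_prov <- function(df, path, prov = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(prov))
    writeLines(paste0("# ", paste(names(prov), unname(prov), sep = "=",
                                  collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path, header = TRUE, ...) {
  utils::read.table(path, sep = "\t", header = header, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
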