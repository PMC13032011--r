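#' Read and write cohort tables
#'
#' Cohorts round-trip as CSV with a header of the 16 schema feature names
#' plus `Myopia`. Reading validates the column set against the schema and
#' reports the exact difference on mismatch; rows with missing values are
#' rejected (the pipeline analyses complete cases).
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @param strict Validate the schema on read (default TRUE).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, strict = TRUE) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (strict) {
    expected <- c(myopia_feature_names(), "Myopia")
    missing <- setdiff(expected, names(out))
    extra <- setdiff(names(out), expected)
    if (length(missing) || length(extra)) {
      abort(paste0("cohort schema mismatch; missing: [",
                   paste(missing, collapse = ", "), "], unexpected: [",
                   paste(extra, collapse = ", "), "]"))
    }
    if (any(!complete.cases(out))) abort("cohort contains missing values")
  }
  out
}

#' Load a run configuration
#'
#' Plain-text `key = value` configuration; `#` starts a comment. Unknown
#' keys are rejected. Every parameter has the package default when the
#' file omits it.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @param overrides Named list of values taking precedence over the file.
#' @return A validated named list (`run_config`).
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L, alpha = 0.05, max_depth = 3L, grid_num = 10L, bins_k = 10L,
    epochs = 200L, lr = 0.01, batch_size = 32L,
    ensemble_gbdt = 10, ensemble_rf = 1,
    refute_relative_threshold = 0.10, refute_absolute_threshold = 0.05,
    refute_reps = 20L
  )
  cfg <- defaults
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) abort(paste("bad config line:", ln))
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(defaults)) abort(paste("unknown config key:", key))
      cfg[[key]] <- if (is.integer(defaults[[key]])) as.integer(val) else as.numeric(val)
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(defaults)) abort(paste("unknown config key:", key))
    if (!is.null(overrides[[key]])) cfg[[key]] <- overrides[[key]]
  }
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$grid_num >= 2, cfg$bins_k >= 2,
            cfg$refute_reps >= 1)
  structure(cfg, class = "run_config")
}
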