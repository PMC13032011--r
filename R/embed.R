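#' Infer column kinds for mixed-type embedding
#'
#' Columns matching the cohort schema take their documented kind; otherwise
#' numeric columns that are integer-valued with at most `max_levels` distinct
#' values are treated as discrete, everything else as continuous.
#'
#' @param data A data frame.
#' @param max_levels Distinct-value cutoff for calling a column discrete.
#' @return Named character vector, one of `continuous`, `discrete_ordinal`,
#'   `binary` per column.
#' @export
infer_kinds <- function(data, max_levels = 10) {
  spec <- myopia_variable_specs()
  vapply(names(data), function(nm) {
    if (nm %in% spec$name) return(spec$kind[spec$name == nm])
    x <- data[[nm]]
    u <- unique(x[is.finite(x)])
    if (length(u) == 2) "binary"
    else if (all(u == round(u)) && length(u) <= max_levels) "discrete_ordinal"
    else "continuous"
  }, character(1))
}

#' One-hot / degenerate-Gaussian embedding of mixed columns
#'
#' Builds the real design matrix the degenerate-Gaussian likelihood-ratio
#' test operates on: continuous columns are standardized to mean 0, SD 1;
#' each discrete or binary column is replaced by one-hot level indicators
#' with the first (lowest) level dropped as reference. The returned mapping
#' records which embedded columns belong to each original variable.
#'
#' @param data A data frame.
#' @param columns Columns to embed (default: all).
#' @param kinds Optional named kind vector as from [infer_kinds()].
#' @return A list with `matrix` (n x p numeric), `blocks` (named list of
#'   column indices per original variable), and `kinds`.
#' @examples
#' emb <- embed_mixed(generate_cohort(default_myopia_scm(), 200, seed = 1),
#'                    columns = c("AL", "PWG"))
#' sapply(emb$blocks, length)
#' @export
embed_mixed <- function(data, columns = names(data), kinds = NULL) {
  kinds <- kinds %||% infer_kinds(data[columns])
  mats <- list()
  blocks <- list()
  p <- 0L
  for (nm in columns) {
    x <- data[[nm]]
    if (kinds[[nm]] == "continuous") {
      s <- sd(x)
      if (!is.finite(s) || s == 0) abort(paste0("column '", nm, "' is constant: degenerate input"))
      m <- matrix((x - mean(x)) / s, ncol = 1)
    } else {
      lev <- sort(unique(x))
      if (length(lev) < 2) abort(paste0("column '", nm, "' is constant: degenerate input"))
      m <- vapply(lev[-1], function(l) as.numeric(x == l), numeric(length(x)))
      m <- matrix(m, nrow = length(x))
    }
    mats[[nm]] <- m
    blocks[[nm]] <- p + seq_len(ncol(m))
    p <- p + ncol(m)
  }
  X <- do.call(cbind, mats)
  colnames(X) <- unlist(lapply(names(blocks), function(nm) {
    k <- length(blocks[[nm]])
    if (k == 1) nm else paste0(nm, "_", seq_len(k))
  }))
  list(matrix = X, blocks = blocks, kinds = kinds[columns])
}
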