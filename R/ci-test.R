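#' @keywords internal
#' @noRd
pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 1e-300)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Sufficient statistics for the degenerate-Gaussian CI test: embed once,
# keep the MLE covariance of the embedded matrix. All tests then reduce to
# small determinant computations on sub-blocks.
ci_cache <- function(data, columns = names(data), kinds = NULL) {
  emb <- embed_mixed(data, columns, kinds)
  X <- emb$matrix
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  list(S = S, n = n, blocks = emb$blocks, kinds = emb$kinds)
}

# log det of the residual covariance of block `yb` after regressing out the
# embedded columns `cb` (possibly empty). Returns list(logdet, singular).
resid_logdet <- function(S, yb, cb) {
  Syy <- S[yb, yb, drop = FALSE]
  singular <- FALSE
  if (length(cb)) {
    Scc <- S[cb, cb, drop = FALSE]
    Syc <- S[yb, cb, drop = FALSE]
    inv <- tryCatch(solve(Scc), error = function(e) {
      singular <<- TRUE
      pinv(Scc)
    })
    Syy <- Syy - Syc %*% inv %*% t(Syc)
  }
  d <- determinant(Syy, logarithm = TRUE)
  list(logdet = as.numeric(d$modulus), singular = singular)
}

dg_lrt_cache <- function(cache, x, y, cond = character(0)) {
  S <- cache$S
  xb <- cache$blocks[[x]]
  yb <- cache$blocks[[y]]
  cb <- unlist(cache$blocks[cond], use.names = FALSE)
  full <- resid_logdet(S, yb, c(cb, xb))
  red <- resid_logdet(S, yb, cb)
  if (full$singular || red$singular) {
    warn(sprintf("collinear embedded design in CI test of %s vs %s", x, y))
  }
  stat <- max(0, cache$n * (red$logdet - full$logdet))
  dof <- length(xb) * length(yb)
  p <- pchisq(stat, df = dof, lower.tail = FALSE)
  tibble(x = x, y = y, cond = paste(sort(cond), collapse = ","),
         statistic = stat, dof = dof, p_value = p)
}

#' Degenerate-Gaussian likelihood-ratio conditional-independence test
#'
#' Tests whether columns `x` and `y` are conditionally independent given the
#' columns in `cond`, on mixed continuous/discrete data. Discrete columns are
#' one-hot embedded ([embed_mixed()]); the test is then the Gaussian
#' likelihood-ratio comparison of the regression of `y`'s embedded block on
#' the blocks of `cond` plus `x` versus `cond` alone. The statistic
#' `n * log(det ratio)` of the residual covariances is referred to a
#' chi-squared distribution with `(x columns) x (y columns)` degrees of
#' freedom. The block statistic is symmetric in `x` and `y` (both directions
#' reduce to the same canonical-correlation determinant ratio), so no
#' direction has to be privileged.
#'
#' @param data A data frame containing `x`, `y` and `cond` columns.
#' @param x,y Column names to test; must differ and not appear in `cond`.
#' @param cond Character vector of conditioning column names.
#' @param kinds Optional named kind vector ([infer_kinds()]).
#' @return A one-row tibble with `statistic`, `dof` and `p_value`.
#' @examples
#' d <- data.frame(a = rnorm(500), b = rnorm(500))
#' dg_lrt(d, "a", "b")$p_value
#' @export
dg_lrt <- function(data, x, y, cond = character(0), kinds = NULL) {
  if (x == y) abort("x and y must differ")
  if (x %in% cond || y %in% cond) abort("x and y may not appear in cond")
  cols <- c(x, y, cond)
  if (!all(cols %in% names(data))) abort("columns missing from data")
  cache <- ci_cache(data, cols, kinds)
  dims <- sum(lengths(cache$blocks))
  if (nrow(data) <= dims + 2) abort("too few rows for the embedded dimension")
  dg_lrt_cache(cache, x, y, cond)
}
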