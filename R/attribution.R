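#' Gaussian summary of the input distribution
#'
#' Sample mean vector and covariance matrix of the model's input features on
#' the standardized scale the network sees. This is the object
#' do-interventions mutate: the second-order Taylor approximation of an
#' intervention expectation only needs these two moments.
#'
#' @param cohort Cohort data frame.
#' @param model Optional `fnn_classifier`; when given, its feature order and
#'   standardization constants are used (recommended, so summary and model
#'   share a scale). Otherwise the cohort's own mean/SD standardize.
#' @param features Feature columns when no model is given.
#' @return A `gaussian_summary`: `mean`, `cov`, `features`, `center`,
#'   `scale`.
#' @export
fit_gaussian_summary <- function(cohort, model = NULL, features = NULL) {
  if (!is.null(model)) {
    features <- model$feature_order
    center <- model$center
    scale <- model$scale
  } else {
    features <- features %||% setdiff(names(cohort), "Myopia")
    X0 <- as.matrix(cohort[features])
    center <- colMeans(X0)
    scale <- apply(X0, 2, sd)
    if (any(scale == 0)) {
      warn("constant column(s): zero variance rows/columns in the covariance")
      scale[scale == 0] <- 1
    }
  }
  if (nrow(cohort) <= length(features)) abort("need more records than features")
  X <- standardize_features(as.matrix(cohort[features]), center, scale)
  S <- cov(X)
  S <- (S + t(S)) / 2
  structure(list(mean = colMeans(X), cov = S, features = features,
                 center = center, scale = scale),
            class = "gaussian_summary")
}

#' @export
print.gaussian_summary <- function(x, ...) {
  cat(sprintf("<gaussian_summary> %d features (standardized scale)\n",
              length(x$features)))
  invisible(x)
}

to_std <- function(summary, unit, value) {
  (value - summary$center[[unit]]) / summary$scale[[unit]]
}

#' Apply a do-intervention to a Gaussian summary
#'
#' do(x = alpha) semantics on the moments: the intervened feature's mean is
#' pinned to the (standardized) intervention value and its covariance row
#' and column are zeroed — a fixed variable has no variance and no
#' co-variation. For isolated units nothing else changes. When a causal
#' graph and edge coefficients are supplied (pure-unit mode), downstream
#' means are additionally shifted by the sum over directed paths of the
#' path coefficient product times the mean displacement, and the covariance
#' is replaced by its Schur complement with respect to the intervened
#' feature, which removes the variance the descendants inherited through
#' it while staying positive-semidefinite.
#'
#' @param summary A `gaussian_summary`.
#' @param unit Feature name to intervene on.
#' @param alpha Intervention value on the raw feature scale.
#' @param graph,coeffs Optional finalized `causal_graph` and edge
#'   coefficient tibble ([fit_edge_coefficients()]) switching on pure-unit
#'   propagation.
#' @return A new `gaussian_summary`.
#' @export
intervene_summary <- function(summary, unit, alpha, graph = NULL, coeffs = NULL) {
  if (!unit %in% summary$features) abort(paste("unknown unit:", unit))
  i <- match(unit, summary$features)
  mu <- summary$mean
  S <- summary$cov
  a_std <- to_std(summary, unit, alpha)
  if (!is.null(graph)) {
    if (is.null(coeffs)) abort("pure-unit intervention needs edge coefficients")
    desc <- setdiff(intersect(descendants(graph, unit), summary$features), unit)
    # raw-scale displacement of the intervened unit
    d_raw <- alpha - (summary$center[[unit]] + mu[i] * summary$scale[[unit]])
    for (d in desc) {
      eff <- total_effect_pure(graph, coeffs, unit, d)$effect
      mu[d] <- mu[d] + eff * d_raw / summary$scale[[d]]
    }
    if (S[i, i] > 1e-12) {
      S <- S - tcrossprod(S[, i]) / S[i, i]
    }
  }
  mu[i] <- a_std
  S[i, ] <- 0
  S[, i] <- 0
  out <- summary
  out$mean <- mu
  out$cov <- (S + t(S)) / 2
  out
}

#' Second-order Taylor approximation of an intervention expectation
#'
#' `E[f(x)]` for `x ~ N(mu, Sigma)` approximated by
#' `f(mu) + 0.5 * tr(H(mu) %*% Sigma)` with `H` the Hessian of the chosen
#' class output at the mean. Exact for linear and quadratic outputs; for
#' the ReLU network it is a local approximation whose error grows with the
#' covariance scale.
#'
#' @param model An `fnn_classifier` or `linear_surrogate`.
#' @param summary A `gaussian_summary` on the model's feature scale.
#' @param class_index Output class (1 = "No", 2 = "Yes").
#' @return Scalar expectation approximation.
#' @export
taylor_expectation <- function(model, summary, class_index = 2) {
  H <- model_hessian(model, summary$mean, class_index)
  if (any(!is.finite(H))) abort("non-finite Hessian entries")
  model_value(model, summary$mean, class_index) + 0.5 * sum(H * summary$cov)
}

#' Intervention grid for a unit
#'
#' `num` evenly spaced intervention values including the endpoints. Default
#' bounds are the observed 1st and 99th percentiles of the unit (avoiding
#' extrapolation past the data); binary units get the two-point grid
#' `{0, 1}`.
#'
#' @param cohort Cohort data frame.
#' @param unit Feature name.
#' @param num Number of grid points (default 10).
#' @param probs Quantile bounds (default `c(0.01, 0.99)`).
#' @return List with `unit`, `low`, `high`, `num`, `alphas`.
#' @export
intervention_grid <- function(cohort, unit, num = 10, probs = c(0.01, 0.99)) {
  x <- cohort[[unit]]
  if (is.null(x)) abort(paste("unknown unit:", unit))
  u <- unique(x)
  if (length(u) == 2 && all(sort(u) == c(0, 1))) {
    return(list(unit = unit, low = 0, high = 1, num = 2L, alphas = c(0, 1)))
  }
  lo <- as.numeric(quantile(x, probs[1]))
  hi <- as.numeric(quantile(x, probs[2]))
  if (!(lo < hi)) abort("degenerate grid: low must be below high")
  list(unit = unit, low = lo, high = hi, num = as.integer(num),
       alphas = seq(lo, hi, length.out = num))
}

assemble_curve <- function(unit, alphas, exp_no, exp_yes, num) {
  curve <- tibble(
    unit = unit,
    class = rep(c("No", "Yes"), each = length(alphas)),
    alpha = rep(alphas, 2),
    expectation = c(exp_no, exp_yes)
  ) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::mutate(centered = .data$expectation - mean(.data$expectation)) %>%
    dplyr::ungroup()
  ace <- if (num == 2) {
    # binary units: the two-point interventional contrast E[do(1)] - E[do(0)]
    c(No = exp_no[2] - exp_no[1], Yes = exp_yes[2] - exp_yes[1])
  } else {
    c(No = mean(exp_no), Yes = mean(exp_yes))
  }
  structure(curve, class = c("ace_curve", class(curve)),
            unit = unit, ace = ace)
}

#' Causal attribution curve for an isolated unit
#'
#' Sweeps the intervention grid: for every alpha, the Gaussian summary is
#' intervened with do(unit = alpha) and the expectation of each output
#' class is approximated with [taylor_expectation()]. For a two-point
#' (binary) grid the reported ACE is the interventional contrast
#' `E[y|do(1)] - E[y|do(0)]`; for larger grids it is the grid average of
#' the intervention expectations. The `centered` column subtracts each
#' class's own curve mean, which is how trends are read off the curve.
#'
#' @param model An `fnn_classifier` (or `linear_surrogate`).
#' @param summary A `gaussian_summary`.
#' @param grid An [intervention_grid()].
#' @param graph Optional finalized `causal_graph`; when given, the unit
#'   must classify as Isolated or the call is refused (pure/confounded
#'   units have their own engines).
#' @return An `ace_curve` tibble (`unit`, `class`, `alpha`, `expectation`,
#'   `centered`) with attribute `ace` (named per class).
#' @export
ace_isolated <- function(model, summary, grid, graph = NULL) {
  if (!is.null(graph)) {
    cat_ <- classify_units(graph, graph$nodes)
    k <- cat_$category[cat_$unit == grid$unit]
    if (length(k) && k != "Isolated") {
      abort(sprintf("unit '%s' is %s, not Isolated: use the matching engine",
                    grid$unit, as.character(k)))
    }
  }
  ex <- vapply(grid$alphas, function(a) {
    s <- intervene_summary(summary, grid$unit, a)
    c(taylor_expectation(model, s, 1), taylor_expectation(model, s, 2))
  }, numeric(2))
  assemble_curve(grid$unit, grid$alphas, ex[1, ], ex[2, ], grid$num)
}

#' Linear edge coefficients of a causal graph
#'
#' Assuming linear causal relationships, fits each node with parents by
#' ordinary least squares on all its parents jointly (raw feature scale);
#' the coefficient attached to an edge is the corresponding partial slope.
#' Collinear parent sets fall back to the minimum-norm pseudo-inverse
#' solution with a warning.
#'
#' @param cohort Cohort data frame.
#' @param g Finalized `causal_graph` over cohort columns.
#' @return Tibble `from`, `to`, `coef`.
#' @export
fit_edge_coefficients <- function(cohort, g) {
  if (!is_finalized(g)) abort("graph must be a DAG")
  out <- list()
  for (v in g$nodes) {
    pa <- parents(g, v)
    if (!length(pa)) next
    X <- cbind(1, as.matrix(cohort[pa]))
    y <- cohort[[v]]
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      warn(sprintf("collinear parents of %s: using pseudo-inverse", v))
      beta <- as.numeric(pinv(crossprod(X)) %*% crossprod(X, y))
    } else {
      beta <- qr.coef(qrX, y)
    }
    out[[v]] <- tibble(from = pa, to = v, coef = as.numeric(beta[-1]))
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble(from = character(), to = character(), coef = numeric())
}

#' Total causal effect of a pure unit along directed paths
#'
#' The total effect is the sum over all directed paths from `unit` to
#' `target` of the product of the edge coefficients along the path
#' (direct effect plus every mediated contribution). No directed path
#' means a zero effect.
#'
#' @param g Finalized `causal_graph`.
#' @param coeffs Edge coefficients ([fit_edge_coefficients()] or SCM truth).
#' @param unit,target Node names.
#' @return List with `effect` (scalar) and `paths` (tibble `path`,
#'   `effect`, one row per directed path).
#' @export
total_effect_pure <- function(g, coeffs, unit, target) {
  paths <- enumerate_paths(g, unit, target)
  paths <- paths[lengths(paths) > 1 | (unit == target)]
  if (!length(paths)) {
    return(list(effect = 0,
                paths = tibble(path = character(), effect = numeric())))
  }
  lut <- setNames(coeffs$coef, paste(coeffs$from, coeffs$to))
  rows <- purrr::map_dfr(paths, function(p) {
    if (length(p) == 1) return(tibble(path = p, effect = 1))
    steps <- paste(p[-length(p)], p[-1])
    if (any(!steps %in% names(lut))) abort("missing edge coefficient on a path")
    tibble(path = paste(p, collapse = " -> "), effect = prod(lut[steps]))
  })
  list(effect = sum(rows$effect), paths = rows)
}

#' Causal attribution curve for a pure unit
#'
#' Like [ace_isolated()], but the intervention is propagated through the
#' causal graph before the Taylor step: downstream mediators' means are
#' shifted by the path-product total effects of the displacement, and the
#' covariance loses the variance the mediators inherited through the unit
#' (Schur complement). The network then sees a summary consistent with the
#' interventional distribution.
#'
#' @param model An `fnn_classifier` (or `linear_surrogate`).
#' @param cohort Cohort data frame (used for the summary and the edge
#'   regressions unless both are supplied).
#' @param g Finalized `causal_graph`.
#' @param grid An [intervention_grid()].
#' @param coeffs Optional precomputed edge coefficients.
#' @param summary Optional precomputed `gaussian_summary`.
#' @param check Refuse units that do not classify as Pure (default TRUE).
#' @return An `ace_curve` tibble, as [ace_isolated()].
#' @export
ace_pure <- function(model, cohort, g, grid, coeffs = NULL, summary = NULL,
                     check = TRUE) {
  if (check) {
    cat_ <- classify_units(g, g$nodes)
    k <- cat_$category[cat_$unit == grid$unit]
    if (length(k) && k != "Pure") {
      abort(sprintf("unit '%s' is %s, not Pure", grid$unit, as.character(k)))
    }
  }
  coeffs <- coeffs %||% fit_edge_coefficients(cohort, g)
  summary <- summary %||% fit_gaussian_summary(cohort, model)
  ex <- vapply(grid$alphas, function(a) {
    s <- intervene_summary(summary, grid$unit, a, graph = g, coeffs = coeffs)
    c(taylor_expectation(model, s, 1), taylor_expectation(model, s, 2))
  }, numeric(2))
  assemble_curve(grid$unit, grid$alphas, ex[1, ], ex[2, ], grid$num)
}

#' Average causal effect of a curve
#'
#' @param curve An `ace_curve`.
#' @return Named numeric vector (`No`, `Yes`).
#' @export
ace <- function(curve) attr(curve, "ace")

#' Write an attribution curve as CSV
#'
#' Columns `alpha`, `expectation_no`, `expectation_yes`, `centered_no`,
#' `centered_yes`.
#'
#' @param curve An `ace_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  wide <- as_tibble(curve) %>%
    tidyr::pivot_wider(names_from = "class",
                       values_from = c("expectation", "centered")) %>%
    dplyr::rename_with(tolower)
  readr::write_csv(wide, path)
  invisible(path)
}

#' Plot an attribution curve
#'
#' Centered intervention-response curves per output class: the
#' difference between each class's intervention expectation and its
#' grid average, against the intervention value.
#'
#' @param object An `ace_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ace_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha, y = .data$centered,
                                       colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = paste0("do(", attr(object, "unit"), " = alpha)"),
                  y = "centered intervention expectation",
                  colour = "output class") +
    ggplot2::theme_minimal()
}
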