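#' Discretize a continuous treatment into ordered bins
#'
#' Equal-width bins split the observed range into `k` intervals of equal
#' length; equal-frequency bins place the edges at the `i/k` empirical
#' quantiles so group sizes differ by at most one. The last bin is
#' right-closed; every value is assigned.
#'
#' @param values Numeric vector.
#' @param strategy `"equal_width"` or `"equal_frequency"`.
#' @param k Bin count (>= 2).
#' @return A `binning`: `strategy`, `k`, `edges` (length k+1) and
#'   `assignment` (integer bin index per value).
#' @examples
#' discretize(0:10, "equal_width", k = 10)$edges
#' @export
discretize <- function(values, strategy = c("equal_width", "equal_frequency"), k = 10) {
  strategy <- match.arg(strategy)
  if (k < 2) abort("k must be at least 2")
  if (length(unique(values)) < k) abort("too few distinct values for k bins")
  if (strategy == "equal_width") {
    lo <- min(values); hi <- max(values)
    if (lo == hi) abort("constant vector cannot be discretized")
    edges <- seq(lo, hi, length.out = k + 1)
  } else {
    sx <- sort(values)
    n <- length(sx)
    # edges at the i*n/k order statistics so bin counts differ by <= 1
    edges <- c(sx[1], sx[ceiling(seq_len(k - 1) * n / k)], sx[n])
    if (anyDuplicated(edges)) abort("too few distinct values for k quantile bins")
  }
  assignment <- as.integer(cut(values, breaks = edges, right = TRUE,
                               include.lowest = TRUE, labels = FALSE))
  structure(list(strategy = strategy, k = as.integer(k), edges = edges,
                 assignment = assignment),
            class = "binning")
}

#' @export
print.binning <- function(x, ...) {
  cat(sprintf("<binning> %s, k = %d\n", x$strategy, x$k))
  invisible(x)
}

clip01 <- function(p, lo = 0.01, hi = 0.99) pmin(pmax(p, lo), hi)

make_folds <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

xgb_fit <- function(X, y, objective, weight = NULL, control) {
  d <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
  if (!is.null(weight)) xgboost::setinfo(d, "weight", weight)
  xgboost::xgb.train(
    params = list(objective = objective, max_depth = control$max_depth,
                  eta = control$eta, nthread = 1),
    data = d, nrounds = control$nrounds, verbose = 0
  )
}

#' Default learner settings for the meta-learner
#'
#' @param nrounds,max_depth,eta Gradient-boosting settings.
#' @param num_trees,min_node_size Random-forest settings.
#' @return A named list.
#' @export
meta_learner_control <- function(nrounds = 100, max_depth = 3, eta = 0.1,
                                 num_trees = 200, min_node_size = 10) {
  list(nrounds = nrounds, max_depth = max_depth, eta = eta,
       num_trees = num_trees, min_node_size = min_node_size)
}

#' Cross-fitted propensity scores
#'
#' Probability of treatment given the adjustment covariates, fitted by a
#' gradient-boosted classifier with K-fold cross-fitting (each record is
#' scored by a model that never saw it). Scores are clipped to
#' `[0.01, 0.99]` before any weighting. A calibration slope (logistic
#' regression of the treatment on the score logit) is reported as a
#' diagnostic.
#'
#' @param cohort Data frame holding the covariates.
#' @param treatment 0/1 treatment indicator vector.
#' @param Z Covariate column names (non-empty).
#' @param folds Cross-fitting folds (default 5).
#' @param seed Integer seed.
#' @param control Learner settings ([meta_learner_control()]).
#' @return A `propensity_model`: `score` (clipped per-record vector),
#'   `Z`, `calibration_slope`, `folds`.
#' @export
estimate_propensity <- function(cohort, treatment, Z, folds = 5, seed = 1,
                                control = meta_learner_control()) {
  if (!length(Z)) abort("Z must be non-empty")
  if (length(unique(treatment)) < 2) abort("treatment indicator is constant")
  X <- as.matrix(cohort[Z])
  n <- nrow(X)
  fold_id <- make_folds(n, folds, seed)
  raw <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- xgb_fit(X[tr, , drop = FALSE], treatment[tr], "binary:logistic",
                   control = control)
    raw[!tr] <- predict(fit, X[!tr, , drop = FALSE])
  }
  score <- clip01(raw)
  slope <- tryCatch({
    co <- coef(glm(treatment ~ qlogis(score), family = binomial()))
    unname(co[2])
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  structure(list(score = score, Z = Z, folds = folds,
                 calibration_slope = slope),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("<propensity_model> %d covariates, %d folds, calibration slope %.3f\n",
              length(x$Z), x$folds, x$calibration_slope))
  invisible(x)
}

#' Backdoor-adjusted treatment-effect model (R-learner ensemble)
#'
#' Estimates the conditional treatment effect tau(x) of a binary treatment
#' on a numeric outcome, adjusting for the covariates `Z`, with the
#' residual-on-residual (R-learner) recipe:
#'
#' 1. cross-fitted propensity scores `e(z)` ([estimate_propensity()]);
#' 2. cross-fitted per-arm outcome models, each arm trained with
#'    inverse-propensity weights, combined into the marginal outcome model
#'    `m(x) = e(x) mu1(x) + (1 - e(x)) mu0(x)`;
#' 3. the effect model minimizes the R-loss
#'    `sum[((Y - m) - tau(X) (T - e))^2]`, fitted as a weighted regression
#'    of the pseudo-outcome `(Y - m)/(T - e)` with weights `(T - e)^2`;
#' 4. tau is the 10:1 convex combination (10/11 gradient-boosted trees,
#'    1/11 random forest) of the two component effect learners; a
#'    `"constant"` learner (the R-loss-minimizing constant) is available
#'    as the baseline.
#'
#' The ATE is the mean of tau over the cohort. A positivity warning fires
#' when more than 20% of the propensity scores sit at the clip bounds.
#'
#' @param cohort Data frame with the covariates.
#' @param treatment 0/1 indicator vector.
#' @param outcome Numeric outcome vector (class probability or label).
#' @param Z Covariate column names.
#' @param ensemble_weights Component weights, normalized internally
#'   (default `c(10, 1)`).
#' @param folds Cross-fitting folds (default 5).
#' @param seed Integer seed.
#' @param learner `"ensemble"` (default) or `"constant"`.
#' @param control Learner settings ([meta_learner_control()]).
#' @return A `treatment_effect_model` with `tau` (per-record effects),
#'   `ate`, residuals and nuisance fits.
#' @export
fit_meta_learner <- function(cohort, treatment, outcome, Z,
                             ensemble_weights = c(10, 1), folds = 5, seed = 1,
                             learner = c("ensemble", "constant"),
                             control = meta_learner_control()) {
  learner <- match.arg(learner)
  if (!is.numeric(outcome)) abort("outcome must be numeric")
  t_ <- as.numeric(treatment)
  if (!all(t_ %in% c(0, 1))) abort("treatment must be binary 0/1")
  X <- as.matrix(cohort[Z])
  n <- nrow(X)
  prop <- estimate_propensity(cohort, t_, Z, folds = folds, seed = seed,
                              control = control)
  e <- prop$score
  if (mean(e <= 0.01 | e >= 0.99) > 0.2) {
    warn("positivity violation: > 20% of propensity scores at the clip bounds")
  }
  fold_id <- make_folds(n, folds, seed + 1)
  mu1 <- numeric(n); mu0 <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    i1 <- tr & t_ == 1
    i0 <- tr & t_ == 0
    f1 <- xgb_fit(X[i1, , drop = FALSE], outcome[i1], "reg:squarederror",
                  weight = 1 / e[i1], control = control)
    f0 <- xgb_fit(X[i0, , drop = FALSE], outcome[i0], "reg:squarederror",
                  weight = 1 / (1 - e[i0]), control = control)
    mu1[!tr] <- predict(f1, X[!tr, , drop = FALSE])
    mu0[!tr] <- predict(f0, X[!tr, , drop = FALSE])
  }
  m_hat <- e * mu1 + (1 - e) * mu0
  ry <- outcome - m_hat
  rt <- t_ - e
  w <- rt^2
  pseudo <- ry / rt
  const_tau <- sum(w * pseudo) / sum(w)  # R-loss-minimizing constant
  if (learner == "constant") {
    tau <- rep(const_tau, n)
    weights_norm <- NULL
  } else {
    weights_norm <- ensemble_weights / sum(ensemble_weights)
    set.seed(seed + 2)
    gb <- xgb_fit(X, pseudo, "reg:squarederror", weight = w, control = control)
    df <- as.data.frame(X)
    df$.pseudo <- pseudo
    rf <- ranger::ranger(
      dependent.variable.name = ".pseudo", data = df, case.weights = w,
      num.trees = control$num_trees, min.node.size = control$min_node_size,
      seed = seed + 2, num.threads = 1
    )
    tau <- weights_norm[1] * predict(gb, X) +
      weights_norm[2] * predict(rf, df)$predictions
  }
  structure(
    list(tau = tau, ate = mean(tau), constant_tau = const_tau,
         residual_y = ry, residual_t = rt, m_hat = m_hat,
         mu1 = mu1, mu0 = mu0, propensity = prop,
         ensemble_weights = weights_norm, learner = learner,
         Z = Z, folds = folds, fold_id = fold_id, seed = seed),
    class = "treatment_effect_model"
  )
}

#' @export
print.treatment_effect_model <- function(x, ...) {
  cat(sprintf("<treatment_effect_model> %s learner, ATE = %.4f (n = %d)\n",
              x$learner, x$ate, length(x$tau)))
  invisible(x)
}

#' @export
glance.treatment_effect_model <- function(x, ...) {
  tibble(ate = x$ate, learner = x$learner, n = length(x$tau),
         folds = x$folds, r_score = r_score(x)$r_score)
}

#' @export
tidy.treatment_effect_model <- function(x, ...) {
  tibble(record = seq_along(x$tau), tau = x$tau,
         residual_y = x$residual_y, residual_t = x$residual_t)
}

#' R score of a treatment-effect model
#'
#' `R score = 1 - L_R / L_base`, where `L_R` is the cross-validated R-loss
#' `mean[((Y - m) - tau(X)(T - e))^2]` of the fitted effect model and
#' `L_base` the same loss with tau replaced by the constant effect that
#' minimizes it (the cross-fitted ATE in the R-learner sense). Zero means
#' no improvement over a constant effect; positive values measure how much
#' effect heterogeneity the model explains; the constant model scores
#' exactly zero by construction.
#'
#' @param effect_model A `treatment_effect_model`.
#' @param folds Evaluation folds (default: the model's own cross-fitting
#'   folds, whose held-out residuals are reused).
#' @return One-row tibble: `r_loss`, `baseline_loss`, `r_score`, `folds`.
#' @export
r_score <- function(effect_model, folds = NULL) {
  ry <- effect_model$residual_y
  rt <- effect_model$residual_t
  tau <- effect_model$tau
  w <- rt^2
  const_tau <- sum(w * (ry / rt)) / sum(w)
  l_r <- mean((ry - tau * rt)^2)
  l_base <- mean((ry - const_tau * rt)^2)
  if (l_base == 0) abort("baseline loss is zero: R score undefined")
  tibble(r_loss = l_r, baseline_loss = l_base,
         r_score = 1 - l_r / l_base,
         folds = folds %||% effect_model$folds)
}

#' Attribution curve for a confounded unit
#'
#' The unit's values are discretized into ordered bins; for every adjacent
#' bin pair the records falling in either bin form a two-arm cohort with
#' treatment = membership in the upper bin, outcome = the classifier's
#' class probability, and adjustment set = the unit's backdoor set in the
#' causal graph (its parents). The meta-learner ATE of each pair is the
#' per-interval ACE; the reported curve starts from a 0 benchmark and adds
#' each interval's effect cumulatively, tracing how the output neuron
#' value moves across the unit's range.
#'
#' @param model An `fnn_classifier`.
#' @param cohort Cohort data frame.
#' @param g Finalized `causal_graph` over the features (the outcome node
#'   is appended internally as a child of CR when absent).
#' @param unit Confounded unit name.
#' @param binning A [discretize()] result for the unit's values, or `NULL`
#'   to build one.
#' @param strategy,k Used when `binning` is `NULL`.
#' @param class_label `"Yes"` (myopic, default) or `"No"`.
#' @param outcome Outcome node name.
#' @param check Refuse units that do not classify as Confounded.
#' @param folds,seed,control Meta-learner settings.
#' @return A `confounded_curve` tibble: `pair`, `bin_low`, `bin_high`,
#'   `ace`, `cumulative`, `n_pair`, `class`; attribute `binning`.
#' @export
ace_confounded <- function(model, cohort, g, unit, binning = NULL,
                           strategy = "equal_width", k = 10,
                           class_label = c("Yes", "No"), outcome = "Myopia",
                           check = TRUE, folds = 5, seed = 1,
                           control = meta_learner_control()) {
  class_label <- match.arg(class_label)
  if (check) {
    cat_ <- classify_units(g, setdiff(g$nodes, outcome))
    kk <- cat_$category[cat_$unit == unit]
    if (length(kk) && kk != "Confounded") {
      abort(sprintf("unit '%s' is %s, not Confounded", unit, as.character(kk)))
    }
  }
  binning <- binning %||% discretize(cohort[[unit]], strategy, k)
  ga <- if (outcome %in% g$nodes) g else {
    causal_graph(c(g$nodes, outcome),
                 dplyr::bind_rows(g$edges,
                                  tibble(from = "CR", to = outcome, directed = TRUE)))
  }
  Z <- as.character(backdoor_set(ga, unit, outcome))
  if (!length(Z)) abort("confounded unit has an empty backdoor set")
  y_all <- predict_proba(model, cohort)[[class_label]]
  bins <- binning$assignment
  rows <- purrr::map_dfr(seq_len(binning$k - 1), function(j) {
    sel <- bins %in% c(j, j + 1)
    if (sum(bins == j) == 0 || sum(bins == j + 1) == 0) {
      abort(sprintf("empty adjacent bin pair (%d, %d)", j, j + 1))
    }
    fit <- fit_meta_learner(cohort[sel, ], as.numeric(bins[sel] == j + 1),
                            y_all[sel], Z, folds = folds, seed = seed + j,
                            control = control)
    tibble(pair = j, bin_low = binning$edges[j], bin_high = binning$edges[j + 2],
           ace = fit$ate, n_pair = sum(sel))
  })
  rows$cumulative <- cumsum(rows$ace)
  rows$class <- class_label
  structure(rows, class = c("confounded_curve", class(rows)),
            unit = unit, binning = binning)
}

#' Plot a confounded-unit attribution curve
#'
#' Per-interval ACE bars plus the cumulative output-neuron trajectory
#' benchmarked at zero.
#'
#' @param object A `confounded_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confounded_curve <- function(object, ...) {
  mid <- (object$bin_low + object$bin_high) / 2
  df <- tibble(mid = mid, ace = object$ace, cumulative = object$cumulative)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$ace), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::labs(x = attr(object, "unit"),
                  y = "ACE per interval / cumulative output value") +
    ggplot2::theme_minimal()
}

#' Write a confounded-unit curve as CSV
#'
#' @param curve A `confounded_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confounded_csv <- function(curve, path) {
  readr::write_csv(as_tibble(curve), path)
  invisible(path)
}
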