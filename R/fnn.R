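relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

fnn_forward <- function(model, Xstd, keep = FALSE) {
  w <- model$weights
  z1 <- sweep(Xstd %*% w$W1, 2, w$b1, "+")
  a1 <- relu(z1)
  z2 <- sweep(a1 %*% w$W2, 2, w$b2, "+")
  a2 <- relu(z2)
  z3 <- sweep(a2 %*% w$W3, 2, w$b3, "+")
  p <- softmax_rows(z3)
  if (keep) list(p = p, z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3) else p
}

standardize_features <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, "/")
}

#' Train the 16-12-8-2 feedforward myopia classifier
#'
#' A four-layer fully connected network: input units for each feature, two
#' ReLU hidden layers of 12 and 8 neurons, and a 2-unit softmax output
#' (class 1 = "No" non-myopic, class 2 = "Yes" myopic). Trained by
#' mini-batch stochastic gradient descent on the cross-entropy loss, with
#' inputs standardized by training-set mean and SD. A fixed seed fixes the
#' weight initialization and batch order, so training is reproducible.
#'
#' @param cohort Data frame with feature columns and a binary outcome.
#' @param outcome Outcome column name (default `"Myopia"`).
#' @param features Feature column names (default: all but the outcome).
#' @param hidden Hidden layer sizes (default `c(12, 8)`).
#' @param lr Learning rate (default 0.01).
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Training epochs (default 200).
#' @param seed Integer seed (default 1).
#' @return An `fnn_classifier`: layer weights, standardization constants,
#'   `feature_order`, and a per-epoch `loss_log`.
#' @examples
#' cohort <- generate_cohort(default_myopia_scm(), 300, seed = 1)
#' model <- train_fnn(cohort, epochs = 5)
#' @export
train_fnn <- function(cohort, outcome = "Myopia",
                      features = setdiff(names(cohort), outcome),
                      hidden = c(12, 8), lr = 0.01, batch_size = 32,
                      epochs = 200, seed = 1) {
  y <- cohort[[outcome]]
  if (length(unique(y)) < 2) abort("cohort must contain both outcome classes")
  X <- as.matrix(cohort[features])
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0] <- 1
  Xs <- standardize_features(X, center, scale)
  n <- nrow(Xs)
  d <- ncol(Xs)
  Y <- cbind(1 - y, y)  # columns: No, Yes
  set.seed(seed)
  he <- function(fi, fo) matrix(rnorm(fi * fo, 0, sqrt(2 / fi)), fi, fo)
  w <- list(W1 = he(d, hidden[1]), b1 = rep(0, hidden[1]),
            W2 = he(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
            W3 = he(hidden[2], 2), b3 = rep(0, 2))
  model <- list(weights = w)
  loss_log <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, n, by = batch_size)) {
      rows <- idx[start:min(start + batch_size - 1, n)]
      Xb <- Xs[rows, , drop = FALSE]
      Yb <- Y[rows, , drop = FALSE]
      fw <- fnn_forward(model, Xb, keep = TRUE)
      m <- nrow(Xb)
      loss <- -mean(rowSums(Yb * log(pmax(fw$p, 1e-12))))
      if (!is.finite(loss)) abort("NaN loss encountered during training")
      ep_loss <- ep_loss + loss
      nb <- nb + 1L
      dz3 <- (fw$p - Yb) / m
      gW3 <- crossprod(fw$a2, dz3); gb3 <- colSums(dz3)
      da2 <- dz3 %*% t(model$weights$W3)
      dz2 <- da2 * (fw$z2 > 0)
      gW2 <- crossprod(fw$a1, dz2); gb2 <- colSums(dz2)
      da1 <- dz2 %*% t(model$weights$W2)
      dz1 <- da1 * (fw$z1 > 0)
      gW1 <- crossprod(Xb, dz1); gb1 <- colSums(dz1)
      model$weights$W3 <- model$weights$W3 - lr * gW3
      model$weights$b3 <- model$weights$b3 - lr * gb3
      model$weights$W2 <- model$weights$W2 - lr * gW2
      model$weights$b2 <- model$weights$b2 - lr * gb2
      model$weights$W1 <- model$weights$W1 - lr * gW1
      model$weights$b1 <- model$weights$b1 - lr * gb1
    }
    loss_log[ep] <- ep_loss / nb
  }
  model$weights <- lapply(model$weights, function(w) {
    if (is.matrix(w)) unname(w) else unname(as.numeric(w))
  })
  structure(
    list(weights = model$weights, feature_order = features,
         center = center, scale = scale,
         hidden = hidden, classes = c("No", "Yes"),
         hyper = list(lr = lr, batch_size = batch_size, epochs = epochs, seed = seed),
         loss_log = loss_log),
    class = "fnn_classifier"
  )
}

#' @export
print.fnn_classifier <- function(x, ...) {
  cat(sprintf("<fnn_classifier> %d-%s-2 ReLU/softmax, trained %d epochs (final loss %.4f)\n",
              length(x$feature_order), paste(x$hidden, collapse = "-"),
              length(x$loss_log), tail(x$loss_log, 1)))
  invisible(x)
}

#' Class probabilities of the classifier
#'
#' Softmax outputs of the network for each record; the two columns sum to 1.
#'
#' @param model An `fnn_classifier`.
#' @param newdata Data frame (or matrix) containing the model's features in
#'   any column order; extra columns are ignored.
#' @return A tibble with columns `No` and `Yes`.
#' @export
predict_proba <- function(model, newdata) {
  X <- as.matrix(as.data.frame(newdata)[model$feature_order])
  if (ncol(X) != length(model$feature_order)) abort("wrong feature arity")
  p <- fnn_forward(model, standardize_features(X, model$center, model$scale))
  tibble(No = p[, 1], Yes = p[, 2])
}

#' @export
predict.fnn_classifier <- function(object, newdata, type = c("prob", "class"), ...) {
  p <- predict_proba(object, newdata)
  if (match.arg(type) == "prob") p else as.integer(p$Yes >= 0.5)
}

# ---- value / gradient / Hessian on the standardized input scale ----------

model_value <- function(model, x_std, class_index) UseMethod("model_value")

#' @export
model_value.fnn_classifier <- function(model, x_std, class_index) {
  if (identical(model$output_mode, "logit")) {
    fw <- fnn_forward(model, matrix(x_std, nrow = 1), keep = TRUE)
    return(fw$z3[1, class_index])
  }
  fnn_forward(model, matrix(x_std, nrow = 1))[1, class_index]
}

model_hessian <- function(model, x_std, class_index, ...) UseMethod("model_hessian")

nudge_off_kink <- function(model, x_std, tol = 1e-8, bump = 1e-6) {
  fw <- fnn_forward(model, matrix(x_std, nrow = 1), keep = TRUE)
  if (any(abs(fw$z1) < tol) || any(abs(fw$z2) < tol)) {
    warn("evaluation point lies on a ReLU kink; perturbing by 1e-6")
    x_std <- x_std + bump
    fw <- fnn_forward(model, matrix(x_std, nrow = 1), keep = TRUE)
  }
  list(x = x_std, fw = fw)
}

softmax_hessian_z <- function(p, k) {
  # d^2 p_k / dz_i dz_j for softmax probabilities p
  m <- length(p)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    D[i, j] <- p[k] * (((i == k) - p[i]) * ((j == k) - p[j]) -
                         p[i] * ((i == j) - p[j]))
  }
  D
}

#' @export
model_hessian.fnn_classifier <- function(model, x_std, class_index,
                                         method = c("analytic", "fd"),
                                         step = 1e-3, ...) {
  method <- match.arg(method)
  if (method == "fd") {
    f <- function(x) model_value(model, x, class_index)
    return(fd_hessian(f, x_std, step = step))
  }
  nk <- nudge_off_kink(model, x_std)
  fw <- nk$fw
  w <- model$weights
  d <- length(x_std)
  if (identical(model$output_mode, "logit")) {
    # logits are piecewise linear in the input: zero curvature off-kink
    return(matrix(0, d, d))
  }
  m1 <- as.numeric(fw$z1 > 0)
  m2 <- as.numeric(fw$z2 > 0)
  # Jacobian of the logits wrt the (standardized) input: 2 x d
  J <- t(w$W3 * m2) %*% (t(w$W2 * m1)) %*% t(w$W1)
  p <- fw$p[1, ]
  D <- softmax_hessian_z(p, class_index)
  H <- t(J) %*% D %*% J
  (H + t(H)) / 2
}

model_gradient <- function(model, x_std, class_index) {
  nk <- nudge_off_kink(model, x_std)
  fw <- nk$fw
  w <- model$weights
  m1 <- as.numeric(fw$z1 > 0)
  m2 <- as.numeric(fw$z2 > 0)
  J <- t(w$W3 * m2) %*% (t(w$W2 * m1)) %*% t(w$W1)
  p <- fw$p[1, ]
  dp_dz <- p[class_index] * ((seq_along(p) == class_index) - p)
  as.numeric(t(J) %*% dp_dz)
}

#' Central finite-difference Hessian
#'
#' Symmetric second-derivative matrix of a scalar function by central
#' differences with step `step` per coordinate; used as the independent
#' cross-check of the analytic network Hessian.
#'
#' @param f Function taking a numeric vector, returning a scalar.
#' @param x Evaluation point.
#' @param step Difference step (default 1e-3).
#' @return Symmetric matrix `length(x)` square.
#' @export
fd_hessian <- function(f, x, step = 1e-3) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, step)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / step^2
    for (j in seq_len(d)) {
      if (j <= i) next
      ej <- replace(numeric(d), j, step)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * step^2)
    }
  }
  (H + t(H)) / 2
}

#' Hessian of a class-probability output
#'
#' Second derivative matrix of the chosen class probability with respect to
#' the standardized inputs, either analytically (exact away from ReLU
#' kinks: the hidden stack is locally linear, so the curvature comes from
#' the softmax alone) or by central finite differences. Points on a kink
#' are perturbed by 1e-6 with a warning.
#'
#' @param model An `fnn_classifier`.
#' @param point Numeric vector on the standardized input scale.
#' @param class_index 1 ("No") or 2 ("Yes").
#' @param method `"analytic"` or `"fd"`.
#' @param step Finite-difference step.
#' @return Symmetric matrix.
#' @export
output_hessian <- function(model, point, class_index = 2,
                           method = c("analytic", "fd"), step = 1e-3) {
  if (any(!is.finite(point))) abort("point must be finite")
  model_hessian(model, point, class_index, method = match.arg(method), step = step)
}

# ---- evaluation -----------------------------------------------------------

#' Confusion-matrix metrics and AUC
#'
#' Accuracy, sensitivity (myopic recall), specificity, F1 of the positive
#' class at a 0.5 probability threshold, plus rank-statistic AUC. A
#' single-class test set leaves AUC `NA` with a warning.
#'
#' @param model An `fnn_classifier`.
#' @param cohort Test cohort with the outcome column.
#' @param outcome Outcome column name.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   `auc`, `n`.
#' @export
evaluate_fnn <- function(model, cohort, outcome = "Myopia") {
  if (nrow(cohort) == 0) abort("test cohort is empty")
  y <- cohort[[outcome]]
  p <- predict_proba(model, cohort)$Yes
  yhat <- as.integer(p >= 0.5)
  tp <- sum(yhat == 1 & y == 1); tn <- sum(yhat == 0 & y == 0)
  fp <- sum(yhat == 1 & y == 0); fn <- sum(yhat == 0 & y == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else NA_real_
  auc <- if (length(unique(y)) < 2) {
    warn("single-class test set: AUC undefined")
    NA_real_
  } else {
    as.numeric(pROC::auc(y, p, quiet = TRUE, direction = "<"))
  }
  tibble(
    accuracy = (tp + tn) / length(y),
    sensitivity = rec,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = f1, auc = auc, n = length(y)
  )
}

#' Repeated-split performance summary
#'
#' Trains and evaluates the classifier on `splits` random 80/20
#' train/test partitions and reports each metric as mean and SD, the usual
#' mean-plus-minus-SD presentation for small tabular cohorts.
#'
#' @param cohort Cohort data frame.
#' @param splits Number of random splits (default 5).
#' @param seed Integer seed.
#' @param outcome Outcome column name.
#' @param ... Passed to [train_fnn()].
#' @return Tibble with `metric`, `mean`, `sd`.
#' @export
fnn_metrics_splits <- function(cohort, splits = 5, seed = 1,
                               outcome = "Myopia", ...) {
  set.seed(seed)
  split_idx <- purrr::map(seq_len(splits), function(s) {
    sample.int(nrow(cohort), floor(0.8 * nrow(cohort)))
  })
  rows <- purrr::map_dfr(seq_len(splits), function(s) {
    idx <- split_idx[[s]]
    model <- train_fnn(cohort[idx, ], outcome = outcome, seed = seed + s, ...)
    evaluate_fnn(model, cohort[-idx, ], outcome = outcome)
  })
  rows %>%
    dplyr::select(-dplyr::all_of("n")) %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") %>%
    dplyr::group_by(.data$metric) %>%
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")
}

#' @export
glance.fnn_classifier <- function(x, ...) {
  tibble(
    n_features = length(x$feature_order),
    hidden = paste(x$hidden, collapse = "-"),
    epochs = x$hyper$epochs,
    lr = x$hyper$lr,
    batch_size = x$hyper$batch_size,
    final_loss = tail(x$loss_log, 1)
  )
}

#' @export
tidy.fnn_classifier <- function(x, ...) {
  purrr::imap_dfr(x$weights[c("W1", "W2", "W3")], function(W, nm) {
    tibble(layer = nm, rows = nrow(W), cols = ncol(W),
           mean_abs_weight = mean(abs(W)), max_abs_weight = max(abs(W)))
  })
}

# ---- serialization --------------------------------------------------------

#' Read and write classifiers as JSON weight files
#'
#' The file records layer shapes, weights, biases, feature order and the
#' standardization constants, so a model round-trips exactly.
#'
#' @param model An `fnn_classifier`.
#' @param path File path.
#' @return `write_fnn()` returns `path` invisibly; `read_fnn()` the model.
#' @export
write_fnn <- function(model, path) {
  obj <- list(
    feature_order = model$feature_order,
    center = as.list(model$center), scale = as.list(model$scale),
    hidden = model$hidden, classes = model$classes, hyper = model$hyper,
    loss_log = model$loss_log,
    weights = lapply(model$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w)) else list(dim = length(w), data = as.numeric(w))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fnn
#' @export
read_fnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(obj$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2]) else as.numeric(w$data)
  })
  structure(
    list(weights = weights, feature_order = obj$feature_order,
         center = setNames(unlist(obj$center), obj$feature_order),
         scale = setNames(unlist(obj$scale), obj$feature_order),
         hidden = obj$hidden, classes = obj$classes, hyper = obj$hyper,
         loss_log = obj$loss_log),
    class = "fnn_classifier"
  )
}

# ---- linear surrogate (diagnostics / oracle checks) -----------------------

#' Linear surrogate model
#'
#' A deliberately simple differentiable "model" `f(x) = w'x + b` exposing
#' the same value/Hessian interface as the network. Its Hessian is exactly
#' zero, which makes it the closed-form reference for the Taylor
#' intervention expectation and for attribution linearity checks.
#'
#' @param w Weight vector (one per feature).
#' @param b Intercept.
#' @param feature_order Optional feature names.
#' @return A `linear_surrogate` object.
#' @export
linear_surrogate <- function(w, b = 0, feature_order = names(w)) {
  structure(list(w = as.numeric(w), b = b,
                 feature_order = feature_order %||% paste0("x", seq_along(w))),
            class = "linear_surrogate")
}

#' @export
model_value.linear_surrogate <- function(model, x_std, class_index) {
  sum(model$w * x_std) + model$b
}

#' @export
model_hessian.linear_surrogate <- function(model, x_std, class_index, ...) {
  matrix(0, length(model$w), length(model$w))
}

#' Quadratic surrogate model
#'
#' `f(x) = x' Q x + w' x + b`, with exact constant Hessian `Q + Q'`. The
#' second-order Taylor intervention expectation is exact for this model
#' (`E[f] = f(mu) + 0.5 tr((Q + Q') Sigma)`), which makes it the
#' closed-form reference complementing [linear_surrogate()].
#'
#' @param Q Square coefficient matrix.
#' @param w Linear term (default zero).
#' @param b Intercept.
#' @param feature_order Optional feature names.
#' @return A `quadratic_surrogate` object.
#' @export
quadratic_surrogate <- function(Q, w = rep(0, nrow(Q)), b = 0,
                                feature_order = NULL) {
  structure(list(Q = Q, w = as.numeric(w), b = b,
                 feature_order = feature_order %||% paste0("x", seq_len(nrow(Q)))),
            class = "quadratic_surrogate")
}

#' @export
model_value.quadratic_surrogate <- function(model, x_std, class_index) {
  as.numeric(t(x_std) %*% model$Q %*% x_std + sum(model$w * x_std) + model$b)
}

#' @export
model_hessian.quadratic_surrogate <- function(model, x_std, class_index, ...) {
  model$Q + t(model$Q)
}

#' Kink margin of a network at a point
#'
#' Distance of every hidden pre-activation from its ReLU kink, in standard
#' deviations of the perturbation that a covariance implies at that layer
#' (linearized through the active path). The Taylor intervention
#' approximation is only second-order accurate while the perturbation is
#' unlikely to cross a kink; a margin of 4 or more keeps the crossing
#' probability negligible, so scaling the covariance by
#' `(margin / 4)^2` when the margin is smaller places the summary in the
#' second-order regime.
#'
#' @param model An `fnn_classifier`.
#' @param point Evaluation point on the standardized scale.
#' @param Sigma Input covariance matrix.
#' @return The minimum margin (scalar).
#' @export
kink_margin <- function(model, point, Sigma) {
  w <- model$weights
  fw <- fnn_forward(model, matrix(point, 1), keep = TRUE)
  J1 <- t(w$W1)
  sd1 <- sqrt(pmax(rowSums((J1 %*% Sigma) * J1), 1e-12))
  J2 <- t(w$W2 * as.numeric(fw$z1 > 0)) %*% J1
  sd2 <- sqrt(pmax(rowSums((J2 %*% Sigma) * J2), 1e-12))
  min(abs(fw$z1) / sd1, abs(fw$z2) / sd2)
}

#' Switch a classifier between probability and logit output
#'
#' Attribution uses the post-softmax class probability by default. For
#' analyses on the pre-softmax scale, `output_mode(model, "logit")`
#' returns a copy whose value/Hessian interface exposes the class logit
#' instead. Logits of a ReLU network are piecewise linear, so their
#' Hessian is exactly zero away from kinks and the Taylor intervention
#' expectation reduces to the logit at the intervened mean.
#'
#' @param model An `fnn_classifier`.
#' @param mode `"probability"` (default) or `"logit"`.
#' @return The model with the requested output mode.
#' @export
output_mode <- function(model, mode = c("probability", "logit")) {
  model$output_mode <- match.arg(mode)
  model
}
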