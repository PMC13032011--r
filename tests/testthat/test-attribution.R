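test_that("gaussian summaries are symmetric and recover iid structure", {
  set.seed(1)
  d <- tibble::as_tibble(matrix(rnorm(20000 * 4), ncol = 4,
                                dimnames = list(NULL, paste0("x", 1:4))))
  s <- fit_gaussian_summary(d, features = paste0("x", 1:4))
  expect_identical(s$cov, t(s$cov))
  expect_lt(max(abs(s$cov[upper.tri(s$cov)])), 0.05)
  expect_equal(unname(diag(s$cov)), rep(1, 4), tolerance = 0.05)
  dd <- d
  dd$x4 <- 1
  expect_warning(fit_gaussian_summary(dd, features = paste0("x", 1:4)),
                 "constant")
})

test_that("do-interventions pin the unit and keep the summary PSD", {
  set.seed(2)
  d <- tibble::as_tibble(matrix(rnorm(500 * 3), ncol = 3,
                                dimnames = list(NULL, c("a", "b", "c"))))
  d$b <- d$a + d$b
  s <- fit_gaussian_summary(d, features = c("a", "b", "c"))
  si <- intervene_summary(s, "a", 2)
  i <- match("a", s$features)
  expect_equal(si$cov[i, i], 0)
  expect_true(all(si$cov[i, ] == 0) && all(si$cov[, i] == 0))
  expect_equal(si$mean[[i]], unitcausal:::to_std(s, "a", 2))
  for (rep in 1:10) {
    alpha <- rnorm(1, 0, 3)
    si <- intervene_summary(s, sample(c("a", "b", "c"), 1), alpha)
    expect_gte(min(eigen(si$cov, symmetric = TRUE, only.values = TRUE)$values),
               -1e-9)
  }
})

test_that("pure-mode intervention shifts downstream means by the path product", {
  g <- causal_graph(c("A", "B"), data.frame(from = "A", to = "B"))
  b_coef <- 1.7
  set.seed(3)
  a <- rnorm(4000)
  d <- tibble::tibble(A = a, B = b_coef * a + rnorm(4000, sd = 0.3))
  s <- fit_gaussian_summary(d, features = c("A", "B"))
  coeffs <- tibble::tibble(from = "A", to = "B", coef = b_coef)
  alpha <- 2.5
  si <- intervene_summary(s, "A", alpha, graph = g, coeffs = coeffs)
  # E[B | do(A = alpha)] shifts by coef * (alpha - mean(A)) on the raw scale
  raw_shift <- b_coef * (alpha - mean(d$A))
  expect_equal((si$mean[["B"]] - s$mean[["B"]]) * s$scale[["B"]], raw_shift,
               tolerance = 1e-9)
  # mediator variance drops by the share explained through A
  expect_lt(si$cov["B", "B"], s$cov["B", "B"])
})

test_that("the Taylor expectation has its closed-form special cases", {
  # linear output: trace term vanishes exactly
  lin <- linear_surrogate(c(0.5, -1, 2), b = 0.3,
                          feature_order = c("a", "b", "c"))
  s <- list(mean = c(a = 1, b = 2, c = -1),
            cov = diag(c(1, 4, 9)), features = c("a", "b", "c"),
            center = c(a = 0, b = 0, c = 0), scale = c(a = 1, b = 1, c = 1))
  class(s) <- "gaussian_summary"
  expect_equal(taylor_expectation(lin, s, 1),
               sum(c(0.5, -1, 2) * c(1, 2, -1)) + 0.3, tolerance = 1e-12)
  # quadratic: E[x^2] = mu^2 + sigma^2, exact under the second-order formula
  quad <- quadratic_surrogate(matrix(1, 1, 1), feature_order = "x")
  sq <- structure(list(mean = c(x = 0), cov = matrix(2^2, 1, 1),
                       features = "x", center = c(x = 0), scale = c(x = 1)),
                  class = "gaussian_summary")
  expect_equal(taylor_expectation(quad, sq, 1), 4, tolerance = 1e-12)
  sq$mean <- c(x = 1.5)
  expect_equal(taylor_expectation(quad, sq, 1), 1.5^2 + 4, tolerance = 1e-12)
})

test_that("the Taylor expectation matches a Monte-Carlo oracle on random nets", {
  # second-order regime: covariance scaled so the perturbation stays at
  # least 4 SDs away from every ReLU kink (see kink_margin)
  for (s in 1:8) {
    m <- make_random_fnn(d = 8, seed = 500 + s)
    set.seed(600 + s)
    mu <- rnorm(8, 0, 0.5)
    A <- matrix(rnorm(64, 0, 0.3), 8, 8)
    Sigma <- 0.1 * (crossprod(A) / 8 + diag(0.05, 8))
    margin <- kink_margin(m, mu, Sigma)
    if (margin < 4) Sigma <- Sigma * (margin / 4)^2
    summ <- structure(list(mean = setNames(mu, m$feature_order), cov = Sigma,
                           features = m$feature_order,
                           center = m$center, scale = m$scale),
                      class = "gaussian_summary")
    approx <- taylor_expectation(m, summ, 2)
    L <- chol(Sigma)
    draws <- 1e5
    Z <- matrix(rnorm(draws * 8), draws, 8) %*% L
    X <- sweep(Z, 2, mu, "+")
    colnames(X) <- m$feature_order
    vals <- predict_proba(m, as.data.frame(X))$Yes
    mc <- mean(vals)
    se <- sd(vals) / sqrt(draws)
    expect_lt(abs(approx - mc), 3 * se + 1e-6,
              label = sprintf("net %d Taylor vs MC deviation", s))
  }
})

test_that("isolated-unit curves: binary contrast, null model, monotone toy net", {
  # binary unit: the two-point grid reports E[do(1)] - E[do(0)]
  lin <- linear_surrogate(c(2, 1), feature_order = c("t", "z"))
  s <- structure(list(mean = c(t = 0.4, z = 0), cov = diag(2),
                      features = c("t", "z"), center = c(t = 0, z = 0),
                      scale = c(t = 1, z = 1)),
                 class = "gaussian_summary")
  grid <- list(unit = "t", low = 0, high = 1, num = 2L, alphas = c(0, 1))
  curve <- ace_isolated(lin, s, grid)
  expect_equal(unname(ace(curve)["No"]), 2, tolerance = 1e-9)
  # model ignoring the unit: centered curve identically zero
  lin0 <- linear_surrogate(c(0, 1), feature_order = c("t", "z"))
  grid10 <- list(unit = "t", low = -1, high = 1, num = 10L,
                 alphas = seq(-1, 1, length.out = 10))
  c0 <- ace_isolated(lin0, s, grid10)
  expect_lt(max(abs(c0$centered)), 1e-9)
  # monotone toy network: Yes curve nondecreasing, No curve nonincreasing
  m <- make_random_fnn(d = 1, seed = 1)
  m$weights$W1 <- matrix(1, 1, 12); m$weights$b1 <- rep(0.5, 12)
  m$weights$W2 <- matrix(0.3, 12, 8); m$weights$b2 <- rep(0.1, 8)
  m$weights$W3 <- cbind(rep(-0.4, 8), rep(0.4, 8)); m$weights$b3 <- c(0, 0)
  sm <- structure(list(mean = c(x1 = 0), cov = matrix(0.2, 1, 1),
                       features = "x1", center = c(x1 = 0), scale = c(x1 = 1)),
                  class = "gaussian_summary")
  gr <- list(unit = "x1", low = -2, high = 2, num = 10L,
             alphas = seq(-2, 2, length.out = 10))
  cm <- ace_isolated(m, sm, gr)
  yes <- cm$expectation[cm$class == "Yes"]
  no <- cm$expectation[cm$class == "No"]
  expect_true(all(diff(yes) >= -1e-9))
  expect_true(all(diff(no) <= 1e-9))
  # two-class curves mirror: expectations sum to 1 at every alpha
  expect_lt(max(abs(yes + no - 1)), 1e-9)
})

test_that("curves are mean-centered and refuse mismatched units", {
  co <- generate_cohort(default_myopia_scm(), 1500, seed = 20)
  model <- train_fnn(co, epochs = 5, seed = 1)
  summ <- fit_gaussian_summary(co, model)
  g <- myopia_reference_graph()
  grid <- intervention_grid(co, "PULSE")
  curve <- ace_isolated(model, summ, grid, graph = g)
  cent <- tapply(curve$centered, curve$class, sum)
  expect_lt(max(abs(cent)), 1e-9)
  expect_error(ace_isolated(model, summ, intervention_grid(co, "AL"), graph = g),
               "Confounded")
  expect_error(ace_pure(model, co, g, intervention_grid(co, "NW")), "Isolated")
})

test_that("edge coefficients recover generator truth and exact linear systems", {
  scm <- default_myopia_scm()
  co <- generate_cohort(scm, 10000, seed = 21)
  est <- fit_edge_coefficients(co, scm$graph)
  truth <- scm$edge_coeff
  m <- merge(as.data.frame(est), as.data.frame(truth), by = c("from", "to"))
  fit <- lm(AL ~ PWG + GENDER + NAR + DAR + K1 + K2 + HEIGHT + REDM, data = co)
  se_max <- max(summary(fit)$coefficients[-1, "Std. Error"])
  ses <- summary(lm(CR ~ AL + PWG + GENDER + NAR + DAR + K1 + K2, data = co))
  se_max <- max(se_max, ses$coefficients[-1, "Std. Error"])
  expect_lt(max(abs(m$coef.x - m$coef.y)), 5 * se_max)
  # noise-free linear data: exact recovery
  set.seed(22)
  a <- rnorm(200); b <- 2 * a; c_ <- -1.5 * b + a
  g <- causal_graph(c("a", "b", "c"),
                    data.frame(from = c("a", "b", "a"), to = c("b", "c", "c")))
  est2 <- suppressWarnings(fit_edge_coefficients(tibble::tibble(a = a, b = b, c = c_), g))
  expect_warning(
    est2b <- fit_edge_coefficients(tibble::tibble(a = a, b = b, c = c_), g),
    "collinear"
  )  # b is an exact multiple of a, the joint regression of c is collinear
  bc <- est2$coef[est2$from == "a" & est2$to == "b"]
  expect_equal(bc, 2, tolerance = 1e-8)
  # parentless nodes emit nothing
  expect_false("a" %in% est2$to)
})

test_that("path-sum total effects: product rule and two-path decomposition", {
  chain <- causal_graph(c("a", "b", "c"),
                        data.frame(from = c("a", "b"), to = c("b", "c")))
  coeffs <- tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                           coef = c(0.7, -1.2))
  res <- total_effect_pure(chain, coeffs, "a", "c")
  expect_equal(res$effect, 0.7 * -1.2, tolerance = 1e-12)
  expect_equal(nrow(res$paths), 1)
  # the published two-path shape: direct plus mediated
  g2 <- causal_graph(c("PWG", "AL", "CR"),
                     data.frame(from = c("PWG", "PWG", "AL"),
                                to = c("CR", "AL", "CR")))
  c2 <- tibble::tibble(from = c("PWG", "PWG", "AL"), to = c("CR", "AL", "CR"),
                       coef = c(-0.3, 0.4, -0.5))
  r2 <- total_effect_pure(g2, c2, "PWG", "CR")
  expect_equal(r2$effect, -0.3 + 0.4 * -0.5, tolerance = 1e-12)
  expect_equal(nrow(r2$paths), 2)
  # unreachable target: zero effect, empty path list
  r3 <- total_effect_pure(chain, coeffs, "c", "a")
  expect_equal(r3$effect, 0)
  expect_equal(nrow(r3$paths), 0)
})

test_that("path-sum equals backdoor-adjusted regression on random linear SCMs", {
  for (s in 1:6) {
    g <- random_dag(6, 0.45, seed = 700 + s)
    scm <- random_linear_scm(g, seed = 700 + s)
    d <- sample_linear_scm(scm, 20000, seed = 800 + s)
    ord <- topological_order(g)
    unit <- ord[1]; target <- ord[6]
    path_sum <- total_effect_pure(g, scm$coeffs, unit, target)$effect
    z <- as.character(suppressWarnings(backdoor_set(g, unit, target)))
    rhs <- paste(c(unit, z), collapse = " + ")
    fit <- lm(stats::as.formula(paste(target, "~", rhs)), data = d)
    se <- summary(fit)$coefficients[unit, "Std. Error"]
    expect_lt(abs(coef(fit)[[unit]] - path_sum), 3 * se + 1e-6,
              label = sprintf("seed %d: |path sum - adjusted slope|", s))
  }
})

test_that("pure-unit curves compose linearly and vanish without influence", {
  # model reads only the mediator; mediator fully determined by the unit
  g <- causal_graph(c("u", "m"), data.frame(from = "u", to = "m"))
  b <- 1.4
  set.seed(23)
  u <- rnorm(3000)
  d <- tibble::tibble(u = u, m = b * u)  # noise-free mediation
  lin <- linear_surrogate(c(0, 1), feature_order = c("u", "m"))
  coeffs <- tibble::tibble(from = "u", to = "m", coef = b)
  s <- fit_gaussian_summary(d, features = c("u", "m"))
  grid <- list(unit = "u", low = -1, high = 1, num = 10L,
               alphas = seq(-1, 1, length.out = 10))
  cp <- ace_pure(lin, d, g, grid, coeffs = coeffs, summary = s, check = FALSE)
  # equivalent route: intervene on the mediator directly at the induced grid
  grid_m <- list(unit = "m", low = -b, high = b, num = 10L,
                 alphas = b * grid$alphas)
  ci <- ace_isolated(lin, s, grid_m)
  expect_equal(cp$expectation, ci$expectation, tolerance = 1e-6)
  # zero path coefficients: flat centered curve
  cz <- ace_pure(lin, d, g, grid,
                 coeffs = tibble::tibble(from = "u", to = "m", coef = 0),
                 summary = s, check = FALSE)
  expect_lt(max(abs(cz$centered)), 1e-9)
  # linear model + linear SCM: curve affine in alpha
  resid_dev <- max(abs(residuals(lm(expectation ~ alpha,
                                    data = cp[cp$class == "No", ]))))
  expect_lt(resid_dev, 1e-6)
})

test_that("curve CSVs and plots are produced", {
  lin <- linear_surrogate(c(1, 0), feature_order = c("a", "b"))
  s <- structure(list(mean = c(a = 0, b = 0), cov = diag(2),
                      features = c("a", "b"), center = c(a = 0, b = 0),
                      scale = c(a = 1, b = 1)),
                 class = "gaussian_summary")
  grid <- list(unit = "a", low = 0, high = 1, num = 5L,
               alphas = seq(0, 1, length.out = 5))
  curve <- ace_isolated(lin, s, grid)
  f <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(curve, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(back), 5)
  expect_true(all(c("alpha", "expectation_no", "centered_yes") %in% names(back)))
  expect_s3_class(autoplot(curve), "ggplot")
})

test_that("pure-unit attribution runs on the myopia pipeline", {
  co <- generate_cohort(default_myopia_scm(), 3000, seed = 30)
  model <- train_fnn(co, epochs = 3, lr = 0.005, seed = 1)
  g <- myopia_reference_graph()
  grid <- intervention_grid(co, "HEIGHT")
  curve <- ace_pure(model, co, g, grid)
  expect_equal(nrow(curve), 20)  # 10 alphas x 2 classes
  expect_true(all(is.finite(curve$expectation)))
  cent <- tapply(curve$centered, curve$class, sum)
  expect_lt(max(abs(cent)), 1e-9)
  # softmax mirror: the two class expectations sum to 1 at every alpha
  yes <- curve$expectation[curve$class == "Yes"]
  no <- curve$expectation[curve$class == "No"]
  expect_lt(max(abs(yes + no - 1)), 1e-9)
})
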