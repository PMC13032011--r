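refutation_strategies <- function() c("BV", "ARCC", "DSV", "PT", "DO")

refutation_err <- function(strategy, new_effect, estimated_effect) {
  if (strategy %in% c("BV", "ARCC", "DSV")) {
    if (estimated_effect == 0) {
      abort("estimated effect is zero: relative refutation error undefined")
    }
    abs((new_effect - estimated_effect) / estimated_effect)
  } else {
    abs(new_effect)
  }
}

perturb_cohort <- function(cohort, strategy, params, rep_seed) {
  set.seed(rep_seed)
  n <- nrow(cohort)
  switch(strategy,
    BV = cohort[sample.int(n, n, replace = TRUE), , drop = FALSE],
    ARCC = {
      out <- cohort
      for (j in seq_len(params$arcc_count %||% 1)) {
        out[[paste0("arcc_", j)]] <- rnorm(n)
      }
      out
    },
    DSV = {
      frac <- params$frac %||% 0.8
      cohort[sample.int(n, floor(frac * n)), , drop = FALSE]
    },
    PT = {
      out <- cohort
      tr <- params$treatment
      if (is.null(tr)) abort("placebo treatment needs params$treatment")
      out[[tr]] <- out[[tr]][sample.int(n)]
      out
    },
    DO = {
      out <- cohort
      oc <- params$outcome
      if (is.null(oc)) abort("dummy outcome needs params$outcome")
      out[[oc]] <- rnorm(n)
      out
    },
    abort(paste("unknown strategy:", strategy))
  )
}

#' Falsify a causal-effect estimate with one refutation strategy
#'
#' Runs the estimator on the original cohort, then `reps` times on a
#' strategy-specific perturbation, and reports the matching error rate:
#'
#' * **BV** (bootstrap validation): resample records with replacement;
#'   err = |new - estimated| / |estimated|.
#' * **ARCC** (add random common cause): append standard-normal noise
#'   covariate(s) named `arcc_*`, which estimators built by this package
#'   absorb into their adjustment set; err relative as BV.
#' * **DSV** (data-subset validation): uniform subsample of fraction
#'   `params$frac` (default 0.8); err relative as BV.
#' * **PT** (placebo treatment): permute the treatment column; err =
#'   |new effect| (a valid estimator should find nothing).
#' * **DO** (dummy outcome): replace the outcome column with
#'   standard-normal noise; err = |new effect|.
#'
#' A relative strategy with a zero original estimate is undefined and
#' rejected. The pass verdict compares err against `threshold` (defaults:
#' 0.10 for the relative strategies, 0.05 on the effect scale for the
#' absolute ones).
#'
#' @param estimator Function `function(cohort) -> scalar effect`,
#'   deterministic given the data (seed anything stochastic inside).
#' @param cohort Cohort data frame.
#' @param strategy One of `"BV"`, `"ARCC"`, `"DSV"`, `"PT"`, `"DO"`.
#' @param reps Repetitions (default 20), averaged by mean.
#' @param seed Integer seed driving the perturbations.
#' @param params List: `frac`, `arcc_count`, `treatment`, `outcome`.
#' @param threshold Pass threshold; `NULL` for the strategy default.
#' @return A one-row `refutation_report` tibble: `strategy`,
#'   `estimated_effect`, `new_effect`, `err`, `reps`, `threshold`, `pass`.
#' @export
refute <- function(estimator, cohort, strategy, reps = 20, seed = 1,
                   params = list(), threshold = NULL) {
  strategy <- match.arg(strategy, refutation_strategies())
  if (reps < 1) abort("reps must be at least 1")
  estimated <- estimator(cohort)
  if (strategy %in% c("BV", "ARCC", "DSV") && estimated == 0) {
    abort("estimated effect is zero: relative refutation error undefined")
  }
  new_effects <- vapply(seq_len(reps), function(r) {
    pert <- perturb_cohort(cohort, strategy, params, seed + 7919 * r)
    estimator(pert)
  }, numeric(1))
  new_effect <- mean(new_effects)
  err <- refutation_err(strategy, new_effect, estimated)
  threshold <- threshold %||% if (strategy %in% c("BV", "ARCC", "DSV")) 0.10 else 0.05
  out <- tibble(strategy = strategy, estimated_effect = estimated,
                new_effect = new_effect, err = err, reps = as.integer(reps),
                threshold = threshold, pass = err < threshold)
  structure(out, class = c("refutation_report", class(out)),
            new_effects = new_effects)
}

#' Run all five refutation strategies
#'
#' One [refute()] report per strategy, from a shared seed stream; the
#' combined table carries a summary pass verdict per strategy.
#'
#' @inheritParams refute
#' @param thresholds Optional named numeric vector of per-strategy
#'   thresholds.
#' @return A `refutation_report` tibble with five rows.
#' @export
refutation_suite <- function(estimator, cohort, reps = 20, seed = 1,
                             params = list(), thresholds = NULL) {
  rows <- purrr::map_dfr(refutation_strategies(), function(s) {
    th <- if (!is.null(thresholds) && s %in% names(thresholds)) thresholds[[s]] else NULL
    refute(estimator, cohort, s, reps = reps,
           seed = seed + match(s, refutation_strategies()),
           params = params, threshold = th)
  })
  structure(rows, class = c("refutation_report", class(rows)))
}

#' Plot refutation error rates
#'
#' Error rate per strategy against its pass threshold.
#'
#' @param object A `refutation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.refutation_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$strategy, y = .data$err,
                                       fill = .data$pass)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$threshold,
                                        ymax = .data$threshold),
                           linetype = "dashed") +
    ggplot2::labs(x = "refutation strategy", y = "error rate") +
    ggplot2::theme_minimal()
}

#' Write a refutation report
#'
#' JSON plus an aligned plain-text strategy-by-error table.
#'
#' @param report A `refutation_report`.
#' @param path Output path for the JSON; the text table goes to
#'   `<path>.txt`.
#' @return `path`, invisibly.
#' @export
write_refutation_report <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE, digits = NA)
  txt <- c(
    sprintf("%-6s %14s %14s %10s %6s", "strat", "estimated", "new", "err%", "pass"),
    sprintf("%-6s %14.6f %14.6f %9.2f%% %6s",
            report$strategy, report$estimated_effect, report$new_effect,
            100 * report$err, ifelse(report$pass, "yes", "no"))
  )
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}

#' Backdoor-adjusted linear effect estimator factory
#'
#' Builds an estimator closure for [refute()]: the coefficient of the
#' treatment in an ordinary least-squares regression of the outcome on the
#' treatment plus the adjustment covariates. Any `arcc_*` columns a
#' refutation adds are absorbed into the adjustment set automatically.
#'
#' @param treatment,outcome Column names.
#' @param covariates Adjustment column names.
#' @return `function(cohort) -> scalar`.
#' @export
backdoor_lm_estimator <- function(treatment, outcome, covariates = character(0)) {
  force(treatment); force(outcome); force(covariates)
  function(cohort) {
    covs <- c(covariates, grep("^arcc_", names(cohort), value = TRUE))
    rhs <- paste(c(treatment, covs), collapse = " + ")
    fit <- lm(stats::as.formula(paste(outcome, "~", rhs)), data = cohort)
    unname(coef(fit)[treatment])
  }
}

#' Meta-learner effect estimator factory
#'
#' Wraps [fit_meta_learner()] into the single-argument estimator contract
#' of [refute()]: treatment and outcome columns are named, `arcc_*`
#' columns join the adjustment set, and the returned effect is the ATE.
#'
#' @param treatment,outcome Column names.
#' @param covariates Adjustment column names.
#' @param seed,folds,control Passed to [fit_meta_learner()].
#' @return `function(cohort) -> scalar`.
#' @export
meta_learner_estimator <- function(treatment, outcome, covariates,
                                   seed = 1, folds = 5,
                                   control = meta_learner_control()) {
  force(treatment); force(outcome); force(covariates)
  function(cohort) {
    covs <- c(covariates, grep("^arcc_", names(cohort), value = TRUE))
    fit <- fit_meta_learner(cohort, cohort[[treatment]], cohort[[outcome]],
                            covs, folds = folds, seed = seed, control = control)
    fit$ate
  }
}
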