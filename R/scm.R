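#' Variable schema of the pediatric myopia cohort
#'
#' The 16 features the cohort carries, with their measurement type, plausible
#' range and units: 10 continuous measures (cycloplegic refraction CR, axial
#' length AL, nearwork NW, outdoor distance-viewing DTO, accommodative
#' abilities NAR/DAR, HEIGHT, PULSE, corneal keratometry K1/K2), 5
#' discrete/ordinal exposures (CB, EGG, REDM, WHIM dietary frequencies and
#' parental-myopia count PWG) and binary GENDER. The published K2 range
#' (38-183) is physiologically implausible for keratometry; the generator
#' uses a K1-like range for K2 and the schema records the plausible one.
#'
#' @return A tibble with columns `name`, `kind`
#'   (continuous/discrete_ordinal/binary), `low`, `high`, `units`.
#' @export
myopia_variable_specs <- function() {
  tibble(
    name = c("CR", "AL", "NW", "DTO", "NAR", "DAR", "HEIGHT", "PULSE",
             "GENDER", "CB", "EGG", "REDM", "WHIM", "PWG", "K1", "K2"),
    kind = c(rep("continuous", 8), "binary", rep("discrete_ordinal", 5),
             "continuous", "continuous"),
    low = c(-5.4, 20, 0, 0, -5.1, -6.6, 97, 52, 0, 1, 1, 1, 1, 0, 38, 38),
    high = c(8.7, 34, 102, 57, 2.2, 4.4, 143, 140, 1, 5, 4, 5, 5, 2, 71, 71),
    units = c("D", "mm", "h", "h", "D", "D", "cm", "bpm", "0/1",
              "times/week", "times/week", "times/week", "times/week",
              "persons", "mm", "mm")
  )
}

#' @rdname myopia_variable_specs
#' @export
myopia_feature_names <- function() myopia_variable_specs()$name

# Source distributions and child equations of the default ground-truth SCM.
# All constants live here so tests and documentation reference one table.
myopia_scm_constants <- function() {
  list(
    sources = list(
      NW     = list(dist = "normal", mean = 40, sd = 12),
      DTO    = list(dist = "normal", mean = 20, sd = 8),
      NAR    = list(dist = "normal", mean = -1.5, sd = 1.0),
      DAR    = list(dist = "normal", mean = -1.0, sd = 1.5),
      HEIGHT = list(dist = "normal", mean = 120, sd = 7),
      PULSE  = list(dist = "normal", mean = 90, sd = 12),
      K1     = list(dist = "normal", mean = 43.5, sd = 1.4),
      K2     = list(dist = "normal", mean = 44.5, sd = 1.6),
      GENDER = list(dist = "categorical", values = c(0, 1), probs = c(0.422, 0.578)),
      PWG    = list(dist = "categorical", values = 0:2, probs = c(0.45, 0.40, 0.15)),
      CB     = list(dist = "categorical", values = 1:5, probs = c(0.30, 0.30, 0.20, 0.12, 0.08)),
      EGG    = list(dist = "categorical", values = 1:4, probs = c(0.25, 0.35, 0.25, 0.15)),
      REDM   = list(dist = "categorical", values = 1:5, probs = c(0.20, 0.30, 0.25, 0.15, 0.10)),
      WHIM   = list(dist = "categorical", values = 1:5, probs = c(0.20, 0.30, 0.25, 0.15, 0.10))
    ),
    children = list(
      # Coefficient pairs (source -> AL, source -> CR) are chosen away from
      # the collider-cancellation ratio: with a dominant AL -> CR edge,
      # conditioning on CR (or AL) induces an association between a source
      # and AL that can cancel the direct edge, making the model unfaithful
      # and the edge undiscoverable. Keeping AL -> CR moderate and the two
      # coefficients of each shared source on compatible signs keeps every
      # edge's partial signal well above the detection scale of the cohort.
      AL = list(
        target_mean = 24,
        noise_sd = 0.55,
        coef = c(PWG = 0.40, GENDER = 0.35, NAR = -0.25, DAR = -0.20,
                 K1 = -0.25, K2 = -0.20, HEIGHT = 0.05, REDM = 0.10)
      ),
      CR = list(
        target_mean = -0.5,
        noise_sd = 0.70,
        coef = c(AL = -0.5, PWG = -0.20, GENDER = -0.15, NAR = -0.20,
                 DAR = -0.15, K1 = -0.20, K2 = -0.15)
      )
    )
  )
}

source_mean <- function(s) {
  if (s$dist == "normal") s$mean else sum(s$values * s$probs)
}

#' Ground-truth structural causal model of the myopia cohort
#'
#' Builds the linear-Gaussian SCM whose graph is [myopia_reference_graph()]:
#' eight source variables feed axial length (AL), seven variables (the six
#' shared sources plus AL itself) feed cycloplegic refraction (CR), and six
#' variables (CB, EGG, NW, PULSE, WHIM, DTO) are edge-free. Children are
#' linear in their parents with Gaussian noise; intercepts are derived in
#' closed form from the source means so that AL centres near 24 mm and CR
#' near -0.5 D, which keeps the myopia label split roughly balanced. AL has
#' a negative coefficient on CR (longer eyes are more myopic); HEIGHT
#' enters AL positively.
#'
#' @return An object of class `ground_truth_scm`: `graph` (a finalized
#'   `causal_graph`), `edge_coeff` tibble (`from`, `to`, `coef`),
#'   `intercepts`, `noise_sd`, and `source_dists`.
#' @examples
#' scm <- default_myopia_scm()
#' nrow(scm$edge_coeff)  # 15 causal edges
#' @export
default_myopia_scm <- function() {
  k <- myopia_scm_constants()
  g <- myopia_reference_graph()
  coeffs <- purrr::imap_dfr(k$children, function(ch, name) {
    tibble(from = names(ch$coef), to = name, coef = unname(ch$coef))
  })
  mu <- vapply(k$sources, source_mean, numeric(1))
  intercepts <- numeric(0)
  # children in topological order so implied parent means are available
  implied <- mu
  for (name in c("AL", "CR")) {
    ch <- k$children[[name]]
    icpt <- ch$target_mean - sum(ch$coef * implied[names(ch$coef)])
    intercepts[name] <- icpt
    implied[name] <- ch$target_mean
  }
  noise_sd <- vapply(k$children, function(ch) ch$noise_sd, numeric(1))
  structure(
    list(graph = g, edge_coeff = coeffs, intercepts = intercepts,
         noise_sd = noise_sd, source_dists = k$sources,
         implied_means = implied),
    class = "ground_truth_scm"
  )
}

#' @export
print.ground_truth_scm <- function(x, ...) {
  cat(sprintf("<ground_truth_scm> %d nodes, %d edges, %d sources\n",
              length(x$graph$nodes), nrow(x$edge_coeff), length(x$source_dists)))
  invisible(x)
}

#' Myopia labelling rule
#'
#' A record is myopic when its cycloplegic refraction is at most -0.5
#' diopters: `CR <= -0.5` maps to 1, `CR > -0.5` to 0 (the boundary value
#' -0.5 is myopic).
#'
#' @param cr Numeric vector of cycloplegic refraction values in diopters.
#' @return Integer vector of 0/1 labels.
#' @examples
#' label_myopia(c(-0.5, 0, -3.2))
#' @export
label_myopia <- function(cr) {
  if (!is.numeric(cr)) abort("cr must be numeric")
  if (any(!is.finite(cr))) abort("cr must be finite")
  as.integer(cr <= -0.5)
}

sample_source <- function(s, n) {
  if (s$dist == "normal") {
    rnorm(n, s$mean, s$sd)
  } else {
    sample(s$values, n, replace = TRUE, prob = s$probs)
  }
}

#' Generate a synthetic cohort from a structural causal model
#'
#' Ancestral sampling in topological order: sources are drawn from their
#' stated distributions (Gaussian for continuous measures, categorical for
#' discrete ones), children as linear combinations of their parents plus
#' Gaussian noise, and the binary outcome `Myopia` from [label_myopia()] on
#' the CR column. No clipping is applied, so children are exactly
#' linear-Gaussian in their parents. The same seed reproduces the identical
#' table.
#'
#' @param scm A `ground_truth_scm`, e.g. [default_myopia_scm()].
#' @param n Number of records (>= 1).
#' @param seed Optional integer seed.
#' @return A tibble with the 16 feature columns (in schema order) plus
#'   `Myopia`.
#' @examples
#' cohort <- generate_cohort(default_myopia_scm(), n = 100, seed = 1)
#' table(cohort$Myopia)
#' @export
generate_cohort <- function(scm, n, seed = NULL) {
  if (!inherits(scm, "ground_truth_scm")) abort("scm must be a ground_truth_scm")
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("n must be a positive count")
  n <- as.integer(n)
  ord <- topological_order(scm$graph)
  if (is.null(ord)) abort("scm graph is cyclic")
  if (!is.null(seed)) set.seed(seed)
  cols <- list()
  for (v in ord) {
    pa <- parents(scm$graph, v)
    if (!length(pa)) {
      cols[[v]] <- sample_source(scm$source_dists[[v]], n)
    } else {
      e <- scm$edge_coeff[scm$edge_coeff$to == v, ]
      x <- rep(scm$intercepts[[v]], n)
      for (i in seq_len(nrow(e))) x <- x + e$coef[i] * cols[[e$from[i]]]
      cols[[v]] <- x + rnorm(n, 0, scm$noise_sd[[v]])
    }
  }
  out <- as_tibble(cols)[, myopia_feature_names()[myopia_feature_names() %in% ord]]
  out$Myopia <- label_myopia(out$CR)
  out
}

#' Write a ground-truth SCM to plain-text files
#'
#' The graph goes to a tab-separated edge list at `path` and the linear
#' coefficients to a `<path>.coef.tsv` sidecar with columns
#' `from`, `to`, `coef`.
#'
#' @param scm A `ground_truth_scm`.
#' @param path Edge-list path.
#' @return `path`, invisibly.
#' @export
write_scm <- function(scm, path) {
  write_edge_list(scm$graph, path)
  readr::write_tsv(scm$edge_coeff, paste0(path, ".coef.tsv"))
  invisible(path)
}
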