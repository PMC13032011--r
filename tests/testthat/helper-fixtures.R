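# Shared fixtures: random DAGs, random linear SCMs with samplers, a
# brute-force d-separation oracle, and small hand-built networks.

random_dag <- function(n_nodes, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  from <- character(0); to <- character(0)
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < p_edge) {
        from <- c(from, nodes[i]); to <- c(to, nodes[j])
      }
    }
  }
  causal_graph(nodes, tibble::tibble(from = from, to = to, directed = TRUE))
}

# linear-Gaussian SCM over a DAG: unit-variance sources, coefficients in
# +/-[0.5, 1.5], noise sd 1
random_linear_scm <- function(g, seed = 1) {
  set.seed(seed)
  e <- g$edges
  coef <- stats::runif(nrow(e), 0.5, 1.5) * sample(c(-1, 1), nrow(e), replace = TRUE)
  list(graph = g, coeffs = tibble::tibble(from = e$from, to = e$to, coef = coef))
}

sample_linear_scm <- function(scm, n, seed = 1) {
  set.seed(seed)
  ord <- topological_order(scm$graph)
  cols <- list()
  for (v in ord) {
    pa <- parents(scm$graph, v)
    x <- rnorm(n)
    for (p in pa) {
      b <- scm$coeffs$coef[scm$coeffs$from == p & scm$coeffs$to == v]
      x <- x + b * cols[[p]]
    }
    cols[[v]] <- x
  }
  tibble::as_tibble(cols)[ord]
}

# Brute-force d-separation oracle: enumerate every undirected path and
# apply the blocking rules directly. Independent of the package's
# moralization-based implementation.
dsep_oracle <- function(g, a, b, cond = character(0)) {
  e <- g$edges
  nb <- function(v) unique(c(e$to[e$from == v], e$from[e$to == v]))
  desc_tab <- lapply(setNames(g$nodes, g$nodes),
                     function(v) unitcausal:::descendants(g, v))
  paths <- list()
  walk <- function(v, trail) {
    if (v == b) { paths[[length(paths) + 1L]] <<- c(trail, v); return(invisible()) }
    for (w in setdiff(nb(v), trail)) walk(w, c(trail, v))
  }
  walk(a, character(0))
  is_edge <- function(x, y) any(e$from == x & e$to == y)
  for (p in paths) {
    open <- TRUE
    if (length(p) > 2) {
      for (k in 2:(length(p) - 1)) {
        v <- p[k]
        collider <- is_edge(p[k - 1], v) && is_edge(p[k + 1], v)
        if (collider) {
          if (!any(desc_tab[[v]] %in% cond)) { open <- FALSE; break }
        } else {
          if (v %in% cond) { open <- FALSE; break }
        }
      }
    }
    if (open) return(FALSE)
  }
  TRUE
}

# small untrained network with reproducible random weights
make_random_fnn <- function(d = 16, seed = 1, scale = 1) {
  set.seed(seed)
  he <- function(fi, fo) matrix(rnorm(fi * fo, 0, scale * sqrt(2 / fi)), fi, fo)
  structure(
    list(weights = list(W1 = he(d, 12), b1 = rnorm(12, 0, 0.1),
                        W2 = he(12, 8), b2 = rnorm(8, 0, 0.1),
                        W3 = he(8, 2), b3 = rnorm(2, 0, 0.1)),
         feature_order = paste0("x", seq_len(d)),
         center = setNames(rep(0, d), paste0("x", seq_len(d))),
         scale = setNames(rep(1, d), paste0("x", seq_len(d))),
         hidden = c(12, 8), classes = c("No", "Yes"),
         hyper = list(lr = 0, batch_size = 0, epochs = 0, seed = seed),
         loss_log = 0),
    class = "fnn_classifier"
  )
}

# two-class cohort linearly separable in one feature
separable_cohort <- function(n = 2000, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  tibble::tibble(
    x1 = rnorm(n, mean = ifelse(y == 1, 3, -3), sd = 0.5),
    x2 = rnorm(n),
    y = y
  )
}

# confounded world with constant treatment effect tau0:
# z -> t (logistic), z -> y, t -> y with coefficient tau0
confounded_world <- function(n, tau0, conf_strength = 1, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  p <- plogis(conf_strength * (z1 - 0.5 * z2))
  t_ <- rbinom(n, 1, p)
  y <- tau0 * t_ + conf_strength * (z1 + z2) + rnorm(n)
  tibble::tibble(z1 = z1, z2 = z2, t = t_, y = y)
}
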