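test_that("mixed embedding produces the expected blocks", {
  co <- generate_cohort(default_myopia_scm(), 500, seed = 1)
  emb <- embed_mixed(co, c("AL", "GENDER", "PWG", "CB"))
  expect_length(emb$blocks$AL, 1)       # continuous: one standardized column
  expect_length(emb$blocks$GENDER, 1)   # binary: 2 levels - reference
  expect_length(emb$blocks$PWG, 2)      # 3 levels - reference
  expect_length(emb$blocks$CB, 4)       # 5 levels - reference
  al <- emb$matrix[, emb$blocks$AL]
  expect_lt(abs(mean(al)), 1e-12)
  expect_equal(sd(al), 1, tolerance = 1e-12)
  expect_error(embed_mixed(data.frame(x = rep(1, 10))), "constant|degenerate")
})

test_that("CI statistic is invariant to affine rescaling and level relabeling", {
  set.seed(42)
  d <- tibble::tibble(x = rnorm(400), z = rnorm(400))
  d$y <- 0.5 * d$x + 0.5 * d$z + rnorm(400)
  d$g <- sample(1:3, 400, replace = TRUE)
  base <- dg_lrt(d, "x", "y", "z")
  resc <- d
  resc$x <- 100 * resc$x - 7
  resc$y <- -0.01 * resc$y + 3
  expect_equal(dg_lrt(resc, "x", "y", "z")$statistic, base$statistic,
               tolerance = 1e-8)
  withg <- dg_lrt(d, "g", "y")
  relab <- d
  relab$g <- c(10, 20, 30)[d$g]  # order-preserving relabel
  expect_equal(dg_lrt(relab, "g", "y")$statistic, withg$statistic,
               tolerance = 1e-8)
})

test_that("deterministic dependence and true independence behave at the extremes", {
  set.seed(1)
  d <- tibble::tibble(x = rnorm(500))
  d$y <- d$x
  expect_lt(dg_lrt(d, "x", "y")$p_value, 1e-10)
})

test_that("the null distribution of the CI test is calibrated", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    d <- tibble::tibble(x = rnorm(2000), y = rnorm(2000))
    dg_lrt(d, "x", "y")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.01)
  expect_lte(mean(hits), 0.10)
})

test_that("conditioning on a mediator removes chain dependence", {
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(5000)
    z <- x + rnorm(5000)
    y <- z + rnorm(5000)
    d <- tibble::tibble(x = x, z = z, y = y)
    dg_lrt(d, "x", "y", "z")$p_value >= 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("PC skeleton prunes independent columns and keeps chains", {
  spurious <- vapply(1:50, function(s) {
    set.seed(s)
    d <- tibble::tibble(a = rnorm(3000), b = rnorm(3000),
                        c = rnorm(3000), d = rnorm(3000))
    nrow(pc_skeleton(d, alpha = 0.05)$skeleton$edges)
  }, numeric(1))
  expect_gte(mean(spurious <= 1), 0.90)
  chain_ok <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    a <- rnorm(5000); b <- a + rnorm(5000); c_ <- b + rnorm(5000)
    sk <- pc_skeleton(tibble::tibble(a = a, b = b, c = c_), alpha = 0.05)$skeleton
    keys <- paste(sk$edges$from, sk$edges$to)
    setequal(keys, c("a b", "b c"))
  }, logical(1))
  expect_gte(mean(chain_ok), 0.90)
})

test_that("a too-small sample caps the depth and keeps the complete graph", {
  d <- tibble::tibble(a = c(0.1, 2.2), b = c(1.3, -0.7), c = c(0.5, 0.9))
  expect_warning(res <- pc_skeleton(d, alpha = 0.05), "capped|small")
  expect_equal(nrow(res$skeleton$edges), 3)  # complete graph on 3 nodes
})

test_that("v-structure orientation follows the sepset rule", {
  sk <- causal_graph(c("A", "B", "C"),
                     data.frame(from = c("A", "B"), to = c("C", "C"),
                                directed = FALSE))
  seps <- tibble::tibble(x = "A", y = "B", sepset = list(character(0)), p_value = 0.5)
  out <- orient_v_structures(sk, seps)
  expect_true(all(out$edges$directed))
  expect_setequal(paste(out$edges$from, out$edges$to), c("A C", "B C"))
  # mediator case: sepset contains C, nothing oriented
  seps2 <- tibble::tibble(x = "A", y = "B", sepset = list("C"), p_value = 0.5)
  out2 <- orient_v_structures(sk, seps2)
  expect_true(all(!out2$edges$directed))
})

test_that("a collider is recovered from data by the full pipeline", {
  hit <- vapply(1:50, function(s) {
    set.seed(s)
    a <- rnorm(5000); b <- rnorm(5000); c_ <- a + b + rnorm(5000)
    g <- suppressMessages(discover_graph(tibble::tibble(a = a, b = b, c = c_),
                                         alpha = 0.05, outcome = NULL))
    keys <- paste(g$edges$from, g$edges$to, g$edges$directed)
    setequal(keys, c("a c TRUE", "b c TRUE"))
  }, logical(1))
  expect_gte(mean(hit), 0.80)
})

test_that("Meek R1 fires and the closure is idempotent", {
  pdag <- causal_graph(c("A", "B", "C"),
                       data.frame(from = c("A", "B"), to = c("B", "C"),
                                  directed = c(TRUE, FALSE)))
  out <- apply_meek_rules(pdag)
  expect_true(all(out$edges$directed))
  expect_true(any(out$edges$from == "B" & out$edges$to == "C"))
  again <- apply_meek_rules(out)
  expect_equal(shd(again, out), 0)
})

test_that("Meek closure equals brute-force exhaustive rule application", {
  # independent oracle: repeatedly scan all node triples/quads with the rule
  # definitions spelled out directly on edge tibbles
  brute_close <- function(g) {
    repeat {
      e <- g$edges
      dir <- e[e$directed, ]; und <- e[!e$directed, ]
      has_dir <- function(u, v) any(dir$from == u & dir$to == v)
      adj <- function(u, v) {
        any((e$from == u & e$to == v) | (e$from == v & e$to == u))
      }
      oriented <- FALSE
      for (i in seq_len(nrow(und))) {
        for (ab in list(c(und$from[i], und$to[i]), c(und$to[i], und$from[i]))) {
          a <- ab[1]; b <- ab[2]
          fire <- FALSE
          for (x in g$nodes) {
            if (has_dir(x, a) && !adj(x, b)) fire <- TRUE                     # R1
          }
          for (c_ in g$nodes) {
            if (has_dir(a, c_) && has_dir(c_, b)) fire <- TRUE               # R2
          }
          cands <- Filter(function(c_) {
            any((und$from == a & und$to == c_) | (und$from == c_ & und$to == a)) &&
              has_dir(c_, b)
          }, g$nodes)
          if (length(cands) >= 2) {
            for (u in cands) for (v in cands) {
              if (u < v && !adj(u, v)) fire <- TRUE                          # R3
            }
          }
          for (c_ in g$nodes) {
            if (!any((und$from == a & und$to == c_) | (und$from == c_ & und$to == a))) next
            if (adj(c_, b)) next
            for (d_ in g$nodes) {
              if (has_dir(c_, d_) && has_dir(d_, b)) fire <- TRUE            # R4
            }
          }
          if (fire) {
            keep <- !((e$from == a & e$to == b) | (e$from == b & e$to == a)) | e$directed
            g <- causal_graph(g$nodes,
                              dplyr::bind_rows(e[keep, ],
                                               tibble::tibble(from = a, to = b, directed = TRUE)))
            oriented <- TRUE
            break
          }
        }
        if (oriented) break
      }
      if (!oriented) return(g)
    }
  }
  for (s in 1:12) {
    g <- random_dag(5, 0.5, seed = 400 + s)
    # build a CPDAG-like input: orient v-structures of the true DAG, rest undirected
    e <- g$edges
    is_coll <- rep(FALSE, nrow(e))
    for (i in seq_len(nrow(e))) {
      v <- e$to[i]
      others <- setdiff(parents(g, v), e$from[i])
      for (o in others) {
        if (!any((e$from == o & e$to == e$from[i]) | (e$from == e$from[i] & e$to == o))) {
          is_coll[i] <- TRUE
        }
      }
    }
    pdag <- causal_graph(g$nodes, tibble::tibble(from = e$from, to = e$to,
                                                 directed = is_coll))
    expect_equal(shd(apply_meek_rules(pdag), brute_close(pdag)), 0,
                 info = paste("seed", 400 + s))
  }
})

test_that("discovery is deterministic and orientation never creates a cycle", {
  co <- generate_cohort(default_myopia_scm(), 3000, seed = 9)
  g1 <- suppressMessages(discover_graph(co, alpha = 0.01))
  g2 <- suppressMessages(discover_graph(co, alpha = 0.01))
  expect_equal(shd(g1, g2), 0)
  dir_part <- causal_graph(g1$nodes, g1$edges[g1$edges$directed, ])
  expect_false(is.null(topological_order(dir_part)))
})

test_that("recorded sepsets d-separate their pairs in the oracle graph", {
  # structural check at large n on the known-truth generator
  scm <- default_myopia_scm()
  co <- generate_cohort(scm, 20000, seed = 13)
  sk <- pc_skeleton(co[myopia_feature_names()], alpha = 0.01)
  seps <- sk$sepsets
  ok <- vapply(seq_len(nrow(seps)), function(i) {
    pair_in_truth <- any(paste(scm$graph$edges$from, scm$graph$edges$to) %in%
                           paste(c(seps$x[i], seps$y[i]), c(seps$y[i], seps$x[i])))
    if (pair_in_truth) return(NA)  # a removed true edge cannot be d-separable
    d_separated(scm$graph, seps$x[i], seps$y[i], seps$sepset[[i]])
  }, logical(1))
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("the PCA collinearity screen maps merged blocks back to variables", {
  set.seed(7)
  base <- rnorm(2000)
  d <- tibble::tibble(
    u = base + rnorm(2000, sd = 0.05),   # |r| > 0.95 with v
    v = base + rnorm(2000, sd = 0.05),
    w = rnorm(2000)
  )
  d$y <- d$u + d$v + rnorm(2000)
  g <- suppressMessages(discover_graph(d, alpha = 0.05, use_pca = TRUE,
                                       outcome = NULL))
  expect_setequal(g$nodes, c("u", "v", "w", "y"))
  expect_false(any(grepl("pcagrp", c(g$edges$from, g$edges$to))))
  # the collinear pair's association with y is attributed to both members
  expect_true(any((g$edges$from == "u" & g$edges$to == "y") |
                    (g$edges$from == "y" & g$edges$to == "u")))
})
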