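sorted_subsets <- function(x, k) {
  # deterministic enumeration of size-k subsets of a sorted vector
  x <- sort(x)
  if (k == 0) return(list(character(0)))
  if (length(x) < k) return(list())
  cmb <- utils::combn(x, k, simplify = FALSE)
  cmb
}

#' PC skeleton search with the degenerate-Gaussian CI test
#'
#' Classical PC edge deletion: start from the complete undirected graph over
#' `columns`, and for conditioning-set sizes 0, 1, ... up to `max_depth`
#' test each remaining edge against subsets of the current adjacencies of
#' its endpoints, removing the edge at the first test with
#' `p >= alpha` and recording the separating set. Nodes, pairs and subsets
#' are scanned in lexicographic order, so the result is deterministic for a
#' given data set. When the sample is too small for the embedded dimension
#' of a test, that test is skipped and a capped-depth warning is issued
#' once.
#'
#' @param data A data frame (cohort).
#' @param alpha Significance level in (0, 1); an edge survives while every
#'   test rejects independence at `alpha`.
#' @param max_depth Largest conditioning-set size (default 3).
#' @param columns Columns to learn over (default: all).
#' @param kinds Optional named kind vector ([infer_kinds()]).
#' @return A list with `skeleton` (a `causal_graph` of undirected edges),
#'   `sepsets` (tibble: `x`, `y`, `sepset` list-column, `p_value`), and
#'   `edge_pvalues` (largest p-value seen for retained edges).
#' @export
pc_skeleton <- function(data, alpha = 0.05, max_depth = 3,
                        columns = names(data), kinds = NULL) {
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0,1)")
  nodes <- sort(columns)
  cache <- ci_cache(data, nodes, kinds)
  n <- cache$n
  adj <- matrix(TRUE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  diag(adj) <- FALSE
  sepsets <- list()
  edge_p <- list()
  capped <- FALSE
  testable <- function(x, y, cond) {
    dims <- length(cache$blocks[[x]]) + length(cache$blocks[[y]]) +
      sum(lengths(cache$blocks[cond]))
    n > dims + 2
  }
  for (depth in 0:max_depth) {
    any_big_enough <- FALSE
    for (x in nodes) {
      for (y in nodes[nodes > x]) {
        if (!adj[x, y]) next
        cands <- union(setdiff(nodes[adj[x, ]], y), setdiff(nodes[adj[y, ]], x))
        if (length(cands) >= depth) any_big_enough <- TRUE
        removed <- FALSE
        for (side in list(setdiff(nodes[adj[x, ]], y), setdiff(nodes[adj[y, ]], x))) {
          if (removed) break
          for (cond in sorted_subsets(side, depth)) {
            if (!testable(x, y, cond)) {
              capped <- TRUE
              next
            }
            res <- dg_lrt_cache(cache, x, y, cond)
            key <- paste(x, y)
            edge_p[[key]] <- max(edge_p[[key]] %||% 0, res$p_value)
            if (res$p_value >= alpha) {
              adj[x, y] <- adj[y, x] <- FALSE
              sepsets[[length(sepsets) + 1L]] <- tibble(
                x = x, y = y, sepset = list(sort(cond)), p_value = res$p_value
              )
              removed <- TRUE
              break
            }
          }
        }
      }
    }
    if (!any_big_enough && depth > 0) break
  }
  if (capped) {
    warn("sample too small for some conditioning sets; depth effectively capped")
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]], directed = FALSE)
  kept <- paste(edges$from, edges$to)
  list(
    skeleton = causal_graph(nodes, edges),
    sepsets = if (length(sepsets)) dplyr::bind_rows(sepsets) else
      tibble(x = character(), y = character(), sepset = list(), p_value = numeric()),
    edge_pvalues = tibble(
      from = edges$from, to = edges$to,
      max_p = vapply(kept, function(k) edge_p[[k]] %||% 0, numeric(1))
    )
  )
}

lookup_sepset <- function(sepsets, a, b) {
  hit <- (sepsets$x == a & sepsets$y == b) | (sepsets$x == b & sepsets$y == a)
  if (!any(hit)) return(NULL)
  sepsets$sepset[[which(hit)[1]]]
}

#' Orient v-structures in a PC skeleton
#'
#' For every unshielded triple `a - c - b` (with `a`, `b` nonadjacent) whose
#' separating set does not contain `c`, proposes the collider
#' `a -> c <- b`. Edges that receive contradictory proposals from different
#' triples are left undirected.
#'
#' @param skeleton A `causal_graph` of undirected edges (from
#'   [pc_skeleton()]).
#' @param sepsets Sepset tibble from [pc_skeleton()].
#' @return A partially directed `causal_graph`.
#' @export
orient_v_structures <- function(skeleton, sepsets) {
  nodes <- skeleton$nodes
  und <- skeleton$edges[!skeleton$edges$directed, , drop = FALSE]
  adjacent <- function(u, v) any((und$from == u & und$to == v) | (und$from == v & und$to == u))
  proposals <- character(0)
  for (c_ in nodes) {
    nb <- neighbours(skeleton, c_)
    if (length(nb) < 2) next
    cmb <- utils::combn(sort(nb), 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      if (adjacent(a, b)) next
      ss <- lookup_sepset(sepsets, a, b)
      if (is.null(ss)) next
      if (!(c_ %in% ss)) {
        proposals <- c(proposals, edge_key(a, c_), edge_key(b, c_))
      }
    }
  }
  proposals <- unique(proposals)
  parts <- strsplit(proposals, "\r")
  from <- vapply(parts, `[`, "", 1)
  to <- vapply(parts, `[`, "", 2)
  conflicted <- proposals[edge_key(to, from) %in% proposals]
  edges <- und
  for (i in seq_along(proposals)) {
    if (proposals[i] %in% conflicted) next
    u <- from[i]; v <- to[i]
    hit <- (edges$from == u & edges$to == v) | (edges$from == v & edges$to == u)
    hit <- hit & !edges$directed
    if (any(hit)) {
      k <- which(hit)[1]
      edges$from[k] <- u; edges$to[k] <- v; edges$directed[k] <- TRUE
    }
  }
  causal_graph(nodes, edges)
}

has_directed_path <- function(dir, a, b) {
  # dir: logical adjacency matrix of directed edges
  reach <- a
  frontier <- a
  while (length(frontier)) {
    nxt <- colnames(dir)[colSums(dir[frontier, , drop = FALSE]) > 0]
    frontier <- setdiff(nxt, reach)
    reach <- union(reach, frontier)
    if (b %in% reach) return(TRUE)
  }
  FALSE
}

#' Meek orientation-propagation closure
#'
#' Applies Meek's four rules to a partially directed graph until no rule
#' fires, orienting undirected edges without creating new v-structures:
#'
#' * R1: `a -> b`, `b - c`, `a` and `c` nonadjacent: orient `b -> c`.
#' * R2: `a -> c -> b` and `a - b`: orient `a -> b`.
#' * R3: `a - b`, `a - c`, `a - d`, `c -> b`, `d -> b`, `c` and `d`
#'   nonadjacent: orient `a -> b`.
#' * R4: `a - b`, `a - c`, `c -> d`, `d -> b`, `c` and `b` nonadjacent:
#'   orient `a -> b`.
#'
#' An orientation that would close a directed cycle is skipped, so the
#' output's directed part is always acyclic; the closure is idempotent.
#'
#' @param pdag A partially directed `causal_graph` with acyclic directed
#'   part.
#' @return The closed `causal_graph`.
#' @export
apply_meek_rules <- function(pdag) {
  nodes <- sort(pdag$nodes)
  k <- length(nodes)
  dir <- matrix(FALSE, k, k, dimnames = list(nodes, nodes))
  und <- matrix(FALSE, k, k, dimnames = list(nodes, nodes))
  e <- pdag$edges
  for (i in seq_len(nrow(e))) {
    if (e$directed[i]) dir[e$from[i], e$to[i]] <- TRUE
    else und[e$from[i], e$to[i]] <- und[e$to[i], e$from[i]] <- TRUE
  }
  adj <- function(u, v) dir[u, v] || dir[v, u] || und[u, v]
  orient <- function(u, v) {
    # refuse orientations that would close a directed cycle
    if (has_directed_path(dir, v, u)) return(FALSE)
    und[u, v] <<- und[v, u] <<- FALSE
    dir[u, v] <<- TRUE
    TRUE
  }
  repeat {
    changed <- FALSE
    for (a in nodes) for (b in nodes) {
      if (!und[a, b]) next
      fired <- FALSE
      # R1: x -> a, a - b, x and b nonadjacent  => a -> b
      for (x in nodes[dir[, a]]) {
        if (!adj(x, b)) { fired <- orient(a, b); break }
      }
      # R2: a -> c -> b with a - b => a -> b
      if (!fired) {
        for (c_ in nodes[dir[a, ]]) {
          if (dir[c_, b]) { fired <- orient(a, b); break }
        }
      }
      # R3: a - c, a - d, c -> b, d -> b, c and d nonadjacent => a -> b
      if (!fired) {
        cands <- nodes[und[a, ] & dir[, b]]
        if (length(cands) >= 2) {
          cmb <- utils::combn(cands, 2)
          for (j in seq_len(ncol(cmb))) {
            if (!adj(cmb[1, j], cmb[2, j])) { fired <- orient(a, b); break }
          }
        }
      }
      # R4: a - c, c -> d, d -> b, c and b nonadjacent => a -> b
      if (!fired) {
        for (c_ in nodes[und[a, ]]) {
          if (adj(c_, b)) next  # c and b must be nonadjacent
          dd <- nodes[dir[c_, ] & dir[, b]]
          if (length(dd)) { fired <- orient(a, b); break }
        }
      }
      if (fired) changed <- TRUE
    }
    if (!changed) break
  }
  idxd <- which(dir, arr.ind = TRUE)
  idxu <- which(und & upper.tri(und), arr.ind = TRUE)
  edges <- dplyr::bind_rows(
    tibble(from = nodes[idxd[, 1]], to = nodes[idxd[, 2]], directed = TRUE),
    tibble(from = nodes[idxu[, 1]], to = nodes[idxu[, 2]], directed = FALSE)
  )
  causal_graph(pdag$nodes, edges)
}

collinear_groups <- function(data, columns, threshold = 0.95) {
  kinds <- infer_kinds(data[columns])
  cont <- columns[kinds == "continuous"]
  if (length(cont) < 2) return(list())
  r <- abs(stats::cor(data[cont]))
  diag(r) <- 0
  # connected components of the |r| > threshold graph
  groups <- list()
  left <- cont
  while (length(left)) {
    comp <- left[1]
    repeat {
      nb <- cont[colSums(r[comp, , drop = FALSE] > threshold) > 0]
      nb <- setdiff(nb, comp)
      if (!length(nb)) break
      comp <- c(comp, nb)
    }
    if (length(comp) > 1) groups[[length(groups) + 1L]] <- sort(comp)
    left <- setdiff(left, comp)
  }
  groups
}

#' Constraint-based causal discovery over a mixed-type cohort
#'
#' Full pipeline: one-hot/standardizing embedding, PC skeleton search with
#' the degenerate-Gaussian likelihood-ratio test, collider orientation, and
#' Meek-rule closure. Edges the closure cannot orient are reported as
#' undirected rather than forced. With `use_pca = TRUE`, groups of
#' continuous columns with pairwise `|r| > 0.95` are merged into a single
#' principal-component block for testing (a collinearity screen), and edges
#' found for a merged block are mapped back to every member variable;
#' within-group edges stay undirected.
#'
#' @param data A cohort data frame; the binary outcome column (default
#'   `"Myopia"`) is excluded from discovery.
#' @param alpha Significance level (default 0.05).
#' @param max_depth PC conditioning-depth cap (default 3).
#' @param use_pca Collinearity screen switch (default `FALSE`).
#' @param columns Feature columns (default: all but `outcome`).
#' @param outcome Outcome column name to exclude.
#' @return A `causal_graph` with attributes `alpha`, `max_depth`,
#'   `sepsets` and `edge_pvalues`.
#' @examples
#' cohort <- generate_cohort(default_myopia_scm(), 2000, seed = 1)
#' g <- discover_graph(cohort, alpha = 0.01)
#' @export
discover_graph <- function(data, alpha = 0.05, max_depth = 3, use_pca = FALSE,
                           columns = NULL, outcome = "Myopia") {
  columns <- columns %||% setdiff(names(data), outcome)
  groups <- if (use_pca) collinear_groups(data, columns) else list()
  work <- as_tibble(data[columns])
  merged_names <- character(0)
  if (length(groups)) {
    for (gi in seq_along(groups)) {
      grp <- groups[[gi]]
      pc <- stats::prcomp(work[grp], center = TRUE, scale. = TRUE)
      keep <- which(cumsum(pc$sdev^2) / sum(pc$sdev^2) < 0.999)
      keep <- union(keep, 1L)
      nm <- paste0(".pcagrp", gi)
      merged_names <- c(merged_names, nm)
      work <- work[setdiff(names(work), grp)]
      work[[nm]] <- pc$x[, 1]  # leading score; remaining scores below
      if (length(keep) > 1) {
        for (j in keep[-1]) work[[paste0(nm, "_", j)]] <- pc$x[, j]
      }
    }
  }
  sk <- pc_skeleton(work, alpha = alpha, max_depth = max_depth,
                    columns = names(work))
  pdag <- orient_v_structures(sk$skeleton, sk$sepsets)
  g <- apply_meek_rules(pdag)
  if (length(groups)) {
    # map merged-block edges back to the original variables
    edges <- g$edges
    out <- list()
    for (i in seq_len(nrow(edges))) {
      f <- edges$from[i]; t_ <- edges$to[i]
      fl <- if (grepl("^\\.pcagrp", f)) groups[[as.integer(sub("^\\.pcagrp(\\d+).*", "\\1", f))]] else f
      tl <- if (grepl("^\\.pcagrp", t_)) groups[[as.integer(sub("^\\.pcagrp(\\d+).*", "\\1", t_))]] else t_
      for (ff in fl) for (tt in tl) {
        if (ff != tt) out[[length(out) + 1L]] <- tibble(from = ff, to = tt, directed = edges$directed[i])
      }
    }
    # unresolved within-group adjacency stays undirected
    for (grp in groups) {
      cmb <- utils::combn(grp, 2)
      for (j in seq_len(ncol(cmb))) {
        out[[length(out) + 1L]] <- tibble(from = cmb[1, j], to = cmb[2, j], directed = FALSE)
      }
    }
    edges <- if (length(out)) dplyr::distinct(dplyr::bind_rows(out)) else
      tibble(from = character(), to = character(), directed = logical())
    g <- causal_graph(columns, edges)
  }
  if (any(!g$edges$directed)) {
    inform(sprintf("%d edge(s) left undirected by orientation; excluded from path-based attribution",
                   sum(!g$edges$directed)))
  }
  stopifnot(!is.null(topological_order(causal_graph(g$nodes, g$edges[g$edges$directed, ]))))
  attr(g, "alpha") <- alpha
  attr(g, "max_depth") <- max_depth
  attr(g, "sepsets") <- sk$sepsets
  attr(g, "edge_pvalues") <- sk$edge_pvalues
  g
}

#' Structural Hamming distance between two graphs
#'
#' Edge-level edit distance: one point for each node pair adjacent in one
#' graph but not the other, and one point for each shared adjacency whose
#' orientation differs (reversed, or directed vs undirected).
#'
#' @param g1,g2 `causal_graph` objects over the same node set.
#' @return Non-negative integer.
#' @export
shd <- function(g1, g2) {
  stopifnot(setequal(g1$nodes, g2$nodes))
  code <- function(g) {
    e <- g$edges
    keys <- ifelse(e$directed, paste0(e$from, ">", e$to),
                   paste0(pmin(e$from, e$to), "-", pmax(e$from, e$to)))
    pair <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    setNames(keys, pair)
  }
  c1 <- code(g1); c2 <- code(g2)
  pairs <- union(names(c1), names(c2))
  sum(vapply(pairs, function(p) {
    a <- c1[p]; b <- c2[p]
    if (is.na(a) || is.na(b)) 1L else if (a != b) 1L else 0L
  }, integer(1)))
}

#' Write a discovery run report
#'
#' JSON report with the significance level, depth cap, the discovered edge
#' list with orientations, and the retained-edge p-values.
#'
#' @param g Graph from [discover_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discovery_report <- function(g, path) {
  rep <- list(
    alpha = attr(g, "alpha"),
    max_depth = attr(g, "max_depth"),
    edges = data.frame(from = g$edges$from, to = g$edges$to,
                       orientation = ifelse(g$edges$directed, "directed", "undirected")),
    edge_pvalues = as.data.frame(attr(g, "edge_pvalues"))
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
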