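#' Causal graphs over named features
#'
#' A `causal_graph` is a light container for a mixed graph over named nodes:
#' a character vector of nodes plus an edge tibble with columns `from`, `to`
#' and `directed`. Undirected edges (CPDAG leftovers from constraint-based
#' discovery) are stored once with `directed = FALSE`; `from`/`to` order is
#' canonicalised alphabetically for them. A *finalized* graph has only
#' directed edges and no directed cycle, and is what the attribution engines
#' require.
#'
#' @param nodes Character vector of node names.
#' @param edges A data frame with columns `from`, `to` and optionally
#'   `directed` (default `TRUE`). Zero-row input gives an edgeless graph.
#' @return A `causal_graph` object.
#' @examples
#' g <- causal_graph(c("A", "B", "C"), data.frame(from = c("A", "B"), to = c("B", "C")))
#' is_dag(g)
#' @export
causal_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node names")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character(), directed = logical())
  } else {
    edges <- as_tibble(edges)
    if (!"directed" %in% names(edges)) edges$directed <- TRUE
    edges <- edges[, c("from", "to", "directed")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    bad <- setdiff(c(edges$from, edges$to), nodes)
    if (length(bad)) abort(paste("edge endpoints not in node set:", paste(bad, collapse = ", ")))
    if (any(edges$from == edges$to)) abort("self-loops are not allowed")
    # canonical order for undirected edges
    u <- !edges$directed
    swap <- u & edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key[!edges$directed]) ||
        any(key[edges$directed] %in% key[!edges$directed])) {
      abort("a node pair may not carry both a directed and an undirected edge")
    }
    dup <- duplicated(paste(edges$from, edges$to, edges$directed))
    edges <- edges[!dup, ]
  }
  structure(list(nodes = nodes, edges = edges), class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  nd <- sum(x$edges$directed)
  nu <- sum(!x$edges$directed)
  cat(sprintf("<causal_graph> %d nodes, %d directed / %d undirected edges\n",
              length(x$nodes), nd, nu))
  if (nrow(x$edges)) {
    e <- x$edges
    arrows <- ifelse(e$directed, "->", "--")
    cat(paste0("  ", e$from, " ", arrows, " ", e$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
format.causal_graph <- function(x, ...) {
  sprintf("<causal_graph: %d nodes, %d edges>", length(x$nodes), nrow(x$edges))
}

edge_key <- function(from, to) paste(from, to, sep = "\r")

#' @rdname causal_graph
#' @param g A `causal_graph`.
#' @export
is_dag <- function(g) {
  if (any(!g$edges$directed)) return(FALSE)
  !is.null(topological_order(g))
}

is_finalized <- function(g) is_dag(g)

#' Topological order of a directed graph
#'
#' Kahn's algorithm with alphabetical tie-breaking so the order is
#' deterministic. Returns `NULL` when the directed part is cyclic.
#'
#' @param g A `causal_graph` (undirected edges are ignored).
#' @return Character vector of nodes in topological order, or `NULL`.
#' @export
topological_order <- function(g) {
  nodes <- sort(g$nodes)
  e <- g$edges[g$edges$directed, , drop = FALSE]
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(e$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- nodes[indeg == 0]
  while (length(avail)) {
    v <- sort(avail)[1]
    avail <- setdiff(avail, v)
    out <- c(out, v)
    ch <- e$to[e$from == v]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(out) < length(nodes)) NULL else out
}

#' Structural neighbourhoods
#'
#' `parents()`, `children()` and `neighbours()` return the nodes connected to
#' `v` by incoming directed, outgoing directed, and any edges respectively.
#'
#' @param g A `causal_graph`.
#' @param v A node name.
#' @return Character vector of node names (sorted).
#' @export
parents <- function(g, v) {
  stopifnot(v %in% g$nodes)
  e <- g$edges
  sort(unique(e$from[e$directed & e$to == v]))
}

#' @rdname parents
#' @export
children <- function(g, v) {
  stopifnot(v %in% g$nodes)
  e <- g$edges
  sort(unique(e$to[e$directed & e$from == v]))
}

#' @rdname parents
#' @export
neighbours <- function(g, v) {
  stopifnot(v %in% g$nodes)
  e <- g$edges
  sort(unique(c(e$to[e$from == v], e$from[e$to == v])))
}

ancestors <- function(g, vs) {
  # vs included in the result
  e <- g$edges[g$edges$directed, , drop = FALSE]
  seen <- unique(vs)
  frontier <- seen
  while (length(frontier)) {
    pa <- unique(e$from[e$to %in% frontier])
    frontier <- setdiff(pa, seen)
    seen <- union(seen, frontier)
  }
  seen
}

descendants <- function(g, vs) {
  e <- g$edges[g$edges$directed, , drop = FALSE]
  seen <- unique(vs)
  frontier <- seen
  while (length(frontier)) {
    ch <- unique(e$to[e$from %in% frontier])
    frontier <- setdiff(ch, seen)
    seen <- union(seen, frontier)
  }
  seen
}

#' Read and write edge lists
#'
#' Graphs round-trip as two-column (plus orientation) tab-separated edge
#' lists: columns `from`, `to`, `orientation` with orientation in
#' `{directed, undirected}`. Isolated nodes are preserved through an optional
#' `#nodes:` header comment.
#'
#' @param g A `causal_graph`.
#' @param path File path.
#' @return `write_edge_list()` returns `path` invisibly; `read_edge_list()`
#'   returns a `causal_graph`.
#' @export
write_edge_list <- function(g, path) {
  lines <- c(
    paste0("#nodes: ", paste(g$nodes, collapse = ",")),
    "from\tto\torientation"
  )
  if (nrow(g$edges)) {
    lines <- c(lines, paste(g$edges$from, g$edges$to,
                            ifelse(g$edges$directed, "directed", "undirected"),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  nodes <- character(0)
  hdr <- grep("^#nodes:", lines, value = TRUE)
  if (length(hdr)) {
    nodes <- strsplit(sub("^#nodes:\\s*", "", hdr[1]), ",")[[1]]
    nodes <- trimws(nodes)
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(tab))) abort("edge list needs from/to columns")
  directed <- if ("orientation" %in% names(tab)) tab$orientation == "directed" else TRUE
  nodes <- union(nodes, c(tab$from, tab$to))
  causal_graph(nodes, tibble(from = tab$from, to = tab$to, directed = directed))
}

#' The published 15-edge myopia causal graph
#'
#' The directed acyclic graph over the 16 cohort features that the discovery
#' stage recovers on the real pediatric-myopia cohort: six variables (PWG,
#' GENDER, NAR, DAR, K1, K2) are direct causes of both axial length (AL) and
#' cycloplegic refraction (CR); HEIGHT and REDM affect AL only; AL is a direct
#' cause of CR; CB, EGG, NW, PULSE, WHIM and DTO carry no edges.
#'
#' @param with_outcome If `TRUE`, append the binary outcome node `"Myopia"`
#'   as a child of CR (the label is a deterministic threshold of CR), which
#'   makes treatment-to-outcome backdoor queries well-posed.
#' @return A finalized `causal_graph` with 15 edges (16 with the outcome).
#' @examples
#' g <- myopia_reference_graph()
#' classify_units(g, g$nodes)
#' @export
myopia_reference_graph <- function(with_outcome = FALSE) {
  sources6 <- c("PWG", "GENDER", "NAR", "DAR", "K1", "K2")
  edges <- tibble(
    from = c(rep(sources6, each = 2), "HEIGHT", "REDM", "AL"),
    to = c(rep(c("AL", "CR"), times = 6), "AL", "AL", "CR"),
    directed = TRUE
  )
  nodes <- myopia_feature_names()
  if (with_outcome) {
    nodes <- c(nodes, "Myopia")
    edges <- dplyr::bind_rows(edges, tibble(from = "CR", to = "Myopia", directed = TRUE))
  }
  causal_graph(nodes, edges)
}

#' Directed part of a mixed graph
#'
#' Drops any undirected leftovers a discovery run could not orient,
#' warning how many were excluded. Path-based attribution and unit
#' classification require a fully directed acyclic graph; dropping the
#' unresolved edges (rather than orienting them arbitrarily) is the
#' conservative reading of a CPDAG.
#'
#' @param g A `causal_graph`.
#' @return A `causal_graph` with only the directed edges.
#' @export
directed_part <- function(g) {
  nu <- sum(!g$edges$directed)
  if (nu > 0) {
    warn(sprintf("dropping %d undirected edge(s) that orientation could not resolve", nu))
  }
  causal_graph(g$nodes, g$edges[g$edges$directed, , drop = FALSE])
}
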