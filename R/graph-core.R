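# Graph substrate: construction, I/O, distances, summary statistics.
# Graphs are undirected igraph objects with vertex ids 1..n.

#' Build a graph from a plain-text edge list
#'
#' Parses the package's edge-list dialect: one edge per line as two
#' whitespace-separated integer tokens, `#` starts a comment, blank
#' lines are ignored, and an optional first line `n=<int>` declares the
#' vertex count (needed only to preserve isolated vertices).  Vertex
#' labels in the file may be arbitrary non-negative integers (0- or
#' 1-based both work); they are remapped to `1..n` in order of first
#' appearance.  Duplicate edges are collapsed; self-loops are an error.
#'
#' @param text Character scalar (possibly multi-line) or character
#'   vector of lines.
#' @return An undirected [igraph][igraph::graph] object.
#' @examples
#' g <- graph_from_edge_list("0 1\n1 2")
#' igraph::vcount(g)  # 3
#' @export
graph_from_edge_list <- function(text) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  n_declared <- NA_integer_
  if (length(lines) && grepl("^n\\s*=\\s*[0-9]+$", lines[[1]])) {
    n_declared <- as.integer(sub("^n\\s*=\\s*", "", lines[[1]]))
    lines <- lines[-1]
  }

  ends <- matrix(character(), 0, 2)
  if (length(lines)) {
    toks <- strsplit(lines, "\\s+")
    bad <- vapply(toks, length, 1L) != 2L
    if (any(bad)) {
      stop("edge-list format error: expected two tokens per line, got: ",
           lines[bad][[1]])
    }
    ends <- do.call(rbind, toks)
    if (any(!grepl("^[0-9]+$", ends))) {
      stop("edge-list format error: non-integer vertex token")
    }
  }

  labels <- unique(as.vector(t(ends)))   # first-appearance order
  n <- length(labels)
  if (!is.na(n_declared)) {
    if (n_declared < n) stop("declared n= smaller than number of labels seen")
    n <- n_declared
  }
  if (nrow(ends)) {
    u <- match(ends[, 1], labels)
    v <- match(ends[, 2], labels)
    if (any(u == v)) stop("edge-list format error: self-loop")
    em <- cbind(pmin(u, v), pmax(u, v))
    em <- unique(em)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(em))
  } else {
    g <- igraph::make_empty_graph(max(n, 0L), directed = FALSE)
  }
  g
}

#' Write a graph in the package's edge-list dialect
#'
#' @param g An igraph object.
#' @param path File path; if `NULL` the lines are returned invisibly.
#' @return Invisibly, the character vector of lines written.
#' @export
write_edge_list <- function(g, path = NULL) {
  el <- sorted_edges(g)
  lines <- c(sprintf("n=%d", igraph::vcount(g)),
             sprintf("%d %d", el[, 1], el[, 2]))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Parametric generators for the named graph families
#'
#' Families and their deterministic labelings:
#' \describe{
#'   \item{`path`}{`params = n`; vertices `1..n` along the path.}
#'   \item{`cycle`}{`params = n` (`n >= 3`); vertices `1..n` around the cycle.}
#'   \item{`star`}{`params = n` (`n >= 2`); hub is vertex 1.}
#'   \item{`bistar`}{`params = c(m, n)` (`m, n >= 1`): two adjacent
#'     centres, vertex 1 carrying `m` pendant leaves and vertex 2
#'     carrying `n`; leaves of vertex 1 come first.}
#'   \item{`complete`}{`params = n`.}
#'   \item{`cycle_with_stars`}{`params = list(r, t)` with `r >= 3` and
#'     `t` a vector of `r` pendant-star sizes `t_i >= 0`: cycle vertices
#'     `1..r`, then the `t_1` leaves of vertex 1, the `t_2` leaves of
#'     vertex 2, and so on.}
#' }
#'
#' @param family One of `"path"`, `"cycle"`, `"star"`, `"bistar"`,
#'   `"complete"`, `"cycle_with_stars"`.
#' @param params Numeric vector (or `list(r, t)` for
#'   `cycle_with_stars`); see Details.
#' @return An igraph object.
#' @examples
#' named_graph("star", 5)          # S5: 5 vertices, hub degree 4
#' named_graph("bistar", c(2, 3))  # 7 vertices
#' @export
named_graph <- function(family, params) {
  family <- match.arg(family, c("path", "cycle", "star", "bistar",
                                "complete", "cycle_with_stars"))
  switch(family,
    path = {
      n <- as.integer(params[[1]])
      if (is.na(n) || n < 1) stop("path needs n >= 1")
      g <- igraph::make_empty_graph(n, directed = FALSE)
      if (n > 1) g <- igraph::add_edges(g, rbind(1:(n - 1), 2:n))
      g
    },
    cycle = {
      n <- as.integer(params[[1]])
      if (is.na(n) || n < 3) stop("cycle needs n >= 3")
      igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                        rbind(1:n, c(2:n, 1)))
    },
    star = {
      n <- as.integer(params[[1]])
      if (is.na(n) || n < 2) stop("star needs n >= 2")
      igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                        rbind(1L, 2:n))
    },
    bistar = {
      p <- as.integer(unlist(params))
      if (length(p) != 2 || any(is.na(p)) || any(p < 1)) {
        stop("bistar needs params c(m, n) with m, n >= 1")
      }
      m <- p[1]; n <- p[2]
      g <- igraph::make_empty_graph(m + n + 2L, directed = FALSE)
      leaves1 <- if (m > 0) 2L + seq_len(m) else integer()
      leaves2 <- if (n > 0) 2L + m + seq_len(n) else integer()
      igraph::add_edges(g, c(rbind(1L, 2L),
                             rbind(rep(1L, m), leaves1),
                             rbind(rep(2L, n), leaves2)))
    },
    complete = {
      n <- as.integer(params[[1]])
      if (is.na(n) || n < 1) stop("complete needs n >= 1")
      igraph::make_full_graph(n)
    },
    cycle_with_stars = {
      if (!is.list(params) || length(params) != 2) {
        stop("cycle_with_stars needs list(r, t)")
      }
      r <- as.integer(params[[1]]); tsz <- as.integer(params[[2]])
      if (is.na(r) || r < 3) stop("cycle_with_stars needs r >= 3")
      if (length(tsz) != r || any(is.na(tsz)) || any(tsz < 0)) {
        stop("cycle_with_stars needs r pendant-star sizes t_i >= 0")
      }
      n <- r + sum(tsz)
      g <- igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                             rbind(1:r, c(2:r, 1L)))
      nxt <- r
      for (i in seq_len(r)) {
        if (tsz[i] > 0) {
          g <- igraph::add_edges(g, rbind(i, nxt + seq_len(tsz[i])))
          nxt <- nxt + tsz[i]
        }
      }
      g
    })
}

#' Parse a compact graph description
#'
#' Accepts either a named-family string (`"path:8"`, `"cycle:5"`,
#' `"star:6"`, `"bistar:2,3"`, `"complete:4"`, `"cstars:3:3,0,0"`) or a
#' path to an edge-list file.
#'
#' @param spec Character scalar.
#' @return An igraph object.
#' @export
parse_graph_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  if (grepl("^(path|cycle|star|bistar|complete|cstars):", spec)) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    fam <- parts[1]
    if (fam == "cstars") {
      r <- as.integer(parts[2])
      tsz <- as.integer(strsplit(parts[3], ",", fixed = TRUE)[[1]])
      return(named_graph("cycle_with_stars", list(r, tsz)))
    }
    params <- as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    fam <- if (fam == "cstars") "cycle_with_stars" else fam
    return(named_graph(fam, params))
  }
  if (!file.exists(spec)) stop("not a named-graph spec and not a file: ", spec)
  graph_from_edge_list(paste(readLines(spec), collapse = "\n"))
}

#' All-pairs shortest-path distances
#'
#' Unweighted breadth-first-search distances.  Disconnected pairs carry
#' `Inf`; callers that require connectivity must check it themselves.
#'
#' @param g An igraph object.
#' @return An `n x n` numeric matrix, symmetric with zero diagonal.
#' @export
all_pairs_distances <- function(g) {
  igraph::distances(g, algorithm = "unweighted")
}

# Edges as a 2-column matrix with u < v, ordered lexicographically.
# Every per-edge accumulation in the package iterates in this order so
# floating-point sums are reproducible.
sorted_edges <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) return(matrix(integer(), 0, 2))
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

# |N(u) \cap N(v)| for every edge, in sorted_edges() order.
common_neighbor_counts <- function(g) {
  el <- sorted_edges(g)
  if (nrow(el) == 0) return(integer())
  adj <- igraph::as_adj_list(g)
  vapply(seq_len(nrow(el)), function(i) {
    length(intersect(adj[[el[i, 1]]], adj[[el[i, 2]]]))
  }, integer(1))
}

#' Summary statistics of a graph
#'
#' Degree sequence, eccentricities, diameter, triangle count,
#' bipartiteness and connectivity.  The triangle count is obtained by
#' common-neighbour counting over the edges, using the identity that
#' the common-neighbour counts over all edges sum to three times the
#' number of triangles.
#'
#' @param g An igraph object.
#' @return A list of class `"graph_stats"` with elements `n`, `m`,
#'   `degrees`, `eccentricity` (all `NA` when disconnected), `diameter`,
#'   `triangles`, `bipartite`, `connected`.
#' @export
graph_stats <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  connected <- n <= 1 || igraph::is_connected(g)
  if (connected && n >= 1) {
    D <- all_pairs_distances(g)
    ecc <- apply(D, 1, max)
    diam <- max(ecc)
  } else {
    ecc <- rep(NA_real_, n)
    diam <- NA_real_
  }
  t_g <- sum(common_neighbor_counts(g)) / 3
  stopifnot(t_g == round(t_g))
  out <- list(n = n, m = m,
              degrees = igraph::degree(g),
              eccentricity = ecc,
              diameter = diam,
              triangles = as.integer(round(t_g)),
              bipartite = igraph::bipartite_mapping(g)$res,
              connected = connected)
  class(out) <- "graph_stats"
  out
}

#' @export
print.graph_stats <- function(x, ...) {
  cat(sprintf("graph: n=%d m=%d connected=%s bipartite=%s\n",
              x$n, x$m, x$connected, x$bipartite))
  cat(sprintf("diameter=%s triangles=%d\n",
              format(x$diameter), x$triangles))
  cat("degrees:", paste(x$degrees, collapse = " "), "\n")
  invisible(x)
}
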