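# The four classical graph products, their SDZ bounds and equality
# conditions.  Vertex naming is part of the contract so downstream
# cut-count checks are reproducible:
#   join:          G1 vertices 1..n1, then G2 vertices n1+1..n1+n2;
#   corona:        G1 vertices 1..n1, then copy i of G2 occupying
#                  n1 + (i-1)*n2 + (1..n2);
#   cartesian/lex: pair (i, j) maps to (i-1)*n2 + j.

#' Construct a graph product
#'
#' * `join` (`G1 + G2`) — disjoint union plus every cross edge;
#' * `corona` (`G1 o G2`) — one copy of `G2` per vertex of `G1`, each
#'   copy fully joined to its host vertex;
#' * `cartesian` (`G1 x G2`) — edges move along one coordinate at a time;
#' * `lexicographic` (`G1[G2]`) — `(i, j) ~ (k, l)` iff `ik` is an edge
#'   of `G1`, or `i == k` and `jl` an edge of `G2`.
#'
#' @param kind One of `"join"`, `"corona"`, `"cartesian"`,
#'   `"lexicographic"`.
#' @param g1,g2 igraph objects with at least one vertex each.
#' @return An igraph object; see the file header for vertex naming.
#' @examples
#' igraph::isomorphic(product_graph("cartesian",
#'                                  named_graph("complete", 2),
#'                                  named_graph("complete", 2)),
#'                    named_graph("cycle", 4))
#' @export
product_graph <- function(kind, g1, g2) {
  kind <- match.arg(kind, c("join", "corona", "cartesian", "lexicographic"))
  n1 <- igraph::vcount(g1); n2 <- igraph::vcount(g2)
  if (n1 < 1 || n2 < 1) stop("both factors need at least one vertex")
  e1 <- sorted_edges(g1); e2 <- sorted_edges(g2)
  edges <- switch(kind,
    join = {
      cross <- cbind(rep(seq_len(n1), each = n2),
                     n1 + rep(seq_len(n2), times = n1))
      rbind(e1, e2 + n1, cross)
    },
    corona = {
      blocks <- lapply(seq_len(n1), function(i) {
        off <- n1 + (i - 1L) * n2
        rbind(if (nrow(e2)) e2 + off else NULL,
              cbind(rep(i, n2), off + seq_len(n2)))
      })
      rbind(e1, do.call(rbind, blocks))
    },
    cartesian = {
      id <- function(i, j) (i - 1L) * n2 + j
      a <- if (nrow(e2)) do.call(rbind, lapply(seq_len(n1), function(i) {
        cbind(id(i, e2[, 1]), id(i, e2[, 2]))
      })) else NULL
      b <- if (nrow(e1)) do.call(rbind, lapply(seq_len(n2), function(j) {
        cbind(id(e1[, 1], j), id(e1[, 2], j))
      })) else NULL
      rbind(a, b)
    },
    lexicographic = {
      id <- function(i, j) (i - 1L) * n2 + j
      within <- if (nrow(e2)) do.call(rbind, lapply(seq_len(n1), function(i) {
        cbind(id(i, e2[, 1]), id(i, e2[, 2]))
      })) else NULL
      across <- if (nrow(e1)) do.call(rbind, lapply(seq_len(nrow(e1)), function(r) {
        i <- e1[r, 1]; k <- e1[r, 2]
        cbind(rep(id(i, seq_len(n2)), each = n2),
              rep(id(k, seq_len(n2)), times = n2))
      })) else NULL
      rbind(within, across)
    })
  ntot <- switch(kind,
    join = n1 + n2,
    corona = n1 * (1L + n2),
    cartesian = , lexicographic = n1 * n2)
  g <- igraph::make_empty_graph(ntot, directed = FALSE)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::simplify(g)
}

# SDD with the two endpoint degrees corrected by the common-neighbour
# count of the edge: sum over edges of
#   (d(u)-|N(uv)|)/(d(v)-|N(uv)|) + reciprocal.
# Equals SDD(G) exactly when every edge has equal endpoint degrees or
# no common neighbour; always >= the plain degree ratio term-wise.
sdd_common_neighbor_sum <- function(g) {
  el <- sorted_edges(g)
  if (nrow(el) == 0) return(0)
  deg <- igraph::degree(g)
  cn <- common_neighbor_counts(g)
  a <- deg[el[, 1]] - cn
  b <- deg[el[, 2]] - cn
  stopifnot(all(a >= 1), all(b >= 1))
  sum(a / b + b / a)
}

# SDD extended to edgeless factors (empty sum), needed for corona with
# a single-vertex inner factor.
sdd_or_zero <- function(g) {
  if (igraph::ecount(g) == 0) 0 else companion_index(g, "SDD")
}

sdz_or_zero <- function(g) {
  if (igraph::ecount(g) == 0) 0 else sdz(g)
}

#' SDZ bound of a graph product
#'
#' Returns the proved right-hand side for the product's SDZ:
#' \describe{
#'   \item{join}{\eqn{SDZ(G_1 + G_2) \ge SDD(G_1) + SDD(G_2) + 2 n_1 n_2}.}
#'   \item{corona}{\eqn{SDZ(G_1 \circ G_2) \ge SDZ(G_1) + n_1 SDD(G_2) +
#'     n_1 n_2 (Q + 1/Q)} with \eqn{Q = n_1 + n_1 n_2 - n_2}.}
#'   \item{cartesian}{\eqn{SDZ(G_1 \times G_2) = n_2 SDZ(G_1) + n_1 SDZ(G_2)}
#'     — an identity, `exact = TRUE`.}
#'   \item{lexicographic}{\eqn{SDZ(G_1[G_2]) \ge n_1 SDD(G_2) + 2 m_1 n_2^2}.}
#' }
#'
#' @inheritParams product_graph
#' @return A list with `bound` (numeric) and `exact` (logical, `TRUE`
#'   only for the Cartesian product).
#' @export
product_bound <- function(kind, g1, g2) {
  kind <- match.arg(kind, c("join", "corona", "cartesian", "lexicographic"))
  n1 <- igraph::vcount(g1); n2 <- igraph::vcount(g2)
  m1 <- igraph::ecount(g1)
  if (n1 < 1 || n2 < 1) stop("both factors need at least one vertex")
  switch(kind,
    join = list(bound = sdd_or_zero(g1) + sdd_or_zero(g2) + 2 * n1 * n2,
                exact = FALSE),
    corona = {
      q <- n1 + n1 * n2 - n2
      list(bound = sdz_or_zero(g1) + n1 * sdd_or_zero(g2) +
             n1 * n2 * (q + 1 / q),
           exact = FALSE)
    },
    cartesian = list(bound = n2 * sdz_or_zero(g1) + n1 * sdz_or_zero(g2),
                     exact = TRUE),
    lexicographic = list(bound = n1 * sdd_or_zero(g2) + 2 * m1 * n2^2,
                         exact = FALSE))
}

is_regular <- function(g) {
  d <- igraph::degree(g)
  length(d) == 0 || all(d == d[1])
}

is_complete_graph <- function(g) {
  n <- igraph::vcount(g)
  igraph::ecount(g) == n * (n - 1) / 2
}

#' Stated equality condition of a product bound
#'
#' * join — both factors regular, say `k`- and `k'`-regular, with
#'   `n1 - k == n2 - k'`;
#' * corona — `G2` complete (sufficient condition);
#' * lexicographic — `G2` regular and `G1` distance-balanced.
#'
#' The Cartesian product is an identity, so asking for its equality
#' condition is an error.
#'
#' @inheritParams product_graph
#' @return Logical scalar.
#' @export
product_equality_condition <- function(kind, g1, g2) {
  kind <- match.arg(kind, c("join", "corona", "cartesian", "lexicographic"))
  switch(kind,
    join = {
      d1 <- igraph::degree(g1); d2 <- igraph::degree(g2)
      is_regular(g1) && is_regular(g2) &&
        (igraph::vcount(g1) - d1[1]) == (igraph::vcount(g2) - d2[1])
    },
    corona = is_complete_graph(g2),
    cartesian = stop("the Cartesian product bound is an identity; no equality condition"),
    lexicographic = is_regular(g2) && is_distance_balanced(g1))
}
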