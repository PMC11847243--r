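# Exhaustive enumeration of small graphs, one representative per
# isomorphism class.  Canonical forms come from igraph's BLISS-based
# canonical_permutation(); the canonical edge-list string doubles as the
# deterministic sort key.

# Canonical key: relabel by the canonical permutation and flatten the
# sorted edge list.  Two graphs get the same key iff isomorphic.
canonical_key <- function(g) {
  p <- igraph::canonical_permutation(g)$labeling
  gc <- igraph::permute(g, p)
  el <- sorted_edges(gc)
  paste0(igraph::vcount(g), "|", paste(t(el), collapse = ","))
}

# Dedup a list of graphs by canonical key; returns them sorted by key.
dedup_canonical <- function(graphs) {
  if (!length(graphs)) return(graphs)
  keys <- vapply(graphs, canonical_key, character(1))
  keep <- !duplicated(keys)
  graphs <- graphs[keep]
  graphs[order(keys[keep], method = "radix")]
}

#' Enumerate free trees
#'
#' Generates exactly one representative of every isomorphism class of
#' trees on `n` vertices, optionally restricted to a maximum degree.
#' Trees are grown by attaching a leaf to every vertex of every tree on
#' `n - 1` vertices, deduplicating by canonical form at each size; the
#' output is sorted by canonical encoding, so the order is
#' deterministic.
#'
#' @param n Number of vertices, `1 <= n <= 12`.
#' @param max_degree Maximum vertex degree allowed (default `Inf`).
#'   `max_degree = 4` with `n = 8` yields the 18 carbon skeletons of the
#'   octane isomers.
#' @return A list of igraph objects.
#' @examples
#' length(enumerate_trees(8))     # 23
#' length(enumerate_trees(8, 4))  # 18
#' @export
enumerate_trees <- function(n, max_degree = Inf) {
  n <- as.integer(n)
  if (is.na(n) || n < 1 || n > 12) stop("enumerate_trees supports 1 <= n <= 12")
  trees <- list(igraph::make_empty_graph(1, directed = FALSE))
  if (n > 1) {
    for (k in 2:n) {
      cands <- list()
      for (tr in trees) {
        for (v in seq_len(k - 1)) {
          cands[[length(cands) + 1]] <-
            igraph::add_edges(igraph::add_vertices(tr, 1), c(v, k))
        }
      }
      trees <- dedup_canonical(cands)
    }
  }
  if (is.finite(max_degree)) {
    trees <- Filter(function(g) max(igraph::degree(g)) <= max_degree, trees)
  }
  trees
}

#' Enumerate unicyclic graphs
#'
#' One representative per isomorphism class of connected graphs on `n`
#' vertices with exactly `n` edges (a single cycle).  Every unicyclic
#' graph is a spanning tree plus one extra edge, so the enumeration adds
#' each non-edge to each tree on `n` vertices and deduplicates by
#' canonical form.
#'
#' @param n Number of vertices, `3 <= n <= 9`.
#' @return A list of igraph objects, sorted by canonical encoding.
#' @examples
#' length(enumerate_unicyclic(4))  # 2: C4 and the triangle with a pendant
#' @export
enumerate_unicyclic <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3 || n > 9) stop("enumerate_unicyclic supports 3 <= n <= 9")
  cands <- list()
  for (tr in enumerate_trees(n)) {
    A <- igraph::as_adjacency_matrix(tr, sparse = FALSE)
    for (u in seq_len(n - 1)) {
      for (v in (u + 1):n) {
        if (!A[u, v]) {
          cands[[length(cands) + 1]] <- igraph::add_edges(tr, c(u, v))
        }
      }
    }
  }
  dedup_canonical(cands)
}

#' Enumerate connected graphs
#'
#' One representative per isomorphism class of connected simple graphs
#' on `n` vertices, by exhausting all edge subsets of the complete
#' graph.  Intended for exhaustive verification of inequalities on
#' small graphs; capped at `n <= 6` (112 classes).
#'
#' @param n Number of vertices, `1 <= n <= 6`.
#' @return A list of igraph objects, sorted by canonical encoding.
#' @export
enumerate_connected_graphs <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1 || n > 6) {
    stop("enumerate_connected_graphs supports 1 <= n <= 6")
  }
  if (n == 1) return(list(igraph::make_empty_graph(1, directed = FALSE)))
  pairs <- t(utils::combn(n, 2))
  np <- nrow(pairs)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (mask in 0:(2^np - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(np - 1))) != 0L)
    if (length(idx) < n - 1) next
    # union-find connectivity before paying for igraph construction
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in idx) {
      ru <- find(pairs[i, 1]); rv <- find(pairs[i, 2])
      if (ru != rv) parent[ru] <- rv
    }
    if (length(unique(vapply(seq_len(n), find, 1L))) != 1L) next
    g <- igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                           t(pairs[idx, , drop = FALSE]))
    key <- canonical_key(g)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1]] <- g
    }
  }
  keys <- vapply(out, canonical_key, character(1))
  out[order(keys, method = "radix")]
}
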