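# Independent oracles used to cross-check the package's computations.
# These deliberately avoid the package's own code paths: distances come
# from a hand-written Floyd-Warshall, tree counts from brute force over
# Prufer sequences, unicyclic counts from brute force over fixed-size
# edge subsets.

# Floyd-Warshall all-pairs distances from the adjacency matrix.
fw_distances <- function(g) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# SDZ recomputed from scratch on Floyd-Warshall distances.
sdz_fw <- function(g) {
  D <- fw_distances(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(el))) {
    du <- D[el[i, 1], ]; dv <- D[el[i, 2], ]
    nu <- sum(du < dv); nv <- sum(dv < du)
    total <- total + nu / nv + nv / nu
  }
  total
}

oracle_canonical_key <- function(g) {
  gc <- igraph::permute(g, igraph::canonical_permutation(g)$labeling)
  el <- igraph::as_edgelist(gc, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste(t(el), collapse = ",")
}

prufer_decode <- function(pr, n) {
  deg <- tabulate(pr, n) + 1L
  edges <- matrix(0L, n - 1L, 2L)
  alive <- rep(TRUE, n)
  for (i in seq_along(pr)) {
    l <- which(alive & deg == 1L)[1]
    edges[i, ] <- c(l, pr[i])
    alive[l] <- FALSE
    deg[l] <- 0L
    deg[pr[i]] <- deg[pr[i]] - 1L
  }
  edges[n - 1L, ] <- which(alive & deg == 1L)
  edges
}

# Number of isomorphism classes of trees on n vertices, by decoding
# every Prufer sequence and counting distinct canonical forms.
count_free_trees_brute <- function(n) {
  if (n <= 2) return(1L)
  seen <- new.env(parent = emptyenv())
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  for (i in seq_len(nrow(grid))) {
    e <- prufer_decode(grid[i, ], n)
    g <- igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE), t(e))
    key <- oracle_canonical_key(g)
    if (is.null(seen[[key]])) seen[[key]] <- TRUE
  }
  length(ls(seen))
}

# Number of isomorphism classes of connected graphs on n vertices with
# exactly n edges, by brute force over all n-subsets of vertex pairs.
count_unicyclic_brute <- function(n) {
  pairs <- t(utils::combn(n, 2))
  subs <- utils::combn(nrow(pairs), n)
  seen <- new.env(parent = emptyenv())
  for (j in seq_len(ncol(subs))) {
    idx <- subs[, j]
    g <- igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                           t(pairs[idx, , drop = FALSE]))
    if (!igraph::is_connected(g)) next
    key <- oracle_canonical_key(g)
    if (is.null(seen[[key]])) seen[[key]] <- TRUE
  }
  length(ls(seen))
}

# Seeded random connected G(n, p) graph (rejection sampling).
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (n == 1 || igraph::is_connected(g)) return(g)
  }
}

# A reusable matrix of small test graphs covering the named families.
standard_test_graphs <- function() {
  c(list(named_graph("path", 2), named_graph("path", 5), named_graph("path", 8),
         named_graph("cycle", 4), named_graph("cycle", 5), named_graph("cycle", 7),
         named_graph("star", 5), named_graph("star", 9),
         named_graph("bistar", c(2, 3)), named_graph("bistar", c(1, 5)),
         named_graph("complete", 4), named_graph("complete", 6),
         named_graph("cycle_with_stars", list(3L, c(3L, 0L, 0L))),
         named_graph("cycle_with_stars", list(4L, c(2L, 1L, 0L, 1L))),
         igraph::make_full_bipartite_graph(2, 3),
         igraph::make_full_bipartite_graph(3, 3)))
}
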