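test_that("cut counts classify every vertex exactly once", {
  k3 <- edge_cut_counts(named_graph("complete", 3), c(1, 2))
  expect_equal(c(k3$n_u, k3$n_v, k3$n_0), c(1, 1, 1))

  c4 <- edge_cut_counts(named_graph("cycle", 4), c(1, 2))
  expect_equal(c(c4$n_u, c4$n_v, c4$n_0), c(2, 2, 0))

  p8 <- edge_cut_counts(named_graph("path", 8), c(1, 2))
  expect_equal(c(p8$n_u, p8$n_v, p8$n_0), c(1, 7, 0))

  expect_error(edge_cut_counts(named_graph("path", 4), c(1, 3)), "not an edge")
  expect_error(edge_cut_counts(graph_from_edge_list("0 1\n2 3"), c(1, 2)),
               "connected")

  set.seed(7)
  for (i in 1:20) {
    g <- random_connected_graph(sample(3:15, 1))
    ct <- edge_cut_table(g)
    expect_true(all(ct$n_u + ct$n_v + ct$n_0 == igraph::vcount(g)))
    expect_true(all(ct$n_u >= 1 & ct$n_v >= 1))
  }
})

test_that("SDZ reproduces the closed values of the named examples", {
  expect_equal(sdz(named_graph("star", 5)), 17)
  expect_equal(sdz(named_graph("complete", 4)), 12)
  expect_equal(sdz(named_graph("path", 8)), 962 / 35, tolerance = 1e-12)
  expect_equal(sdz(named_graph("bistar", c(2, 3))), 395 / 12, tolerance = 1e-12)
  expect_error(sdz(graph_from_edge_list("0 1\n2 3")), "connected")
})

test_that("companion indices match hand-computed values", {
  p8 <- named_graph("path", 8)
  expect_equal(companion_index(p8, "SDD"), 15)
  expect_equal(companion_index(named_graph("complete", 3), "Sz"), 3)
  expect_equal(companion_index(named_graph("cycle", 5), "SDE"), 10)
  for (n in 3:6) {
    kn <- named_graph("complete", n)
    expect_equal(companion_index(kn, "RSz"), n * (n - 1) / 2)
  }
  # RM2 of a path: end edges 1/2 each, inner edges 1/4
  expect_equal(companion_index(named_graph("path", 5), "RM2"), 2 * 0.5 + 2 * 0.25)
  expect_error(companion_index(p8, "nope"))
})

test_that("the generalized symmetric division index specializes correctly", {
  for (g in list(named_graph("path", 6), named_graph("bistar", c(2, 3)),
                 named_graph("cycle_with_stars", list(3L, c(3L, 0L, 0L))))) {
    deg <- igraph::degree(g)
    expect_equal(gsdd(g, function(v, e) deg[v]), companion_index(g, "SDD"),
                 tolerance = 1e-12)

    D <- all_pairs_distances(g)
    f_cut <- function(v, e) {
      other <- if (v == e[1]) e[2] else e[1]
      sum(D[v, ] < D[other, ])
    }
    expect_equal(gsdd(g, f_cut), sdz(g), tolerance = 1e-12)

    expect_equal(gsdd(g, function(v, e) pi), 2 * igraph::ecount(g),
                 tolerance = 1e-12)
  }
  expect_error(gsdd(named_graph("path", 3), function(v, e) 0), "positive")
  expect_error(gsdd(named_graph("path", 3), function(v, e) -1), "positive")
})

test_that("Hosoya root indices follow the stated root convention", {
  expect_equal(hosoya_m_indices(named_graph("complete", 2)),
               list(M1 = 0, M2 = 0))
  expect_equal(hosoya_m_indices(named_graph("complete", 3))$M1, 0)
  # P3: leaves have H = x + x^2 with roots {0, -1}; centre has 2x
  p3 <- hosoya_m_indices(named_graph("path", 3))
  expect_equal(p3$M1, 2, tolerance = 1e-9)
  expect_equal(p3$M2, 2, tolerance = 1e-9)
  # star: leaves have H = x + (n-2)x^2, root modulus 1/(n-2) each
  s5 <- hosoya_m_indices(named_graph("star", 5))
  expect_equal(s5$M1, 4 * (1 / 3), tolerance = 1e-9)
  expect_equal(s5$M2, 4 * sqrt(1 / 3), tolerance = 1e-9)
})

test_that("Hosoya root indices reproduce the published octane columns", {
  d <- octane_dataset()
  h <- lapply(d$skeleton, hosoya_m_indices)
  expect_true(all(abs(vapply(h, `[[`, numeric(1), "M1") - d$M1) <= 0.01))
  expect_true(all(abs(vapply(h, `[[`, numeric(1), "M2") - d$M2) <= 0.01))
})

test_that("distance-balance detection is exact and matches SDZ = 2m", {
  for (n in 3:8) expect_true(is_distance_balanced(named_graph("cycle", n)))
  for (n in 2:6) expect_true(is_distance_balanced(named_graph("complete", n)))
  expect_false(is_distance_balanced(named_graph("path", 4)))

  graphs <- c(enumerate_connected_graphs(4), enumerate_connected_graphs(5))
  set.seed(42)
  for (i in 1:30) graphs <- c(graphs, list(random_connected_graph(sample(5:40, 1))))
  for (g in graphs) {
    if (igraph::ecount(g) == 0) next
    db <- is_distance_balanced(g)
    expect_equal(sdz(g) <= 2 * igraph::ecount(g) + 1e-9, db)
    expect_gte(sdz(g), 2 * igraph::ecount(g) - 1e-9)
  }
})

test_that("bipartite graphs have no equidistant vertices on any edge", {
  bip <- c(list(igraph::make_full_bipartite_graph(2, 3),
                igraph::make_full_bipartite_graph(3, 4),
                named_graph("cycle", 6), named_graph("cycle", 8)),
           enumerate_trees(6))
  for (g in bip) {
    ct <- edge_cut_table(g)
    expect_true(all(ct$n_0 == 0))
    # identity: SDZ = n^2 RSz - 2m for bipartite graphs
    expect_equal(sdz(g),
                 igraph::vcount(g)^2 * companion_index(g, "RSz") -
                   2 * igraph::ecount(g),
                 tolerance = 1e-9)
  }
})

test_that("SDZ agrees with the Floyd-Warshall oracle", {
  graphs <- standard_test_graphs()
  set.seed(99)
  for (i in 1:25) graphs <- c(graphs, list(random_connected_graph(sample(4:25, 1))))
  for (g in graphs) {
    expect_equal(sdz(g), sdz_fw(g), tolerance = 1e-12)
  }
})

test_that("AG2 dominates half the root of SDZ + 2m", {
  graphs <- c(standard_test_graphs(), enumerate_connected_graphs(5))
  for (g in graphs) {
    m <- igraph::ecount(g)
    if (m == 0) next
    ag2 <- companion_index(g, "AG2")
    lhs <- sqrt(sdz(g) + 2 * m) / 2
    if (m >= 2) expect_gt(ag2, lhs) else expect_gte(ag2, lhs - 1e-12)
  }
})
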