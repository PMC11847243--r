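CATALOG <- c("P3.1", "T3.1", "C3.1", "T4.1", "L4.2", "T4.3", "T4.4", "L4.3")

test_that("every catalog inequality holds on all small connected graphs", {
  graphs <- c(enumerate_connected_graphs(4), enumerate_connected_graphs(5))
  set.seed(1234)
  for (i in 1:60) graphs <- c(graphs, list(random_connected_graph(sample(4:15, 1))))
  for (g in graphs) {
    for (th in CATALOG) {
      r <- check_inequality(th, g)
      if (isTRUE(r$applicable)) {
        expect_true(r$holds,
                    info = sprintf("%s violated on n=%d m=%d", th, r$n, r$m))
      }
    }
  }
})

test_that("hypothesis checks gate inapplicable theorems instead of erroring", {
  k3 <- named_graph("complete", 3)
  expect_false(check_inequality("T3.1", k3)$applicable)   # has a triangle
  expect_false(check_inequality("C3.1", k3)$applicable)   # not bipartite
  expect_false(check_inequality("L4.2", named_graph("path", 4))$applicable)
  expect_false(check_inequality("T4.3", named_graph("path", 4))$applicable)
  expect_false(check_inequality("T4.4", named_graph("cycle", 5))$applicable)
  expect_true(check_inequality("T4.4", k3)$hypothesis_unverified)
})

test_that("equality cases land exactly where the theorems say", {
  # two-sided bound: cycles sit on the lower edge, stars on the upper
  r <- check_inequality("T4.1", named_graph("cycle", 6))
  expect_true(r$equality_lower)
  expect_equal(r$value, 12)
  r <- check_inequality("T4.1", named_graph("star", 7))
  expect_true(r$equality_upper)

  # common-neighbour identity on K4: 12 = 3 * 4 triangles
  r <- check_inequality("L4.3", named_graph("complete", 4))
  expect_equal(r$value, 12)
  expect_true(r$holds)

  # triangle-free diameter-2 graphs: reverse Szeged equals reverse Zagreb
  r <- check_inequality("T3.1", named_graph("cycle", 5))
  expect_equal(r$value, 1.25)
  expect_equal(r$upper, 1.25)
  expect_true(r$equality_upper)
  expect_true(r$equality_condition_met)
  # diameter > 2: strict gap and condition false
  r <- check_inequality("T3.1", named_graph("cycle", 7))
  expect_false(r$equality_upper)
  expect_false(r$equality_condition_met)

  # bipartite identity SDZ = n^2 RSz - 2m on C6
  c6 <- named_graph("cycle", 6)
  expect_equal(36 * companion_index(c6, "RSz") - 12, sdz(c6), tolerance = 1e-9)
  expect_true(check_inequality("C3.1", c6)$holds)

  # complete bipartite (diameter 2) attains C3.1 equality
  r <- check_inequality("C3.1", igraph::make_full_bipartite_graph(2, 3))
  expect_true(r$equality_upper)
  expect_true(r$equality_condition_met)
})

test_that("equality iff conditions hold in both directions on small graphs", {
  for (g in enumerate_connected_graphs(5)) {
    if (igraph::ecount(g) == 0) next
    r <- check_inequality("T4.1", g)
    expect_equal(r$equality_lower, is_distance_balanced(g))
    st <- graph_stats(g)
    is_star <- st$m == st$n - 1 && max(st$degrees) == st$n - 1
    expect_equal(r$equality_upper, is_star)
    if (st$triangles == 0 && st$n >= 3) {
      expect_equal(check_inequality("T3.1", g)$equality_upper,
                   st$diameter == 2)
    }
    if (st$bipartite && st$n >= 3) {
      expect_equal(check_inequality("C3.1", g)$equality_upper,
                   st$diameter == 2)
    }
    if (st$m == st$n) {
      expect_equal(check_inequality("L4.2", g)$equality_lower,
                   all(st$degrees == 2))
    }
  }
})

test_that("balanced splits minimize and extreme splits maximize the edge term", {
  # over all splits a + b = s, a/b + b/a is smallest at the most
  # balanced split and largest at (1, s - 1)
  for (s in 3:50) {
    a <- 1:(s - 1)
    term <- a / (s - a) + (s - a) / a
    expect_equal(which.max(term), 1L)
    expect_equal(min(term), term[floor(s / 2)], tolerance = 1e-12)
  }
})

test_that("the shifted-ratio comparison holds for all small integer triples", {
  for (a in 1:30) for (b in 1:a) for (cc in 0:(b - 1)) {
    lhs <- (a - cc) / (b - cc) + (b - cc) / (a - cc)
    rhs <- a / b + b / a
    expect_gte(lhs, rhs - 1e-12)
    if (a > b && cc > 0) expect_gt(lhs, rhs)
  }
})

test_that("tree extremal ordering: path min, star max, broom bistar non-star max", {
  for (n in 4:8) {
    rep <- tree_extremal_check(n)
    expect_true(rep$holds, info = paste("n =", n))
  }
  r7 <- tree_extremal_check(7)
  expect_equal(r7$min_value, sdz(named_graph("path", 7)), tolerance = 1e-9)
  expect_equal(r7$min_value, 22.3, tolerance = 1e-9)
  expect_equal(r7$nonstar_max_value, 33.7333, tolerance = 1e-4)
  expect_equal(r7$max_value, 37)
  expect_equal(tree_extremal_check(8)$max_value, 50)  # n^2 - 2n + 2
  expect_error(tree_extremal_check(3), "4 <= n")
})

test_that("unicyclic extremal graphs: cycle min at 2n, pendant-star triangle max", {
  for (n in 4:8) {
    rep <- unicyclic_extremal_check(n)
    expect_true(rep$holds, info = paste("n =", n))
    expect_equal(rep$min_value, 2 * n, tolerance = 1e-9)
  }
  expect_equal(unicyclic_extremal_check(6)$max_value, 26.1, tolerance = 1e-9)
  expect_error(unicyclic_extremal_check(10), "4 <= n")
})
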