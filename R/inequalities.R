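# Executable verifiers for the known inequalities and extremal results
# on the SDZ index.  Each checker returns a structured report rather
# than a bare logical, so hypothesis failures are visible and equality
# conditions can be audited.

EQ_TOL <- 1e-9

new_inequality_report <- function(theorem, g, value, lower = NA_real_,
                                  upper = NA_real_, strict_lower = FALSE,
                                  strict_upper = FALSE, applicable = TRUE,
                                  equality_lower = NA, equality_upper = NA,
                                  equality_condition_met = NA,
                                  hypothesis_unverified = FALSE,
                                  notes = character()) {
  holds <- NA
  if (applicable) {
    ok_lo <- is.na(lower) ||
      (if (strict_lower) value > lower else value >= lower - EQ_TOL)
    ok_hi <- is.na(upper) ||
      (if (strict_upper) value < upper else value <= upper + EQ_TOL)
    holds <- ok_lo && ok_hi
  }
  structure(list(
    theorem = theorem,
    n = igraph::vcount(g), m = igraph::ecount(g),
    value = value, lower = lower, upper = upper,
    holds = holds,
    equality_lower = equality_lower, equality_upper = equality_upper,
    equality_condition_met = equality_condition_met,
    applicable = applicable,
    hypothesis_unverified = hypothesis_unverified,
    notes = notes), class = "sdz_inequality")
}

#' @export
print.sdz_inequality <- function(x, ...) {
  cat(sprintf("[%s] n=%d m=%d: ", x$theorem, x$n, x$m))
  if (!x$applicable) {
    cat("inapplicable\n")
    return(invisible(x))
  }
  cat(sprintf("value=%.6g", x$value))
  if (!is.na(x$lower)) cat(sprintf(" lower=%.6g", x$lower))
  if (!is.na(x$upper)) cat(sprintf(" upper=%.6g", x$upper))
  cat(sprintf(" holds=%s", x$holds))
  if (x$hypothesis_unverified) cat(" (hypothesis unverified)")
  cat("\n")
  if (length(x$notes)) cat(" ", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

near <- function(a, b) is.finite(a) && is.finite(b) && abs(a - b) <= EQ_TOL

#' Check one named inequality on one graph
#'
#' The catalog (names follow the field's statement of each result):
#' \describe{
#'   \item{`P3.1`}{\eqn{SDZ(G) > \frac{1}{8}(\sqrt{32m+1}+1)} for every
#'     connected graph — the radical lower bound proved by squaring the
#'     arithmetic-geometric comparison.}
#'   \item{`T3.1`}{triangle-free, `n >= 3`: \eqn{RSz(G) \le RM2(G)},
#'     equality iff the diameter is 2.}
#'   \item{`C3.1`}{bipartite, `n >= 3`: \eqn{SDZ(G) \le n^2 RM2(G) - 2m},
#'     equality iff the diameter is 2.  (For bipartite graphs
#'     \eqn{SDZ = n^2 RSz - 2m} holds as an identity.)}
#'   \item{`T4.1`}{any connected graph:
#'     \eqn{2m \le SDZ(G) \le \frac{n^2-2n+2}{n-1} m}; lower equality
#'     iff distance-balanced, upper equality iff a star.}
#'   \item{`L4.2`}{non-tree (`m >= n`): \eqn{SDZ(G) \ge 2n}, equality
#'     iff a cycle.}
#'   \item{`T4.3`}{unicyclic (`m == n`): \eqn{2n \le SDZ(G) \le} the
#'     SDZ of the triangle with all `n - 3` leaves on one vertex (the
#'     derivation-consistent bound; the printed expression is recorded
#'     in `notes`).  Lower equality iff a cycle, upper iff that
#'     extremal graph.}
#'   \item{`T4.4`}{graphs with at least one triangle:
#'     \eqn{SDZ(G) < n^2 m + 9t^2(G) - 6nt(G) - 2m}.  Triangulation of
#'     the plane is not verified — only the triangle count enters the
#'     bound — so the report carries `hypothesis_unverified = TRUE`.}
#'   \item{`L4.3`}{identity, any graph:
#'     \eqn{\sum_{uv \in E}|N(u) \cap N(v)| = 3t(G)}.}
#' }
#'
#' @param theorem_id One of `"P3.1"`, `"T3.1"`, `"C3.1"`, `"T4.1"`,
#'   `"L4.2"`, `"T4.3"`, `"T4.4"`, `"L4.3"`.
#' @param g A connected igraph object.
#' @return An object of class `"sdz_inequality"`; see
#'   [new_inequality_report] fields in the source.  Inapplicable
#'   hypotheses yield `applicable = FALSE`, never an error.
#' @export
check_inequality <- function(theorem_id, g) {
  theorem_id <- match.arg(theorem_id, c("P3.1", "T3.1", "C3.1", "T4.1",
                                        "L4.2", "T4.3", "T4.4", "L4.3"))
  stop_if_disconnected(g)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  st <- graph_stats(g)

  switch(theorem_id,
    "P3.1" = {
      if (m < 1) {
        return(new_inequality_report("P3.1", g, NA_real_, applicable = FALSE))
      }
      new_inequality_report("P3.1", g, sdz(g),
                            lower = (sqrt(32 * m + 1) + 1) / 8,
                            strict_lower = TRUE)
    },
    "T3.1" = {
      if (st$triangles > 0 || n < 3) {
        return(new_inequality_report("T3.1", g, NA_real_, applicable = FALSE,
                                     notes = "needs triangle-free, n >= 3"))
      }
      rsz <- companion_index(g, "RSz")
      rm2 <- companion_index(g, "RM2")
      new_inequality_report("T3.1", g, rsz, upper = rm2,
                            equality_upper = near(rsz, rm2),
                            equality_condition_met = (st$diameter == 2))
    },
    "C3.1" = {
      if (!st$bipartite || n < 3) {
        return(new_inequality_report("C3.1", g, NA_real_, applicable = FALSE,
                                     notes = "needs bipartite, n >= 3"))
      }
      v <- sdz(g)
      up <- n^2 * companion_index(g, "RM2") - 2 * m
      new_inequality_report("C3.1", g, v, upper = up,
                            equality_upper = near(v, up),
                            equality_condition_met = (st$diameter == 2))
    },
    "T4.1" = {
      if (m < 1) {
        return(new_inequality_report("T4.1", g, NA_real_, applicable = FALSE))
      }
      v <- sdz(g)
      lo <- 2 * m
      up <- (n^2 - 2 * n + 2) / (n - 1) * m
      is_star <- m == n - 1 && max(st$degrees) == n - 1
      new_inequality_report("T4.1", g, v, lower = lo, upper = up,
                            equality_lower = near(v, lo),
                            equality_upper = near(v, up),
                            equality_condition_met =
                              is_distance_balanced(g) || is_star,
                            notes = sprintf("lower iff DB (%s), upper iff star (%s)",
                                            is_distance_balanced(g), is_star))
    },
    "L4.2" = {
      if (m < n) {
        return(new_inequality_report("L4.2", g, NA_real_, applicable = FALSE,
                                     notes = "needs a non-tree (m >= n)"))
      }
      v <- sdz(g)
      is_cycle <- m == n && all(st$degrees == 2)
      new_inequality_report("L4.2", g, v, lower = 2 * n,
                            equality_lower = near(v, 2 * n),
                            equality_condition_met = is_cycle)
    },
    "T4.3" = {
      if (m != n) {
        return(new_inequality_report("T4.3", g, NA_real_, applicable = FALSE,
                                     notes = "needs unicyclic (m == n)"))
      }
      v <- sdz(g)
      up <- if (n >= 4) sdz_closed_form("c3_star_max", n) else sdz(g)
      is_cycle <- all(st$degrees == 2)
      extremal <- igraph::isomorphic(
        g, named_graph("cycle_with_stars", list(3L, c(n - 3L, 0L, 0L))))
      new_inequality_report("T4.3", g, v, lower = 2 * n, upper = up,
                            equality_lower = near(v, 2 * n),
                            equality_upper = near(v, up),
                            equality_condition_met = is_cycle || extremal,
                            notes = sprintf("printed upper expression = %.6g",
                                            unicyclic_printed_upper(n)))
    },
    "T4.4" = {
      t_g <- st$triangles
      if (t_g < 1 || m < 1) {
        return(new_inequality_report("T4.4", g, NA_real_, applicable = FALSE,
                                     notes = "needs at least one triangle"))
      }
      new_inequality_report("T4.4", g, sdz(g),
                            upper = n^2 * m + 9 * t_g^2 - 6 * n * t_g - 2 * m,
                            strict_upper = TRUE,
                            hypothesis_unverified = TRUE,
                            notes = "planar triangulation not verified; bound uses t(G) only")
    },
    "L4.3" = {
      v <- sum(common_neighbor_counts(g))
      new_inequality_report("L4.3", g, v,
                            lower = 3 * st$triangles, upper = 3 * st$triangles,
                            equality_lower = TRUE, equality_upper = TRUE)
    })
}

#' Extremal trees for the SDZ index
#'
#' Enumerates every tree on `n` vertices and verifies the extremal
#' ordering: the path is the unique minimizer, the star the unique
#' maximizer, and among non-stars the broom bistar `S(1, n-3)` the
#' unique maximizer.
#'
#' @param n Number of vertices, `4 <= n <= 10`.
#' @return A list with the tree count, the extreme values, uniqueness
#'   flags, and `holds` summarizing the full ordering.
#' @export
tree_extremal_check <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 4 || n > 10) stop("tree_extremal_check supports 4 <= n <= 10")
  trees <- enumerate_trees(n)
  vals <- vapply(trees, sdz, numeric(1))
  path_g <- named_graph("path", n)
  star_g <- named_graph("star", n)
  bistar_g <- named_graph("bistar", c(1, n - 3))
  imin <- which(vals <= min(vals) + EQ_TOL)
  imax <- which(vals >= max(vals) - EQ_TOL)
  nonstar <- which(!vapply(trees, igraph::isomorphic, logical(1), graph2 = star_g))
  ns_vals <- vals[nonstar]
  ins_max <- nonstar[ns_vals >= max(ns_vals) - EQ_TOL]
  min_is_path <- length(imin) == 1 &&
    igraph::isomorphic(trees[[imin]], path_g)
  max_is_star <- length(imax) == 1 &&
    igraph::isomorphic(trees[[imax]], star_g)
  nonstar_max_is_bistar <- length(ins_max) == 1 &&
    igraph::isomorphic(trees[[ins_max]], bistar_g)
  list(n = n, n_trees = length(trees),
       min_value = min(vals), max_value = max(vals),
       nonstar_max_value = max(ns_vals),
       min_is_path = min_is_path,
       max_is_star = max_is_star,
       nonstar_max_is_bistar = nonstar_max_is_bistar,
       holds = min_is_path && max_is_star && nonstar_max_is_bistar &&
         max(ns_vals) < max(vals))
}

#' Extremal unicyclic graphs for the SDZ index
#'
#' Enumerates every unicyclic graph on `n` vertices and verifies that
#' the cycle `C_n` uniquely minimizes SDZ (value `2n`) and the triangle
#' with `n - 3` pendant leaves on one vertex uniquely maximizes it
#' (value `sdz_closed_form("c3_star_max", n)`).
#'
#' @param n Number of vertices, `4 <= n <= 9`.
#' @return A list with the class count, extreme values and flags.
#' @export
unicyclic_extremal_check <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 4 || n > 9) stop("unicyclic_extremal_check supports 4 <= n <= 9")
  graphs <- enumerate_unicyclic(n)
  vals <- vapply(graphs, sdz, numeric(1))
  cyc <- named_graph("cycle", n)
  ext <- named_graph("cycle_with_stars", list(3L, c(n - 3L, 0L, 0L)))
  imin <- which(vals <= min(vals) + EQ_TOL)
  imax <- which(vals >= max(vals) - EQ_TOL)
  min_is_cycle <- length(imin) == 1 && igraph::isomorphic(graphs[[imin]], cyc)
  max_is_c3star <- length(imax) == 1 && igraph::isomorphic(graphs[[imax]], ext)
  list(n = n, n_graphs = length(graphs),
       min_value = min(vals), max_value = max(vals),
       min_is_cycle = min_is_cycle,
       max_is_c3star = max_is_c3star,
       holds = min_is_cycle && max_is_c3star &&
         near(min(vals), 2 * n) &&
         near(max(vals), sdz_closed_form("c3_star_max", n)))
}
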