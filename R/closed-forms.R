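# Closed-form SDZ values for the named families.

#' Closed-form SDZ values
#'
#' Families:
#' \describe{
#'   \item{`star`}{`params = n` (`n >= 2`): \eqn{n^2 - 2n + 2}.}
#'   \item{`bistar`}{`params = c(m, n)`:
#'     \eqn{(m+n)\left(\frac{1}{m+n+1} + (m+n+1)\right) +
#'     \frac{m+1}{n+1} + \frac{n+1}{m+1}} on `m + n + 2` vertices.}
#'   \item{`complete`}{`params = n`: \eqn{n^2 - n}.}
#'   \item{`cycle`}{`params = n` (`n >= 3`): \eqn{2n} (cycles are
#'     distance-balanced with `m = n`).}
#'   \item{`c3_star_max`}{`params = n` (`n >= 4`): the SDZ value of the
#'     triangle carrying `n - 3` pendant leaves on one cycle vertex,
#'     the maximizer among unicyclic graphs:
#'     \eqn{(n-3)\frac{n^2-2n+2}{n-1} + 2\frac{n^2-4n+5}{n-2} + 2},
#'     i.e. the per-edge sum of the pendant, hub-cycle and far-cycle
#'     edge contributions.}
#' }
#'
#' @param family One of `"star"`, `"bistar"`, `"complete"`, `"cycle"`,
#'   `"c3_star_max"`.
#' @param params Numeric vector of family parameters.
#' @return A numeric scalar.
#' @examples
#' sdz_closed_form("star", 5)        # 17
#' sdz_closed_form("bistar", c(2, 3))
#' @export
sdz_closed_form <- function(family, params) {
  family <- match.arg(family, c("star", "bistar", "complete", "cycle",
                                "c3_star_max"))
  p <- as.numeric(unlist(params))
  switch(family,
    star = {
      n <- p[1]; if (is.na(n) || n < 2) stop("star needs n >= 2")
      n^2 - 2 * n + 2
    },
    bistar = {
      if (length(p) != 2 || any(is.na(p)) || any(p < 1)) {
        stop("bistar needs c(m, n), m, n >= 1")
      }
      m <- p[1]; n <- p[2]
      (m + n) * (1 / (m + n + 1) + (m + n + 1)) +
        (m + 1) / (n + 1) + (n + 1) / (m + 1)
    },
    complete = {
      n <- p[1]; if (is.na(n) || n < 2) stop("complete needs n >= 2")
      n^2 - n
    },
    cycle = {
      n <- p[1]; if (is.na(n) || n < 3) stop("cycle needs n >= 3")
      2 * n
    },
    c3_star_max = {
      n <- p[1]; if (is.na(n) || n < 4) stop("c3_star_max needs n >= 4")
      (n - 3) * (n^2 - 2 * n + 2) / (n - 1) +
        2 * (n^2 - 4 * n + 5) / (n - 2) + 2
    })
}

# The upper bound for unicyclic graphs as printed in its source; kept
# for transparency in reports.  It disagrees with the per-edge values
# of its own derivation (see the methods vignette); the derivation-
# consistent value is sdz_closed_form("c3_star_max", n).
unicyclic_printed_upper <- function(n) {
  (n - 3) * (n^2 - 2 * n + 2) / (n - 1) +
    2 * (n^2 - 2 * n + 4) / (n - 2) + 2
}
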