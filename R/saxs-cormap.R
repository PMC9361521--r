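# CorMap-style frame comparison: the longest run of consecutive same-sign
# point-wise differences between two curves, with an exact p-value for the
# null that each sign is an independent fair coin.

#' Exact tail probability of the longest same-sign run
#'
#' Probability that `n` independent fair signs contain a run of identical
#' signs of length at least `c`. Computed from the run-composition
#' recursion: the number of sign sequences whose longest run is below `c`
#' is `2 * C(n)` where `C` counts compositions of `n` into parts `< c`.
#' Evaluated in probability space for numerical stability at large `n`.
#'
#' @param n Number of points.
#' @param c Run length.
#' @return `P(longest run >= c)`.
#' @export
longest_run_pvalue <- function(n, c) {
  stopifnot(n >= 1, c >= 1)
  if (c == 1) {
    return(1)
  }
  if (c > n) {
    return(0)
  }
  # g(m) = C(m)/2^m with parts <= c-1; g(0) = 1
  g <- numeric(n + 1)
  g[1] <- 1
  halves <- 0.5^seq_len(c - 1)
  for (m in seq_len(n)) {
    kmax <- min(c - 1, m)
    g[m + 1] <- sum(halves[seq_len(kmax)] * g[m + 1 - seq_len(kmax)])
  }
  p_below <- 2 * g[n + 1]
  max(0, min(1, 1 - p_below))
}

#' Compare two scattering curves with the longest same-sign run statistic
#'
#' Computes the longest run of consecutive same-sign differences between
#' two curves on a common q-grid and its exact p-value under the
#' independent-fair-sign null. Zero differences are assigned alternating
#' signs in sequence order, a conservative tie-break that cannot create a
#' spurious long run.
#'
#' @param a,b Two [saxs_curve()]s on identical q-grids, at least 10 points.
#' @return A list with `longest_run`, `p_value`, `n`.
#' @export
#' @examples
#' q <- seq(0.01, 0.3, by = 0.01)
#' a <- saxs_curve(q, exp(-q^2 * 50), rep(1, length(q)))
#' b <- saxs_curve(q, exp(-q^2 * 50) + 0.001, rep(1, length(q)))
#' cormap_compare(a, b)$longest_run
cormap_compare <- function(a, b) {
  a <- as_saxs_curve(a)
  b <- as_saxs_curve(b)
  if (nrow(a) != nrow(b) || max(abs(a$q - b$q)) > 1e-9) {
    abort("curves must share a common q-grid")
  }
  n <- nrow(a)
  if (n < 10) abort("fewer than 10 points: run-length distribution unreliable")
  s <- sign(a$I - b$I)
  zeros <- which(s == 0)
  if (length(zeros) > 0) s[zeros] <- rep_len(c(1, -1), length(zeros))
  runs <- rle(s)
  longest <- max(runs$lengths)
  list(
    longest_run = longest,
    p_value = longest_run_pvalue(n, longest),
    n = n
  )
}
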