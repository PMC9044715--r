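#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that the population mean vector length is zero
#' (circular uniformity) against unimodal clustering, using `Z = n * rbar^2`.
#' The p-value uses the standard large-sample exponential series with first-
#' and second-order `1/n` corrections (Greenwood-Durand), clamped to
#' `[0, 1]`.
#'
#' @param sample an [angle_sample()] with at least 2 observations.
#' @return An object of classes `"circ_test"` and `"htest"` with elements
#'   `statistic` (Z), `p.value`, `method` and `n`.
#' @examples
#' rayleigh_test(angle_sample(c(0, 90, 180, 270), unit = "degrees")) # p = 1
#' @export
rayleigh_test <- function(sample) {
  sample <- angle_sample(sample)
  n <- sample$n
  if (n < 2) stop("Rayleigh test needs at least 2 angles")
  rbar <- mean_resultant(sample)$rbar
  z <- n * rbar^2
  p <- .rayleigh_p(z, n)
  structure(
    list(
      statistic = c(Z = z), p.value = p,
      method = "Rayleigh test of circular uniformity",
      data.name = sprintf("%d angles", n), n = n, mc_replicates = NULL
    ),
    class = c("circ_test", "htest")
  )
}

# Greenwood-Durand corrected series; vectorized over z (fixed n)
.rayleigh_p <- function(z, n) {
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  pmin(pmax(p, 0), 1)
}

# the second Hermans-Rasson variant's tuning constant, surfaced so it can be
# adjusted without touching the statistic's code
hr_constant <- 2.895

#' Hermans-Rasson test statistic
#'
#' The second Hermans-Rasson statistic, an omnibus measure of departure from
#' uniformity built from all ordered pairs of angular differences (including
#' the `i = j` terms):
#' `T = (1/n) * sum_ij ( ||theta_i - theta_j| - pi| - pi/2
#'      - 2.895 * (|sin(theta_i - theta_j)| - 2/pi) )`.
#' Depends only on pairwise differences, hence is rotation invariant. Large
#' values indicate clustering, including symmetric multimodal clustering that
#' the Rayleigh statistic cannot see.
#'
#' @param sample an [angle_sample()].
#' @return The statistic, a single number.
#' @export
hermans_rasson_statistic <- function(sample) {
  sample <- angle_sample(sample)
  .hr_stat(sample$angles)
}

.hr_stat <- function(theta) {
  d <- outer(theta, theta, "-")
  sum(abs(abs(d) - pi) - pi / 2 - hr_constant * (abs(sin(d)) - 2 / pi)) /
    length(theta)
}

#' Hermans-Rasson test of circular uniformity
#'
#' The statistic of [hermans_rasson_statistic()] has no tractable null
#' distribution; its p-value is obtained by Monte Carlo, ranking the
#' observed statistic against `B` replicates computed on uniform samples of
#' the same size (upper tail, ties in the rejection region).
#'
#' @param sample an [angle_sample()] with at least 2 observations.
#' @param B number of Monte-Carlo null replicates (default 9999).
#' @return An object of classes `"circ_test"` and `"htest"`; `p.value` is
#'   at least `1 / (B + 1)`.
#' @export
hermans_rasson_test <- function(sample, B = 9999) {
  sample <- angle_sample(sample)
  n <- sample$n
  if (n < 2) stop("Hermans-Rasson test needs at least 2 angles")
  if (B < 1) stop("B must be at least 1")
  observed <- .hr_stat(sample$angles)
  null_stats <- vapply(
    seq_len(B),
    function(b) .hr_stat(stats::runif(n, 0, 2 * pi)),
    numeric(1)
  )
  p <- mc_pvalue(observed, null_stats, tail = "upper")
  structure(
    list(
      statistic = c(T = observed), p.value = p,
      method = "Hermans-Rasson test of circular uniformity (Monte Carlo)",
      data.name = sprintf("%d angles, %d null replicates", n, B),
      n = n, mc_replicates = B
    ),
    class = c("circ_test", "htest")
  )
}

#' Monte-Carlo p-value from a null reference sample
#'
#' Rank-based p-value with the `+1` convention that guarantees validity:
#' upper tail `p = (1 + #\{null >= observed\}) / (B + 1)`; the lower tail
#' mirrors with `<=`. Ties count toward the rejection region.
#'
#' @param observed the observed statistic.
#' @param null_stats numeric vector of `B >= 1` null replicates.
#' @param tail `"upper"` (large values extreme) or `"lower"`.
#' @return A p-value in `[1/(B+1), 1]`.
#' @export
mc_pvalue <- function(observed, null_stats, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  B <- length(null_stats)
  if (B < 1) stop("null_stats must be non-empty")
  extreme <- if (tail == "upper") sum(null_stats >= observed)
             else sum(null_stats <= observed)
  (1 + extreme) / (B + 1)
}
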