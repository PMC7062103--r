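# Deterministic test landscapes: an explicit two-peak landscape for
# initial-condition experiments and small hand-valued systems for oracle
# checks of the flux equations.

#' Explicit landscape with exactly two fitness peaks
#'
#' Fitness decays linearly with Hamming distance to the nearer of two peak
#' states, down to a positive floor: `F(s) = max(high - slope * min(d_a, d_b),
#' low)`. The default slope, `2 * (high - low) / d_H(peak_a, peak_b)`, makes
#' the two basins meet at the floor midway between the peaks, so the strict
#' local-maximum census finds exactly the two peaks.
#'
#' @param n Number of traits.
#' @param peak_a,peak_b Distinct peak state indices (0-based). Peaks at
#'   Hamming distance 1 cannot both be strict maxima and are rejected.
#' @param high Fitness at the peaks (`> low`).
#' @param low Floor fitness (`> 0`, so no state is incompatible).
#' @param slope Linear decay rate per unit Hamming distance.
#' @return A `culture_landscape`.
#' @examples
#' L <- two_peak_landscape(6, peak_a = 4, peak_b = 26)
#' local_maxima(L) # 4 and 26
#' @export
two_peak_landscape <- function(n, peak_a, peak_b, high = 1, low = 0.2,
                               slope = NULL) {
  if (peak_a == peak_b) stop("Peaks must be distinct states.", call. = FALSE)
  if (!(high > low && low > 0)) {
    stop("Need `high > low > 0`.", call. = FALSE)
  }
  d_ab <- hamming_distance(peak_a, peak_b, n = n)
  if (d_ab < 2) {
    stop("Adjacent peaks cannot both be strict local maxima.", call. = FALSE)
  }
  if (is.null(slope)) slope <- 2 * (high - low) / d_ab
  idx <- 0:(2^n - 1L)
  d_near <- pmin(hamming_distance(idx, peak_a, n = n),
                 hamming_distance(idx, peak_b, n = n))
  landscape_from_fitness(pmax(high - slope * d_near, low))
}

#' Small hand-valued systems for dynamics oracle tests
#'
#' Fixed explicit fitness values on 2 or 3 traits, chosen once and hard-coded
#' so that flux expressions can be expanded by hand (n = 2: four states, two
#' traits, two backgrounds per trait) or cross-checked against an independent
#' integrator (n = 3).
#'
#' @param n 2 or 3.
#' @return A list: `fitness` (length `2^n`), `n`, and for `n = 2` the state
#'   indices of the four states in canonical order.
#' @export
oracle_system <- function(n) {
  if (n == 2) {
    list(n = 2L, fitness = c(0.40, 0.90, 0.25, 0.70), states = 0:3)
  } else if (n == 3) {
    list(n = 3L,
         fitness = c(0.35, 0.80, 0.15, 0.60, 0.95, 0.45, 0.70, 0.25),
         states = 0:7)
  } else {
    stop("`n` must be 2 or 3.", call. = FALSE)
  }
}
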