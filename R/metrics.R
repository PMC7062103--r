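#' Hamming similarity kernel over the state space
#'
#' The kernel entry for states `s`, `s'` is `n - d_H(s, s')`: it is `n` on the
#' diagonal and 0 for antipodal pairs, so the induced inner product credits
#' population mass sitting on nearby (not just identical) states.
#'
#' @param n Number of traits.
#' @return A symmetric `2^n x 2^n` numeric matrix.
#' @export
hamming_kernel <- function(n) {
  n - hamming_matrix(n)
}

#' Hamming-kernel inner product of two vectors over the state space
#'
#' Computes `sum_{s,s'} x(s) [n - d_H(s,s')] y(s')`, a symmetric bilinear form
#' on vectors indexed by the `2^n` cultural states in canonical order.
#'
#' @param x,y Numeric vectors of length `2^n` in canonical state order.
#' @param n Number of traits; inferred from `length(x)` when omitted.
#' @param kernel Optional precomputed [hamming_kernel()] matrix, reused across
#'   repeated calls. Results are identical with or without it.
#' @return A single number.
#' @examples
#' kernel_inner(c(1, 0, 0, 0), c(0, 1, 0, 0)) # 1 for n = 2
#' @export
kernel_inner <- function(x, y, n = NULL, kernel = NULL) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must be defined on the same state space.", call. = FALSE)
  }
  if (is.null(n)) n <- round(log2(length(x)))
  if (2^n != length(x)) {
    stop("Vector length must be 2^n.", call. = FALSE)
  }
  if (is.null(kernel)) kernel <- hamming_kernel(n)
  drop(crossprod(x, kernel %*% y))
}

#' Similarity between two population (or fitness) vectors
#'
#' The Hamming-kernel inner product normalized by the geometric mean of the
#' self-products: `sim(x, y) = <x,y> / sqrt(<x,x><y,y>)`. It equals 1 iff the
#' vectors are proportional, is nonnegative for nonnegative vectors, and is 0
#' exactly when all mass of `x` sits antipodal to all mass of `y`.
#'
#' @inheritParams kernel_inner
#' @return A number in `[0, 1]` for nonnegative inputs.
#' @examples
#' x <- c(1, 0, 0, 0) # all mass on state 00
#' kernel_similarity(x, c(0, 1, 0, 0)) # 1/2
#' kernel_similarity(x, c(0, 0, 0, 1)) # 0, antipodal
#' @export
kernel_similarity <- function(x, y, n = NULL, kernel = NULL) {
  if (is.null(n)) n <- round(log2(length(x)))
  if (is.null(kernel)) kernel <- hamming_kernel(n)
  xx <- kernel_inner(x, x, n, kernel)
  yy <- kernel_inner(y, y, n, kernel)
  if (xx <= 0 || yy <= 0) {
    stop("Similarity is undefined for vectors with zero self-product.",
         call. = FALSE)
  }
  kernel_inner(x, y, n, kernel) / sqrt(xx * yy)
}

#' Summary statistics of a population distribution on a landscape
#'
#' @param x Population fractions over all `2^n` states (zeros on incompatible
#'   states), canonical order.
#' @param fitness Per-state fitness vector of the same length.
#' @return A one-row tibble: modal state of the population (`argmax_x`), the
#'   fittest state (`argmax_fitness`), both with bit strings, population mean
#'   fitness, participation ratio `1 / sum(x^2)` (effective number of occupied
#'   states) and Shannon entropy of `x` (nats).
#' @export
population_summary <- function(x, fitness) {
  if (length(x) != length(fitness)) {
    stop("`x` and `fitness` must be defined on the same state space.",
         call. = FALSE)
  }
  n <- round(log2(length(x)))
  amx <- which.max(x) - 1L
  amf <- which.max(fitness) - 1L
  pos <- x[x > 0]
  tibble::tibble(
    argmax_x = amx,
    argmax_x_bits = state_bitstring(amx, n),
    argmax_fitness = amf,
    argmax_fitness_bits = state_bitstring(amf, n),
    mean_fitness = sum(x * fitness),
    participation_ratio = 1 / sum(x^2),
    entropy = -sum(pos * log(pos))
  )
}
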