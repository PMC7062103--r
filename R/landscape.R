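# Seeded NK fitness landscapes, incompatibility thresholding and the
# tau-interpolation between two endpoint landscapes.

with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

new_landscape <- function(n, fitness, base_fitness, f_th, k = NA_integer_,
                          seed = NA_integer_, tables = NULL,
                          source = "nk") {
  structure(
    list(
      n = as.integer(n),
      k = k,
      seed = seed,
      tables = tables,
      f_th = f_th,
      fitness = as.numeric(fitness),
      base_fitness = as.numeric(base_fitness),
      incompatible = fitness == 0,
      source = source
    ),
    class = "culture_landscape"
  )
}

#' Build a seeded NK fitness landscape
#'
#' Fitness of a state is the mean of `n` component contributions, one per
#' trait; contribution `i` reads the cyclic window of `k + 1` traits starting
#' at trait `i` (indices wrap around past `n`). Each component table holds
#' `2^(k+1)` values drawn uniformly on `[0, 1)`, so `0 <= F(s) <= 1`. With
#' `k = 0` the landscape is additive (single-peaked); with `k = n` every state
#' gets an independent uniform fitness (maximally rugged).
#'
#' @param n Number of traits (`>= 1`).
#' @param k Epistasis degree, `0 <= k <= n`: how many further traits each
#'   trait's contribution depends on.
#' @param seed Integer RNG seed; the landscape is a deterministic function of
#'   `(n, k, seed)`. The caller's RNG state is left untouched.
#' @param cap Safety cap on `n`, as in [enumerate_states()].
#' @return A `culture_landscape` object with `$fitness` over all `2^n` states
#'   in canonical order.
#' @examples
#' L <- nk_landscape(6, 1, seed = 42)
#' range(L$fitness)
#' @export
nk_landscape <- function(n, k, seed, cap = 16L) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L) stop("`n` must be >= 1.", call. = FALSE)
  if (k < 0L || k > n) stop("`k` must satisfy 0 <= k <= n.", call. = FALSE)
  if (n > cap) stop("`n` exceeds the state-space cap.", call. = FALSE)
  tables <- with_preserved_rng(seed, {
    matrix(stats::runif(n * 2^(k + 1)), nrow = n)
  })
  fitness <- nk_fitness(tables, n, k)
  new_landscape(n, fitness, fitness, f_th = 0, k = k, seed = as.integer(seed),
                tables = tables, source = "nk")
}

# evaluate mean-of-components NK fitness for all 2^n states from given tables
nk_fitness <- function(tables, n, k) {
  idx <- 0:(2^n - 1L)
  bits <- t(vapply(idx, state_decode, integer(n), n = n))
  acc <- numeric(length(idx))
  pow <- 2^(k:0)
  for (i in seq_len(n)) {
    window <- ((i - 1L) + 0:k) %% n + 1L
    col <- as.integer(bits[, window, drop = FALSE] %*% pow) + 1L
    acc <- acc + tables[i, col]
  }
  acc / n
}

#' Build a landscape from an explicit fitness table
#'
#' @param fitness Numeric vector of length `2^n`, canonical state order;
#'   entries equal to 0 are incompatible states.
#' @param rescale Divide by the maximum so fitness lies in `[0, 1]` (the
#'   dynamics only uses fitness ratios, so this loses no generality).
#' @return A `culture_landscape`.
#' @export
landscape_from_fitness <- function(fitness, rescale = FALSE) {
  n <- round(log2(length(fitness)))
  if (2^n != length(fitness)) stop("Fitness length must be 2^n.", call. = FALSE)
  if (any(fitness < 0)) stop("Fitness must be nonnegative.", call. = FALSE)
  if (rescale) fitness <- fitness / max(fitness)
  new_landscape(n, fitness, fitness, f_th = 0, source = "table")
}

#' Apply the incompatibility threshold to a landscape
#'
#' States whose fitness does not exceed `f_th` become incompatible (zero
#' fitness, never populated); the rest have `f_th` subtracted:
#' `F_th(s) = F(s) - f_th` if `F(s) > f_th`, else 0. The rule is idempotent:
#' applying it a second time with `f_th = 0` changes nothing. The input
#' fitness is kept in `$base_fitness`.
#'
#' @param L A `culture_landscape`.
#' @param f_th Nonnegative threshold.
#' @return A new `culture_landscape` with updated `$fitness` and
#'   `$incompatible`.
#' @export
apply_threshold <- function(L, f_th) {
  stopifnot(inherits(L, "culture_landscape"))
  if (length(f_th) != 1L || is.na(f_th) || f_th < 0) {
    stop("`f_th` must be a single nonnegative number.", call. = FALSE)
  }
  base <- L$fitness
  fitness <- ifelse(base > f_th, base - f_th, 0)
  new_landscape(L$n, fitness, base, f_th = f_th, k = L$k, seed = L$seed,
                tables = L$tables, source = L$source)
}

#' Threshold value yielding a prescribed number of incompatible states
#'
#' Returns the `m`-th smallest fitness value, so that thresholding at it
#' leaves exactly `m` states incompatible (fitness values are almost surely
#' distinct for NK landscapes; exact ties trigger a warning).
#'
#' @param L A `culture_landscape`.
#' @param m Desired number of incompatible states, `0 <= m <= 2^n`.
#' @return A single threshold value (`0` when `m = 0`).
#' @export
threshold_for_count <- function(L, m) {
  stopifnot(inherits(L, "culture_landscape"))
  nstates <- length(L$base_fitness)
  if (length(m) != 1L || is.na(m) || m < 0 || m > nstates || m != floor(m)) {
    stop("`m` must be an integer in [0, 2^n].", call. = FALSE)
  }
  if (m == 0) return(0)
  srt <- sort(L$base_fitness)
  th <- srt[m]
  if (m < nstates && srt[m + 1L] == th) {
    warning("Tied fitness values at the threshold; fewer than `m` states may be incompatible.")
  }
  th
}

#' Construct the pair of endpoint landscapes for a quasi-static sweep
#'
#' Draws two independent NK landscapes `F0` and `F1` with the same `(n, k)`
#' from child seeds of a single master seed, applies the incompatibility
#' threshold to both, and freezes a tau-independent incompatible set: trait
#' incompatibilities are assumed not to change with the environment, so
#' interpolated fitness is exactly 0 on that set for every tau.
#'
#' @param n,k NK parameters shared by both endpoints.
#' @param seed Master seed; child seeds for `F0` and `F1` are derived from it.
#' @param f_th Incompatibility threshold applied to both endpoints
#'   (default 0: no incompatible states).
#' @param incompatible_count Alternative to `f_th`: threshold each endpoint
#'   at its own `m`-th smallest fitness value, so both endpoints have exactly
#'   this many zero-fitness states. (A single threshold derived from `F0`
#'   can exceed every fitness in `F1` and collapse that endpoint entirely;
#'   per-endpoint quantiles keep the configuration meaningful for every
#'   seed.)
#' @param incompatible_from Which endpoint defines the frozen incompatible
#'   set: `"F0"` (default), `"F1"`, their `"union"` or `"intersection"`.
#' @param cap Safety cap on `n`.
#' @return A `landscape_pair` object with elements `F0`, `F1`
#'   (`culture_landscape`s), logical `incompatible`, integer `viable` (0-based
#'   state indices), `n`, `f_th`.
#' @examples
#' pair <- landscape_pair(6, 1, seed = 7)
#' sum(pair$incompatible)
#' @export
landscape_pair <- function(n, k, seed, f_th = 0, incompatible_count = NULL,
                           incompatible_from = c("F0", "F1", "union", "intersection"),
                           cap = 16L) {
  incompatible_from <- match.arg(incompatible_from)
  child <- with_preserved_rng(seed, sample.int(.Machine$integer.max - 1L, 2))
  F0 <- nk_landscape(n, k, seed = child[1], cap = cap)
  F1 <- nk_landscape(n, k, seed = child[2], cap = cap)
  if (!is.null(incompatible_count)) {
    f_th <- threshold_for_count(F0, incompatible_count)
    f_th1 <- threshold_for_count(F1, incompatible_count)
  } else {
    f_th1 <- f_th
  }
  build_pair(F0, F1, f_th, incompatible_from, f_th1 = f_th1,
             master_seed = as.integer(seed))
}

build_pair <- function(F0, F1, f_th, incompatible_from = "F0",
                       f_th1 = f_th, master_seed = NA_integer_) {
  stopifnot(F0$n == F1$n)
  F0 <- apply_threshold(F0, f_th)
  F1 <- apply_threshold(F1, f_th1)
  incompatible <- switch(incompatible_from,
    F0 = F0$incompatible,
    F1 = F1$incompatible,
    union = F0$incompatible | F1$incompatible,
    intersection = F0$incompatible & F1$incompatible
  )
  structure(
    list(
      n = F0$n,
      F0 = F0,
      F1 = F1,
      f_th = f_th,
      incompatible = incompatible,
      viable = which(!incompatible) - 1L,
      incompatible_from = incompatible_from,
      seed = master_seed
    ),
    class = "landscape_pair"
  )
}

#' Pair two explicitly given landscapes
#'
#' User-supplied fitness tables are rescaled by their joint maximum so that
#' all values lie in `[0, 1]` (set `rescale = FALSE` to keep them as given).
#'
#' @param F0,F1 `culture_landscape` objects or numeric fitness vectors of
#'   length `2^n`.
#' @param rescale Rescale both endpoints by their joint maximum.
#' @inheritParams landscape_pair
#' @return A `landscape_pair`.
#' @export
landscape_pair_from_tables <- function(F0, F1, f_th = 0, rescale = TRUE,
                                       incompatible_from = c("F0", "F1", "union", "intersection")) {
  incompatible_from <- match.arg(incompatible_from)
  if (is.numeric(F0)) F0 <- landscape_from_fitness(F0)
  if (is.numeric(F1)) F1 <- landscape_from_fitness(F1)
  if (rescale) {
    top <- max(c(F0$base_fitness, F1$base_fitness))
    if (top > 0) {
      F0 <- landscape_from_fitness(F0$base_fitness / top)
      F1 <- landscape_from_fitness(F1$base_fitness / top)
    }
  }
  build_pair(F0, F1, f_th, incompatible_from)
}

#' Interpolated fitness along the environmental parameter tau
#'
#' On viable states the fitness is the convex combination
#' `F_tau(s) = tau * F1(s) + (1 - tau) * F0(s)` of the two thresholded
#' endpoints; on the frozen incompatible set it is 0 for every tau.
#'
#' @param pair A `landscape_pair`.
#' @param tau Number in `[0, 1]`.
#' @return Numeric fitness vector over all `2^n` states.
#' @export
interpolate_fitness <- function(pair, tau) {
  stopifnot(inherits(pair, "landscape_pair"))
  if (length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1) {
    stop("`tau` must be a single number in [0, 1].", call. = FALSE)
  }
  f <- tau * pair$F1$fitness + (1 - tau) * pair$F0$fitness
  f[pair$incompatible] <- 0
  f
}

#' Similarity between two fitness landscapes
#'
#' Applies the Hamming-kernel similarity ([kernel_similarity()]) to the two
#' per-state fitness vectors; used to verify that consecutive landscapes in a
#' quasi-static sweep are barely distinguishable.
#'
#' @param Fa,Fb `culture_landscape` objects or numeric fitness vectors.
#' @inheritParams kernel_inner
#' @return A number in `[0, 1]`.
#' @export
landscape_similarity <- function(Fa, Fb, kernel = NULL) {
  if (inherits(Fa, "culture_landscape")) Fa <- Fa$fitness
  if (inherits(Fb, "culture_landscape")) Fb <- Fb$fitness
  kernel_similarity(Fa, Fb, kernel = kernel)
}

#' Strict local maxima of a fitness landscape
#'
#' States whose fitness is strictly greater than that of all `n` one-trait
#' neighbours. Generic landscapes (uniform component tables) have no ties; an
#' exact tie with a neighbour disqualifies both under the strict rule (so a
#' constant landscape has no local maxima) and raises a warning.
#'
#' @param F A `culture_landscape` or numeric fitness vector of length `2^n`.
#' @return Integer vector of local-maximum state indices (0-based), always
#'   including the global argmax in the generic (tie-free) case.
#' @export
local_maxima <- function(F) {
  if (inherits(F, "culture_landscape")) F <- F$fitness
  n <- round(log2(length(F)))
  if (2^n != length(F)) stop("Fitness length must be 2^n.", call. = FALSE)
  idx <- 0:(2^n - 1L)
  masks <- as.integer(2^((n - 1L):0L))
  is_max <- rep(TRUE, length(idx))
  tied <- FALSE
  for (m in masks) {
    nb <- bitwXor(idx, m)
    f_nb <- F[nb + 1L]
    if (any(is_max & (F == f_nb))) tied <- TRUE
    is_max <- is_max & (F > f_nb)
  }
  if (tied) warning("Tied fitness between neighbouring states; the strict census excludes tied states.")
  idx[is_max]
}
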