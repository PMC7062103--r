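# Core population dynamics: adoption probability, homophily weight,
# contagion/guided-variation fluxes, and the log-variable RK4 integrator.

#' Parameters of the cultural transmission dynamics
#'
#' @param lambda Rate weight of horizontal transmission (pairwise meetings);
#'   the default 0.999 together with `mu = 0.001` makes 99.9% of trait changes
#'   transmission-driven.
#' @param mu Rate weight of spontaneous single-trait changes (guided
#'   variation). `lambda` and `mu` must be nonnegative and not both zero.
#' @param beta Sharpness of the adoption sigmoid (`> 0`): large `beta` means
#'   strong aversion to cognitive dissonance (fitness-decreasing traits are
#'   almost never adopted), small `beta` means tolerant individuals.
#' @param alpha Homophily exponent (`>= 0`): 0 means no homophily (the most
#'   dissimilar peers are the most influential); larger values concentrate
#'   influence at smaller Hamming distances.
#' @return A `dynamics_params` list.
#' @export
dynamics_params <- function(lambda = 0.999, mu = 0.001, beta = 1, alpha = 0) {
  if (lambda < 0 || mu < 0 || (lambda == 0 && mu == 0)) {
    stop("`lambda` and `mu` must be nonnegative and not both zero.", call. = FALSE)
  }
  if (beta <= 0) stop("`beta` must be positive.", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be nonnegative.", call. = FALSE)
  structure(list(lambda = lambda, mu = mu, beta = beta, alpha = alpha),
            class = "dynamics_params")
}

#' Integrator settings for the RK4 equilibrium solver
#'
#' @param dt Fixed RK4 time step (default 0.1).
#' @param check_interval Time between convergence checks (default 100):
#'   integration stops when `max_s |x(s, t) - x(s, t + check_interval)| < tol`.
#' @param tol Convergence tolerance on the population fractions
#'   (default 1e-4).
#' @param max_time Safety cap on total integration time; exceeding it without
#'   convergence raises an error carrying the last state and residual.
#' @return An `integrator_settings` list.
#' @export
integrator_settings <- function(dt = 0.1, check_interval = 100, tol = 1e-4,
                                max_time = 1e5) {
  vals <- c(dt = dt, check_interval = check_interval, tol = tol,
            max_time = max_time)
  if (any(vals <= 0)) stop("All integrator settings must be positive.", call. = FALSE)
  structure(as.list(vals), class = "integrator_settings")
}

#' Probability of adopting a fitter (or less fit) cultural state
#'
#' The sigmoid `G(r) = r^beta / (1 + r^beta)` evaluated at the fitness ratio
#' `f_new / f_old`. Anchors: `G(0) = 0`, `G(1) = 1/2`, `G(r)` tends to 1 for
#' large ratios, and `G(r) + G(1/r) = 1`. Boundary conventions: result 0 when
#' `f_new = 0`, 1 when `f_old = 0 < f_new`, and 0 when both fitnesses vanish
#' (no flux between unpopulated incompatible states).
#'
#' @param f_new,f_old Nonnegative fitness of the candidate and current state
#'   (vectorized).
#' @param beta Sigmoid sharpness, `> 0`.
#' @return Probability vector in `[0, 1]`.
#' @examples
#' adoption_prob(0.6, 0.6, beta = 2) # 1/2
#' @export
adoption_prob <- function(f_new, f_old, beta) {
  if (beta <= 0) stop("`beta` must be positive.", call. = FALSE)
  if (any(f_new < 0) || any(f_old < 0)) {
    stop("Fitness values must be nonnegative.", call. = FALSE)
  }
  out <- numeric(length(f_new <- rep_len(f_new, max(length(f_new), length(f_old)))))
  f_old <- rep_len(f_old, length(f_new))
  both_zero <- f_new == 0 & f_old == 0
  new_zero <- f_new == 0 & !both_zero
  old_zero <- f_old == 0 & !both_zero
  regular <- !both_zero & !new_zero & !old_zero
  out[old_zero] <- 1
  # logistic form of r^beta / (1 + r^beta), stable for extreme ratios
  out[regular] <- stats::plogis(beta * (log(f_new[regular]) - log(f_old[regular])))
  out
}

#' Homophily weight of an encounter as a function of Hamming distance
#'
#' `W(d) = (d/n) * (1 - d/n)^alpha * (1 + alpha)^(1 + alpha) / alpha^alpha`.
#' The factor `d/n` is the probability that a randomly chosen trait differs
#' between the two individuals; `(1 - d/n)^alpha` weighs their overall
#' similarity; the constant normalizes the maximum over real `d` to 1,
#' attained at `d = n / (1 + alpha)`. For `alpha = 0` (convention `0^0 = 1`)
#' the weight reduces to `d/n`, maximal at full dissimilarity.
#'
#' @param d Hamming distance(s), `0 <= d <= n` (need not be integer).
#' @param n Number of traits.
#' @param alpha Homophily exponent, `>= 0`.
#' @return Weight(s) in `[0, 1]`; `W(0) = 0`.
#' @examples
#' homophily_weight(0:6, 6, alpha = 5) # integer argmax at d = 1
#' @export
homophily_weight <- function(d, n, alpha) {
  if (any(d < 0 | d > n)) stop("`d` must lie in [0, n].", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be nonnegative.", call. = FALSE)
  norm <- if (alpha == 0) 1 else (1 + alpha)^(1 + alpha) / alpha^alpha
  (d / n) * (1 - d / n)^alpha * norm
}

#' Uniform population over the viable states
#'
#' @param fitness Per-state fitness vector (length `2^n`); states with zero
#'   fitness are incompatible and receive no population. A `landscape_pair`
#'   may be given instead, in which case its frozen viable set is used.
#' @return Numeric vector over all `2^n` states summing to 1.
#' @export
uniform_population <- function(fitness) {
  if (inherits(fitness, "landscape_pair")) {
    viable <- !fitness$incompatible
  } else {
    viable <- fitness > 0
  }
  x <- numeric(length(viable))
  x[viable] <- 1 / sum(viable)
  x
}

# --- internal engine: precomputed index maps and homophily kernels ----------

# unnormalized Walsh-Hadamard transform; length must be a power of two
wht_transform <- function(v) {
  N <- length(v)
  h <- 1L
  while (h < N) {
    for (st in seq(1L, N, by = 2L * h)) {
      idx <- st:(st + h - 1L)
      a <- v[idx]; b <- v[idx + h]
      v[idx] <- a + b
      v[idx + h] <- a - b
    }
    h <- 2L * h
  }
  v
}

# Precomputed structures for the flux evaluation on a fixed viable set:
# the one-trait flip map and, because the homophily-weighted peer sums
# A_i(u) = sum_t W(d_H(u,t)) [t_i != u_i] x(t) are XOR-convolutions over the
# hypercube, the Walsh-Hadamard transforms of the per-trait kernels
# f_i(v) = W(popcount(v)) bit_i(v). A dense stacked-kernel form (used by the
# plain-R derivative path) is kept for small state spaces; the two
# representations give identical results.
make_engine <- function(n, viable, alpha, dense = TRUE) {
  m <- length(viable)
  if (m == 0) stop("No viable states: all states are incompatible.", call. = FALSE)
  N <- 2^n
  masks <- as.integer(2^((n - 1L):0L))
  v_all <- 0:(N - 1L)
  w_all <- homophily_weight(popcount(v_all), n, alpha)
  fhat <- vapply(seq_len(n), function(i) {
    wht_transform(w_all * (bitwAnd(v_all, masks[i]) > 0L))
  }, numeric(N))
  pos <- rep(NA_integer_, N)
  pos[viable + 1L] <- seq_len(m)
  flip <- matrix(-1L, nrow = m, ncol = n)
  for (i in seq_len(n)) {
    fp <- pos[bitwXor(viable, masks[i]) + 1L]
    flip[, i] <- ifelse(is.na(fp), -1L, fp - 1L)
  }
  Kstack <- NULL
  if (dense && m <= 2048) {
    d <- matrix(popcount(bitwXor(rep(viable, times = m), rep(viable, each = m))),
                nrow = m)
    w <- homophily_weight(d, n, alpha)
    Kstack <- matrix(0, nrow = n * m, ncol = m)
    for (i in seq_len(n)) {
      bit_t <- bitwAnd(viable, masks[i]) > 0L
      diff <- outer(bit_t, bit_t, `!=`) # t_i != u_i, rows u cols t
      Kstack[((i - 1L) * m + 1L):(i * m), ] <- w * diff
    }
  }
  list(n = n, m = m, viable = viable, alpha = alpha, masks = masks,
       fhat = fhat, flip = flip, Kstack = Kstack)
}

# G factors for inflow/outflow on the viable set at a given fitness vector.
# Entries whose one-trait flip is incompatible are zeroed: no population can
# flow to or from an incompatible state, and the C++ core relies on this to
# run branch-free.
engine_gfactors <- function(engine, fitness, beta) {
  m <- engine$m; n <- engine$n
  fv <- fitness[engine$viable + 1L]
  masks <- as.integer(2^((n - 1L):0L))
  gin <- matrix(0, m, n)
  gout <- matrix(0, m, n)
  for (i in seq_len(n)) {
    f_flip <- fitness[bitwXor(engine$viable, masks[i]) + 1L]
    gin[, i] <- adoption_prob(fv, f_flip, beta)
    gout[, i] <- adoption_prob(f_flip, fv, beta)
  }
  gin[engine$flip < 0L] <- 0
  gout[engine$flip < 0L] <- 0
  list(gin = gin, gout = gout)
}

check_population <- function(x, viable, nstates, what = "x", floor0 = FALSE) {
  if (length(x) == nstates) {
    xv <- x[viable + 1L]
    bad <- setdiff(which(x != 0) - 1L, viable)
    if (length(bad) > 0) {
      stop(sprintf("`%s` puts mass on incompatible state(s) %s.", what,
                   paste(utils::head(bad, 3), collapse = ", ")), call. = FALSE)
    }
  } else if (length(x) == length(viable)) {
    xv <- x
  } else {
    stop(sprintf("`%s` must have length 2^n or match the viable set.", what),
         call. = FALSE)
  }
  if (floor0) {
    # warm starts within a sweep: fractions that underflowed to zero at the
    # previous grid point are restored to the smallest representable level
    xv[xv == 0] <- 1e-300
  }
  if (any(xv <= 0)) {
    stop(sprintf("`%s` must be strictly positive on every viable state (log-variable integration).", what),
         call. = FALSE)
  }
  xv / sum(xv)
}

# --- fluxes (module surface; direct sums, independent of the C++ core) ------

#' Inflow rate of population into one cultural state
#'
#' Direct evaluation of the balance-equation gain term: for each trait `i`,
#' individuals one flip away (at `(1 - s_i, s_-i)`) adopt trait `s_i` either
#' after a homophily-weighted meeting with any individual already holding
#' `s_i` (rate weight `lambda`) or spontaneously (rate weight `mu`), with
#' probability given by the fitness-ratio sigmoid.
#'
#' @param s State index (0-based).
#' @param x Population fractions over all `2^n` states.
#' @param fitness Per-state fitness vector.
#' @param params [dynamics_params()].
#' @return The scalar inflow rate `I(s)`.
#' @export
contagion_inflow <- function(s, x, fitness, params) {
  flux_one_state(s, x, fitness, params, inflow = TRUE)
}

#' Outflow rate of population out of one cultural state
#'
#' Mirror of [contagion_inflow()]: individuals at `s` adopt the opposite value
#' of some trait `i` after meeting individuals that differ from them in that
#' trait, or spontaneously.
#'
#' @inheritParams contagion_inflow
#' @return The scalar outflow rate `O(s)`.
#' @export
contagion_outflow <- function(s, x, fitness, params) {
  flux_one_state(s, x, fitness, params, inflow = FALSE)
}

flux_one_state <- function(s, x, fitness, params, inflow) {
  n <- round(log2(length(x)))
  stopifnot(2^n == length(x), length(fitness) == length(x))
  idx <- 0:(2^n - 1L)
  masks <- as.integer(2^((n - 1L):0L))
  total <- 0
  for (i in seq_len(n)) {
    s_flip <- bitwXor(as.integer(s), masks[i])
    if (inflow) {
      donor <- s_flip                      # population converting into s
      target_bit <- bitwAnd(s, masks[i])   # influencers hold trait value s_i
      g <- adoption_prob(fitness[s + 1L], fitness[s_flip + 1L], params$beta)
    } else {
      donor <- as.integer(s)
      target_bit <- bitwAnd(s_flip, masks[i])
      g <- adoption_prob(fitness[s_flip + 1L], fitness[s + 1L], params$beta)
    }
    peers <- idx[bitwAnd(idx, masks[i]) == target_bit]
    wsum <- sum(homophily_weight(hamming_distance(donor, peers, n = n), n,
                                 params$alpha) * x[peers + 1L])
    total <- total + (params$lambda * wsum + params$mu) * x[donor + 1L] * g
  }
  total
}

#' Time derivative of the population vector
#'
#' The balance equation `dx(s)/dt = I(s) - O(s)` evaluated for every state at
#' once through the precomputed homophily kernels; every pairwise flux appears
#' once as inflow and once as outflow, so the derivatives sum to zero.
#'
#' @param x Population fractions over all `2^n` states.
#' @inheritParams contagion_inflow
#' @return Numeric derivative vector of length `2^n`.
#' @export
population_rhs <- function(x, fitness, params) {
  n <- round(log2(length(x)))
  stopifnot(2^n == length(x), length(fitness) == length(x))
  engine <- make_engine(n, 0:(2^n - 1L), params$alpha)
  g <- engine_gfactors(engine, fitness, params$beta)
  A <- engine$Kstack %*% x
  m <- engine$m
  dx <- numeric(m)
  for (i in seq_len(n)) {
    j <- engine$flip[, i] + 1L
    Ai <- A[((i - 1L) * m + 1L):(i * m)]
    dx <- dx +
      (params$lambda * Ai[j] + params$mu) * x[j] * g$gin[, i] -
      (params$lambda * Ai + params$mu) * x * g$gout[, i]
  }
  dx
}

# --- integration -------------------------------------------------------------

#' Integrate the dynamics to its equilibrium
#'
#' Steps the balance equations with a fixed-step fourth-order Runge-Kutta
#' scheme in the log variables `y(s) = log x(s)` (which keeps all viable
#' fractions positive), stopping when the population changes by less than
#' `tol` in max norm over a window of `check_interval` time units. The result
#' is renormalized to unit sum, correcting the small drift a non-conservative
#' log-space step accumulates.
#'
#' @param x0 Initial population: numeric over all `2^n` states (zero on
#'   incompatible states) or over the viable states only; `"uniform"` for the
#'   uniform distribution on viable states. Must be strictly positive on every
#'   viable state.
#' @param fitness Per-state fitness vector; zero-fitness states are treated as
#'   incompatible unless `viable` says otherwise.
#' @param params [dynamics_params()].
#' @param settings [integrator_settings()].
#' @param viable Optional 0-based indices of viable states (defaults to the
#'   positive-fitness states).
#' @return A list of class `culture_equilibrium`: `x` (full-length equilibrium
#'   fractions summing to 1), `residual` (last convergence check), `time`
#'   (integration time used), `converged` (always `TRUE`; non-convergence
#'   raises an error of class `culturedyn_nonconvergence` carrying the last
#'   state and residual).
#' @examples
#' L <- nk_landscape(3, 1, seed = 1)
#' eq <- integrate_to_equilibrium("uniform", L$fitness, dynamics_params())
#' sum(eq$x)
#' @export
integrate_to_equilibrium <- function(x0, fitness, params,
                                     settings = integrator_settings(),
                                     viable = NULL) {
  run_integrator(x0, fitness, params, settings, viable, fixed_time = NULL)
}

#' Integrate the dynamics for a fixed time span
#'
#' Same scheme as [integrate_to_equilibrium()] but runs for exactly `time`
#' time units without a convergence test; used for trajectory checks.
#'
#' @inheritParams integrate_to_equilibrium
#' @param time Total integration time.
#' @return A `culture_equilibrium`-shaped list with the state at `time`.
#' @export
integrate_population <- function(x0, fitness, params, time,
                                 settings = integrator_settings(),
                                 viable = NULL) {
  if (time <= 0) stop("`time` must be positive.", call. = FALSE)
  run_integrator(x0, fitness, params, settings, viable, fixed_time = time)
}

run_integrator <- function(x0, fitness, params, settings, viable,
                           fixed_time = NULL, engine = NULL, gf = NULL,
                           renormalize = TRUE, floor0 = FALSE) {
  nstates <- length(fitness)
  n <- round(log2(nstates))
  stopifnot(2^n == nstates)
  if (is.null(viable)) viable <- which(fitness > 0) - 1L
  if (is.null(engine)) engine <- make_engine(n, viable, params$alpha, dense = FALSE)
  if (is.null(gf)) gf <- engine_gfactors(engine, fitness, params$beta)
  if (identical(x0, "uniform")) {
    xv <- rep(1 / engine$m, engine$m)
  } else {
    xv <- check_population(x0, viable, nstates, "x0", floor0 = floor0)
  }
  dt <- settings$dt
  steps_per_check <- max(1L, as.integer(round(settings$check_interval / dt)))
  if (is.null(fixed_time)) {
    max_checks <- max(1L, as.integer(ceiling(settings$max_time /
                                               settings$check_interval)))
    tol <- settings$tol
  } else {
    # run exactly `fixed_time`; use one final partial check block if needed
    total_steps <- as.integer(round(fixed_time / dt))
    steps_per_check <- total_steps
    max_checks <- 1L
    tol <- -1
  }
  res <- rk4_log_integrate(log(xv), engine$viable, engine$flip, engine$masks,
                           engine$fhat, gf$gin, gf$gout, params$lambda,
                           params$mu, dt, steps_per_check, tol, max_checks)
  xv_out <- exp(res$y)
  x_full <- numeric(nstates)
  x_full[viable + 1L] <- if (renormalize) xv_out / sum(xv_out) else xv_out
  out <- structure(
    list(x = x_full, residual = res$residual,
         time = res$n_checks * steps_per_check * dt,
         converged = isTRUE(res$converged) || !is.null(fixed_time)),
    class = "culture_equilibrium"
  )
  if (is.null(fixed_time) && !res$converged) {
    rlang::abort(
      sprintf("Integrator did not converge within max_time = %g (residual %.3g).",
              settings$max_time, res$residual),
      class = "culturedyn_nonconvergence",
      x = x_full, residual = res$residual
    )
  }
  out
}
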