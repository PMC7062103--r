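# Quasi-static experiment drivers: forward/backward tau sweeps with warm
# starts, jump detection, hysteresis loops, initial-condition experiments and
# seeded ensembles.

#' Quasi-static sweep of the environmental parameter tau
#'
#' Steps tau across `[0, 1]` in increments of `eps`. At each grid point the
#' population is integrated to equilibrium on the interpolated landscape,
#' warm-started from the previous equilibrium (the first grid point starts
#' from `x_init`). Three similarity curves are recorded: population similarity
#' to the initial equilibrium, step-to-step population similarity, and
#' step-to-step landscape similarity (which should stay ~1, confirming that
#' the environment changes imperceptibly).
#'
#' @param pair A [landscape_pair()].
#' @param params [dynamics_params()].
#' @param settings [integrator_settings()].
#' @param eps Tau step (default 0.01); `1/eps` must be an integer.
#' @param direction `"forward"` (tau 0 to 1) or `"backward"` (1 to 0).
#' @param x_init Initial population at the first grid point: `"uniform"` or a
#'   population vector.
#' @param x_ref Reference population for the `sim_to_initial` curve; defaults
#'   to the first equilibrium of this sweep. A backward sweep in a hysteresis
#'   loop passes the forward sweep's reference so the two branches are
#'   comparable.
#' @param jump_threshold Step-similarity threshold below which a grid point is
#'   flagged as a discontinuous jump (default 0.9).
#' @return A `culture_sweep` object: `curves` (tibble with one row per grid
#'   point: `tau`, `sim_to_initial`, `sim_step`, `landscape_sim_step`,
#'   `argmax_state`, `mean_fitness`, `residual`, `time`), `equilibria` (matrix
#'   of per-state fractions, one column per grid point), `jumps` (tibble from
#'   [detect_jumps()]), plus the grid and configuration.
#' @export
run_sweep <- function(pair, params = dynamics_params(),
                      settings = integrator_settings(), eps = 0.01,
                      direction = c("forward", "backward"),
                      x_init = "uniform", x_ref = NULL,
                      jump_threshold = 0.9) {
  stopifnot(inherits(pair, "landscape_pair"))
  direction <- match.arg(direction)
  nsteps <- 1 / eps
  if (abs(nsteps - round(nsteps)) > 1e-8) {
    stop("`eps` must divide 1.", call. = FALSE)
  }
  tau_grid <- seq(0, 1, length.out = round(nsteps) + 1L)
  if (direction == "backward") tau_grid <- rev(tau_grid)
  n <- pair$n
  nstates <- 2^n
  engine <- make_engine(n, pair$viable, params$alpha, dense = FALSE)
  kernel <- hamming_kernel(n)
  equilibria <- matrix(0, nrow = nstates, ncol = length(tau_grid))
  curves <- vector("list", length(tau_grid))
  x_prev <- x_init
  f_prev <- NULL
  for (j in seq_along(tau_grid)) {
    tau <- tau_grid[j]
    f_tau <- interpolate_fitness(pair, tau)
    gf <- engine_gfactors(engine, f_tau, params$beta)
    eq <- tryCatch(
      run_integrator(x_prev, f_tau, params, settings, viable = pair$viable,
                     engine = engine, gf = gf, floor0 = !identical(x_prev, "uniform")),
      culturedyn_nonconvergence = function(e) {
        rlang::abort(
          sprintf("Sweep failed to equilibrate at tau = %.4g (residual %.3g).",
                  tau, e$residual),
          class = "culturedyn_nonconvergence", parent = e,
          tau = tau, x = e$x, residual = e$residual
        )
      }
    )
    equilibria[, j] <- eq$x
    if (j == 1L && is.null(x_ref)) x_ref <- eq$x
    curves[[j]] <- tibble::tibble(
      tau = tau,
      sim_to_initial = kernel_similarity(x_ref, eq$x, n, kernel),
      sim_step = if (j == 1L) NA_real_ else {
        kernel_similarity(equilibria[, j - 1L], eq$x, n, kernel)
      },
      landscape_sim_step = if (j == 1L) NA_real_ else {
        kernel_similarity(f_prev, f_tau, n, kernel)
      },
      argmax_state = which.max(eq$x) - 1L,
      mean_fitness = sum(eq$x * f_tau),
      residual = eq$residual,
      time = eq$time
    )
    x_prev <- eq$x
    f_prev <- f_tau
  }
  out <- structure(
    list(
      curves = dplyr::bind_rows(curves),
      equilibria = equilibria,
      tau_grid = tau_grid,
      n = n,
      direction = direction,
      eps = eps,
      params = params,
      settings = settings,
      jump_threshold = jump_threshold,
      x_ref = x_ref,
      pair_seed = pair$seed,
      f_th = pair$f_th
    ),
    class = "culture_sweep"
  )
  out$jumps <- detect_jumps(out, jump_threshold)
  out
}

#' Detect discontinuous jumps in a sweep
#'
#' Flags grid points where the step-to-step population similarity drops below
#' `jump_threshold`: the equilibrium moved a long way on the hypercube while
#' the landscape barely changed, the signature of a paradigm shift.
#'
#' @param sweep A `culture_sweep` (or any list with `curves`, `equilibria` and
#'   `n` fields of the same shape).
#' @param jump_threshold Step-similarity threshold (default 0.9).
#' @return A tibble with one row per jump: `tau`, `sim_step`, modal state
#'   before and after the jump, and the Hamming distance between them.
#' @export
detect_jumps <- function(sweep, jump_threshold = 0.9) {
  curves <- sweep$curves
  hit <- which(!is.na(curves$sim_step) & curves$sim_step < jump_threshold)
  n <- sweep$n
  before <- vapply(hit, function(j) which.max(sweep$equilibria[, j - 1L]) - 1L,
                   integer(1))
  after <- vapply(hit, function(j) which.max(sweep$equilibria[, j]) - 1L,
                  integer(1))
  tibble::tibble(
    tau = curves$tau[hit],
    sim_step = curves$sim_step[hit],
    argmax_before = before,
    argmax_after = after,
    hamming_shift = if (length(hit)) hamming_distance(before, after, n = n) else integer(0)
  )
}

#' Forward/backward hysteresis experiment
#'
#' Runs a forward sweep (tau from 0 to 1), then a backward sweep over the same
#' grid reversed, warm-started from the forward endpoint and measured against
#' the same initial reference population. With a reversible (non-epistatic)
#' landscape the two branches coincide; after a discontinuous paradigm shift
#' the backward branch stays on the new paradigm well past the forward tipping
#' point, opening a hysteresis loop.
#'
#' @inheritParams run_sweep
#' @param gap_tol Loop is declared hysteretic when the maximum absolute
#'   pointwise difference of `sim_to_initial` between branches exceeds this
#'   (default 0.05).
#' @return A `culture_hysteresis` object: `forward` and `backward` sweeps,
#'   `loop` (tibble: `tau`, `sim_forward`, `sim_backward`, `gap`),
#'   `max_gap`, and logical `is_hysteretic`.
#' @export
run_hysteresis <- function(pair, params = dynamics_params(),
                           settings = integrator_settings(), eps = 0.01,
                           x_init = "uniform", jump_threshold = 0.9,
                           gap_tol = 0.05) {
  forward <- run_sweep(pair, params, settings, eps, "forward", x_init,
                       jump_threshold = jump_threshold)
  backward <- run_sweep(pair, params, settings, eps, "backward",
                        x_init = forward$equilibria[, ncol(forward$equilibria)],
                        x_ref = forward$x_ref,
                        jump_threshold = jump_threshold)
  loop <- dplyr::inner_join(
    dplyr::select(forward$curves, "tau", sim_forward = "sim_to_initial"),
    dplyr::select(backward$curves, "tau", sim_backward = "sim_to_initial"),
    by = "tau"
  ) |>
    dplyr::mutate(gap = abs(.data$sim_forward - .data$sim_backward))
  max_gap <- max(loop$gap)
  structure(
    list(forward = forward, backward = backward, loop = loop,
         max_gap = max_gap, gap_tol = gap_tol,
         is_hysteretic = max_gap > gap_tol),
    class = "culture_hysteresis"
  )
}

#' Equilibria reached from different initial conditions
#'
#' Integrates each initial population to equilibrium on one fixed landscape
#' and reports the pairwise similarity matrix of the outcomes. On multi-peaked
#' (epistatic) landscapes, nearby initial conditions can settle into very
#' different equilibria.
#'
#' @param fitness Per-state fitness vector or `culture_landscape`.
#' @param inits List of initial populations (full-length vectors or
#'   `"uniform"`). Entries with zeros on viable states are floored at `floor`
#'   and renormalized so the log-variable integrator can represent them.
#' @inheritParams run_sweep
#' @param floor Smallest admissible viable fraction (default 1e-12).
#' @return A `culture_inits` object: `equilibria` (matrix, one column per
#'   initial condition), `similarity` (pairwise similarity matrix) and
#'   `summary` (tibble with per-init modal states).
#' @export
run_initial_conditions <- function(fitness, inits,
                                   params = dynamics_params(),
                                   settings = integrator_settings(),
                                   floor = 1e-12) {
  if (inherits(fitness, "culture_landscape")) fitness <- fitness$fitness
  n <- round(log2(length(fitness)))
  viable <- which(fitness > 0) - 1L
  engine <- make_engine(n, viable, params$alpha, dense = FALSE)
  gf <- engine_gfactors(engine, fitness, params$beta)
  kernel <- hamming_kernel(n)
  eqs <- vapply(inits, function(x0) {
    if (!identical(x0, "uniform")) {
      x0 <- pmax(x0, 0)
      x0[viable + 1L] <- pmax(x0[viable + 1L], floor)
      x0[-(viable + 1L)] <- 0
      x0 <- x0 / sum(x0)
    }
    run_integrator(x0, fitness, params, settings, viable = viable,
                   engine = engine, gf = gf)$x
  }, numeric(length(fitness)))
  k <- length(inits)
  simmat <- diag(1, k)
  if (k > 1) {
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      simmat[a, b] <- simmat[b, a] <-
        kernel_similarity(eqs[, a], eqs[, b], n, kernel)
    }
  }
  structure(
    list(
      equilibria = eqs,
      similarity = simmat,
      summary = purrr::map_dfr(seq_len(k), function(a) {
        dplyr::mutate(population_summary(eqs[, a], fitness), init = a,
                      .before = 1)
      })
    ),
    class = "culture_inits"
  )
}

#' Seeded ensemble of sweep / hysteresis experiments
#'
#' Repeats the quasi-static protocol over an ensemble of landscape pairs whose
#' master seeds are `seed, seed + 1, ...`, and summarizes how often jumps and
#' hysteresis occur. Single realizations are seed-specific, so claims about
#' when paradigm shifts happen are statistical.
#'
#' @param n_seeds Number of landscape pairs.
#' @param seed Master seed of the first pair.
#' @param n,k NK landscape parameters.
#' @param f_th,incompatible_count Incompatibility threshold specification
#'   passed to [landscape_pair()].
#' @inheritParams run_hysteresis
#' @param hysteresis When to run the backward branch: `"jumping"` (only for
#'   seeds whose forward sweep shows a detected jump; default), `"always"`, or
#'   `"never"`.
#' @return A `culture_ensemble` object whose `results` tibble has one row per
#'   seed: jump count, first jump location, largest single-step drop of the
#'   similarity-to-initial curve (`jump_size`) and its location, minimum
#'   step similarities, and (where run) the hysteresis gap.
#' @export
run_ensemble <- function(n_seeds, seed, n = 6, k, f_th = 0,
                         incompatible_count = NULL,
                         params = dynamics_params(),
                         settings = integrator_settings(), eps = 0.01,
                         jump_threshold = 0.9, gap_tol = 0.05,
                         hysteresis = c("jumping", "always", "never")) {
  hysteresis <- match.arg(hysteresis)
  seeds <- seed + seq_len(n_seeds) - 1L
  rows <- purrr::map_dfr(seeds, function(s) {
    pair <- landscape_pair(n, k, seed = s, f_th = f_th,
                           incompatible_count = incompatible_count)
    fwd <- run_sweep(pair, params, settings, eps,
                     jump_threshold = jump_threshold)
    drop <- -diff(fwd$curves$sim_to_initial)
    biggest <- which.max(drop)
    need_back <- hysteresis == "always" ||
      (hysteresis == "jumping" && nrow(fwd$jumps) > 0)
    max_gap <- NA_real_
    if (need_back) {
      bwd <- run_sweep(pair, params, settings, eps, "backward",
                       x_init = fwd$equilibria[, ncol(fwd$equilibria)],
                       x_ref = fwd$x_ref, jump_threshold = jump_threshold)
      gap <- abs(fwd$curves$sim_to_initial -
                   rev(bwd$curves$sim_to_initial))
      max_gap <- max(gap)
    }
    tibble::tibble(
      seed = s,
      n_jumps = nrow(fwd$jumps),
      first_jump_tau = if (nrow(fwd$jumps)) min(fwd$jumps$tau) else NA_real_,
      jump_size = max(drop, 0),
      jump_size_tau = fwd$curves$tau[biggest + 1L],
      min_sim_step = min(fwd$curves$sim_step, na.rm = TRUE),
      min_landscape_sim_step = min(fwd$curves$landscape_sim_step, na.rm = TRUE),
      final_sim_to_initial = fwd$curves$sim_to_initial[nrow(fwd$curves)],
      max_loop_gap = max_gap,
      is_hysteretic = !is.na(max_gap) & max_gap > gap_tol
    )
  })
  structure(
    list(results = rows, n = n, k = k, f_th = f_th,
         incompatible_count = incompatible_count, params = params,
         eps = eps, jump_threshold = jump_threshold, gap_tol = gap_tol,
         hysteresis = hysteresis, seed = seed),
    class = "culture_ensemble"
  )
}
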