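# broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.culture_sweep <- function(x, ...) {
  x$curves
}

#' @export
glance.culture_sweep <- function(x, ...) {
  tibble::tibble(
    direction = x$direction,
    eps = x$eps,
    n_jumps = nrow(x$jumps),
    first_jump_tau = if (nrow(x$jumps)) min(x$jumps$tau) else NA_real_,
    min_sim_step = min(x$curves$sim_step, na.rm = TRUE),
    min_landscape_sim_step = min(x$curves$landscape_sim_step, na.rm = TRUE),
    final_sim_to_initial = x$curves$sim_to_initial[nrow(x$curves)]
  )
}

#' @export
tidy.culture_hysteresis <- function(x, ...) {
  x$loop
}

#' @export
glance.culture_hysteresis <- function(x, ...) {
  tibble::tibble(
    max_gap = x$max_gap,
    gap_tol = x$gap_tol,
    is_hysteretic = x$is_hysteretic,
    n_jumps_forward = nrow(x$forward$jumps),
    n_jumps_backward = nrow(x$backward$jumps)
  )
}

#' @export
tidy.culture_ensemble <- function(x, ...) {
  x$results
}

#' @export
glance.culture_ensemble <- function(x, ...) {
  r <- x$results
  jumping <- r$n_jumps > 0
  tibble::tibble(
    n_seeds = nrow(r),
    jump_fraction = mean(jumping),
    mean_first_jump_tau = mean(r$first_jump_tau, na.rm = TRUE),
    mean_jump_size = mean(r$jump_size[jumping]),
    hysteresis_fraction = mean(r$is_hysteretic[!is.na(r$max_loop_gap)]),
    min_landscape_sim_step = min(r$min_landscape_sim_step)
  )
}

#' @export
tidy.culture_landscape <- function(x, ...) {
  tibble::tibble(
    index = 0:(2^x$n - 1L),
    bitstring = state_bitstring(0:(2^x$n - 1L), x$n),
    fitness = x$fitness,
    incompatible = x$incompatible
  )
}

#' @export
tidy.landscape_pair <- function(x, ...) {
  tibble::tibble(
    state_index = 0:(2^x$n - 1L),
    bitstring = state_bitstring(0:(2^x$n - 1L), x$n),
    F0 = x$F0$fitness,
    F1 = x$F1$fitness,
    incompatible = as.integer(x$incompatible)
  )
}

#' @export
print.culture_sweep <- function(x, ...) {
  cat(sprintf("<culture_sweep> %s, eps = %g, %d grid points, %d jump(s)\n",
              x$direction, x$eps, length(x$tau_grid), nrow(x$jumps)))
  print(glance(x))
  invisible(x)
}

#' @export
print.culture_hysteresis <- function(x, ...) {
  cat(sprintf("<culture_hysteresis> max loop gap %.4f (%shysteretic)\n",
              x$max_gap, if (x$is_hysteretic) "" else "not "))
  invisible(x)
}

#' @export
print.culture_landscape <- function(x, ...) {
  cat(sprintf("<culture_landscape> n = %d%s, %d incompatible state(s)\n",
              x$n,
              if (!is.na(x$k)) sprintf(", k = %d, seed = %s", x$k, x$seed) else "",
              sum(x$incompatible)))
  invisible(x)
}
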