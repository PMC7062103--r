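# ggplot2 presentation of sweep and hysteresis results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.culture_sweep <- function(object, ...) {
  curves <- tidyr::pivot_longer(
    object$curves[, c("tau", "sim_to_initial", "sim_step")],
    -"tau", names_to = "curve", values_to = "similarity"
  )
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$tau, y = .data$similarity,
                                    colour = .data$curve)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c(sim_to_initial = "#b2182b", sim_step = "#2166ac"),
      labels = c(sim_to_initial = "sim(x0, x_tau)",
                 sim_step = "sim(x_tau, x_tau-eps)")
    ) +
    ggplot2::labs(x = expression(tau), y = "similarity", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (nrow(object$jumps) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$jumps$tau,
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' @export
autoplot.culture_hysteresis <- function(object, ...) {
  loop <- tidyr::pivot_longer(object$loop[, c("tau", "sim_forward", "sim_backward")],
                              -"tau", names_to = "branch",
                              values_to = "similarity")
  ggplot2::ggplot(loop, ggplot2::aes(x = .data$tau, y = .data$similarity,
                                     colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(sim_forward = "#b2182b", sim_backward = "#2166ac"),
      labels = c(sim_forward = "tau increasing", sim_backward = "tau decreasing")
    ) +
    ggplot2::labs(x = expression(tau), y = "similarity to initial population",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.culture_ensemble <- function(object, ...) {
  r <- dplyr::filter(object$results, .data$n_jumps > 0)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$first_jump_tau,
                                  y = .data$jump_size)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "tau at first detected jump",
                  y = "jump size (drop of sim to initial)") +
    ggplot2::theme_minimal()
}
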