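#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_step labs
#'   facet_wrap theme_minimal
NULL

#' Plot the equilibrium gating curves of a potassium-current model
#'
#' @param model A [potassium_current_model()].
#' @param V_range Voltage range to draw, mV.
#' @return A ggplot object.
#' @export
plot_gating_curves <- function(model = potassium_current_model(),
                               V_range = c(-100, 0)) {
  V <- seq(V_range[1], V_range[2], length.out = 200)
  df <- dplyr::bind_rows(
    tibble(V = V, gate = "m (activation)",
           x = equilibrium_gate(V, model$m_gate)),
    tibble(V = V, gate = "h (inactivation)",
           x = equilibrium_gate(V, model$h_gate)),
    tibble(V = V, gate = "n (steady-state)",
           x = equilibrium_gate(V, model$n_gate)))
  ggplot(df, aes(.data$V, .data$x, colour = .data$gate)) +
    geom_line() +
    labs(x = "Voltage (mV)", y = "Equilibrium gate", colour = NULL) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sim_result <- function(object, ...) {
  if (is.null(object$trace)) abort("simulation was run with record = FALSE")
  ggplot(object$trace, aes(.data$t, .data$V)) +
    geom_line(linewidth = 0.3) +
    geom_point(data = tibble(t = object$spikes,
                             V = rep(max(object$trace$V) + 5,
                                     length(object$spikes))),
               shape = "|", size = 3) +
    labs(x = "Time (ms)", y = "Voltage (mV)") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.recording <- function(object, max_sweeps = 3, ...) {
  sub <- dplyr::filter(object, .data$sweep <= max_sweeps)
  long <- tidyr::pivot_longer(sub, c("V", "I"), names_to = "channel")
  ggplot(long, aes(.data$t, .data$value, group = .data$sweep)) +
    geom_line(linewidth = 0.2, alpha = 0.7) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "Time (ms)", y = NULL) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.network_sim <- function(object, ...) {
  ggplot(object$rates, aes(.data$t, .data$rate, colour = .data$population)) +
    geom_line(linewidth = 0.3) +
    labs(x = "Time (ms)", y = "Population rate (Hz/neuron)",
         colour = NULL) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gain_analysis <- function(object, ...) {
  ggplot(object$gain_t, aes(.data$t, .data$gain)) +
    geom_step() +
    labs(x = "Time (ms)", y = "Gain (Hz/nA)") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.derivative_encoding <- function(object, ...) {
  ggplot(object$peaks,
         aes(.data$slope, .data$peak_rate,
             colour = factor(.data$baseline))) +
    geom_line() + geom_point() +
    labs(x = "Ramp slope (pA/s)", y = "Peak 5-HT rate (Hz/neuron)",
         colour = "Baseline (pA)") +
    theme_minimal()
}
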