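#' Per-step spike probability of the escape-rate process
#'
#' For an inhomogeneous Poisson process with intensity `lambda_t` (Hz)
#' the probability of at least one spike in a bin of width `dt` (ms) is
#' `1 - exp(-lambda_t * dt / 1000)`.
#'
#' @param lambda_t Intensity, Hz (vectorized, >= 0).
#' @param dt Bin width, ms.
#' @return Probability in \[0, 1\].
#' @export
spike_probability <- function(lambda_t, dt = 0.1) {
  stopifnot(all(lambda_t >= 0), dt > 0)
  -expm1(-lambda_t * dt * 1e-3)
}

#' Escape-rate intensity of a GIF-family model
#'
#' \eqn{\lambda(t) = \lambda_0 \exp[(V - V_T^* - \gamma_{sum} + \theta)/\Delta V]}.
#' At `V = V_T_star` with no spike history (and zero `theta`) the
#' intensity equals `lambda_0` = 1 Hz.
#'
#' @param V Membrane potential, mV.
#' @param model A [gif_params()] family object.
#' @param gamma_sum Summed spike-triggered threshold movement, mV.
#' @param theta iGIF threshold offset, mV.
#' @return Intensity, Hz.
#' @export
escape_rate <- function(V, model, gamma_sum = 0, theta = 0) {
  stopifnot(inherits(model, "gif_params"))
  model$lambda_0 *
    exp((V - model$V_T_star - gamma_sum + theta) / model$DeltaV)
}

#' Simulate a GIF, aGIF or iGIF neuron
#'
#' Euler integration of the subthreshold dynamics at time step `dt`
#' (default 0.1 ms) with stochastic escape-rate spiking, or with the
#' supplied spike times imposed (`mode = "clamped"`, used to reconstruct
#' the subthreshold voltage with spikes constrained to match data).
#' On a spike the voltage is reset to `V_reset` and held for `T_ref`.
#'
#' Identical `(model, stimulus, seed)` give identical results; an aGIF
#' with both maximal conductances at zero reproduces the GIF trajectory
#' bit for bit.
#'
#' @param model A [gif_params()], [agif_params()] or [igif_params()].
#' @param stim Stimulus: a tibble with columns `t`, `I` (see [ou_noise()])
#'   or a numeric current vector (pA).
#' @param dt Time step, ms (taken from the stimulus if available).
#' @param V0 Initial voltage, mV (default `E_l`).
#' @param mode `"stochastic"` or `"clamped"`.
#' @param spike_times Imposed spike times, ms (clamped mode).
#' @param seed Optional integer seed (restores the session RNG afterwards).
#' @param record Keep the full state traces (voltage, gates, filters)?
#' @return An object of class `sim_result`: list with `spikes` (ms),
#'   `trace` (tibble `t`, `V`, `h`, `eta_sum`, `gamma_sum`, and `theta`
#'   for iGIF; `NULL` if `record = FALSE`), `dt` and `duration`.
#' @export
simulate_neuron <- function(model, stim, dt = NULL, V0 = model$E_l,
                            mode = c("stochastic", "clamped"),
                            spike_times = numeric(0), seed = NULL,
                            record = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "gif_params"))
  I <- stimulus_current(stim)
  if (any(!is.finite(I))) abort("stimulus current contains non-finite values")
  dt <- stimulus_dt(stim, dt)
  res <- with_seed(seed,
    sim_gif_cpp(as_sim_pars(model), I, dt, V0,
                stochastic = (mode == "stochastic"),
                forced_spike_times = spike_times, record = record))
  trace <- NULL
  if (record) {
    trace <- tibble(t = (seq_along(I) - 1) * dt, V = res$V, h = res$h,
                    eta_sum = res$eta_sum, gamma_sum = res$gamma_sum)
    if (inherits(model, "igif_params")) trace$theta <- res$theta
  }
  structure(list(spikes = res$spikes, trace = trace, dt = dt,
                 duration = length(I) * dt),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %.3g ms at dt = %.3g ms, %d spikes (%.2f Hz)\n",
              x$duration, x$dt, length(x$spikes),
              1000 * length(x$spikes) / x$duration))
  invisible(x)
}

#' @export
tidy.sim_result <- function(x, ...) {
  if (is.null(x$trace)) abort("simulation was run with record = FALSE")
  x$trace
}

#' Simulate the toy LIF with an inactivating potassium current
#'
#' Euler integration of the nondimensional toy model (time in units of
#' the membrane time constant, default step `0.001`), with deterministic
#' threshold crossing and instant reset.  The inactivation gate starts
#' at its equilibrium for `V0`.  Optional white current noise (standard
#' deviation `noise_sd`, in effective-voltage units) supports population
#' runs with independent background noise.
#'
#' @param params A [toy_lif_params()].
#' @param V_inj Effective input trace (mV, i.e. `I / g_l`): a numeric
#'   vector sampled at `dt_nd`, or a scalar held for `duration`.
#' @param V0 Initial voltage, mV.
#' @param dt_nd Time step in units of the membrane time constant.
#' @param duration Duration in membrane time constants (used when
#'   `V_inj` is scalar).
#' @param noise_sd White-noise standard deviation (0 = deterministic).
#' @param seed Optional integer seed.
#' @param record Keep the voltage/gate traces?
#' @return An object of class `toy_sim_result`: list with `spikes`
#'   (times in units of `tau_mem`), `latency` (first-spike latency, `NA`
#'   if no spike), `trace` and `dt_nd`.
#' @export
simulate_toy <- function(params, V_inj, V0 = params$E_l, dt_nd = 0.001,
                         duration = 10, noise_sd = 0, seed = NULL,
                         record = TRUE) {
  stopifnot(inherits(params, "toy_lif_params"), dt_nd > 0)
  if (length(V_inj) == 1) V_inj <- rep(V_inj, ceiling(duration / dt_nd))
  res <- with_seed(seed,
    sim_toy_cpp(params$E_l, params$E_K, params$g_A_eff, params$tau_h_eff,
                unlist(params$m_gate[c("A", "k", "V_star")], use.names = FALSE),
                unlist(params$h_gate[c("A", "k", "V_star")], use.names = FALSE),
                params$V_T, params$V_reset, V_inj, V0, dt_nd, noise_sd,
                record))
  trace <- NULL
  if (record)
    trace <- tibble(t = (seq_along(V_inj) - 1) * dt_nd, V = res$V, h = res$h)
  structure(list(spikes = res$spikes, latency = res$latency,
                 trace = trace, dt_nd = dt_nd),
            class = "toy_sim_result")
}

#' First-spike latencies of a toy-model population
#'
#' Simulates `n` toy neurons receiving a shared effective input step and
#' independent white background noise, and collects first-spike
#' latencies.  This is the protocol used to show that the A-type current
#' desynchronizes a population's response to a sudden input: with a
#' substantial `g_A_eff` the first-spike times are more jittered (larger
#' SD) and the latency histogram is lower and broader than without.
#'
#' @param params A [toy_lif_params()].
#' @param V_inj Effective input (scalar or trace, mV).
#' @param n Number of neurons.
#' @param V0 Initial voltage, mV.
#' @param noise_sd Background white-noise SD per neuron.
#' @param duration Simulation horizon in membrane time constants.
#' @param dt_nd Time step (units of `tau_mem`).
#' @param seed Optional integer seed.
#' @return A tibble with columns `neuron` and `latency` (units of
#'   `tau_mem`; `NA` when the neuron never spiked).
#' @export
toy_population_latencies <- function(params, V_inj, n = 600, V0 = params$E_l,
                                     noise_sd = 2, duration = 10,
                                     dt_nd = 0.001, seed = NULL) {
  with_seed(seed, {
    lat <- vapply(seq_len(n), function(i) {
      simulate_toy(params, V_inj, V0 = V0, dt_nd = dt_nd,
                   duration = duration, noise_sd = noise_sd,
                   record = FALSE)$latency
    }, 0)
    tibble(neuron = seq_len(n), latency = lat)
  })
}
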