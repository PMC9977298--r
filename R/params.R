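#' Exponential-basis filter coefficients
#'
#' Spike-triggered filters are sums of exponentials,
#' \eqn{f(s) = \sum_j w_j \exp(-s/\tau_j)}, evaluated at the lag `s` since
#' each past spike.  Used both for the adaptation current `eta` (weights in
#' pA; positive values are hyperpolarizing) and the threshold movement
#' `gamma` (weights in mV).  The timescales are fixed hyperparameters;
#' the default log-spaced basis spans the multi-second adaptation seen in
#' dorsal raphe 5-HT neurons.
#'
#' @param weights Basis coefficients (pA for eta, mV for gamma).
#' @param timescales Basis time constants, ms; strictly positive and
#'   increasing, same length as `weights`.
#' @return An object of class `filter_coeffs`.
#' @export
filter_coeffs <- function(weights,
                          timescales = default_filter_timescales()) {
  stopifnot(length(weights) == length(timescales),
            all(timescales > 0), !is.unsorted(timescales, strictly = TRUE))
  structure(list(weights = as.numeric(weights),
                 timescales = as.numeric(timescales)),
            class = "filter_coeffs")
}

#' @rdname filter_coeffs
#' @export
default_filter_timescales <- function() c(10, 30, 100, 300, 1000, 3000)

#' Evaluate a spike-triggered filter at a lag
#'
#' @param f A [filter_coeffs()] object.
#' @param lag Lag since the spike, ms (vectorized, must be >= 0).
#' @return Filter value(s).
#' @export
eval_filter <- function(f, lag) {
  stopifnot(inherits(f, "filter_coeffs"))
  if (any(lag < 0)) abort("lag must be non-negative")
  vapply(lag, function(s) sum(f$weights * exp(-s / f$timescales)), 0)
}

#' Time-integral of a spike-triggered filter
#'
#' \eqn{\int_0^\infty f(s)\,ds = \sum_j w_j \tau_j}; a summary of
#' adaptation potency (pA ms for eta, mV ms for gamma).
#' @param f A [filter_coeffs()] object.
#' @export
filter_integral <- function(f) {
  stopifnot(inherits(f, "filter_coeffs"))
  sum(f$weights * f$timescales)
}

validate_gif_core <- function(p) {
  stopifnot(p$C > 0, p$g_l > 0, p$DeltaV > 0, p$T_ref > 0,
            inherits(p$eta, "filter_coeffs"),
            inherits(p$gamma, "filter_coeffs"))
  invisible(p)
}

#' Generalized integrate-and-fire (GIF) parameter set
#'
#' The GIF combines a leaky subthreshold membrane
#' \deqn{C\,dV/dt = -g_l (V - E_l) - \sum_{\hat t_i < t} \eta(t - \hat t_i) + I(t)}
#' with escape-rate spiking: spikes are emitted as an inhomogeneous
#' Poisson process with intensity
#' \deqn{\lambda(t) = \lambda_0 \exp[(V - V_T^* - \sum \gamma(t - \hat t_i)) / \Delta V]}
#' where \eqn{\lambda_0 = 1} Hz.  After each spike the voltage is reset to
#' `V_reset` and held for the absolute refractory period `T_ref`.
#'
#' @param C Membrane capacitance, pF.
#' @param g_l Leak conductance, nS.
#' @param E_l Leak reversal potential, mV.
#' @param eta Spike-triggered adaptation current, a [filter_coeffs()] (pA).
#' @param gamma Spike-triggered threshold movement, a [filter_coeffs()] (mV).
#' @param V_T_star Stationary threshold, mV.
#' @param DeltaV Threshold sharpness, mV (> 0); larger values make spiking
#'   more stochastic.
#' @param V_reset Post-spike reset voltage, mV.
#' @param T_ref Absolute refractory period, ms.
#' @param lambda_0 Escape-rate scale, Hz (fixed at 1).
#' @return An object of class `gif_params`.
#' @export
gif_params <- function(C, g_l, E_l, eta, gamma, V_T_star, DeltaV,
                       V_reset, T_ref, lambda_0 = 1) {
  p <- structure(list(C = C, g_l = g_l, E_l = E_l, eta = eta, gamma = gamma,
                      V_T_star = V_T_star, DeltaV = DeltaV,
                      V_reset = V_reset, T_ref = T_ref, lambda_0 = lambda_0),
                 class = "gif_params")
  validate_gif_core(p)
}

#' Augmented GIF (aGIF) parameter set
#'
#' A [gif_params()] whose subthreshold equation additionally includes the
#' experimentally constrained potassium currents \eqn{I_A} and \eqn{I_K}
#' (see [potassium_current_model()]):
#' \deqn{C\,dV/dt = -g_l (V - E_l) - I_A - I_K - \sum \eta + I(t).}
#' With both maximal conductances at zero the model reduces exactly to
#' the GIF.
#'
#' @inheritParams gif_params
#' @param k_currents A [potassium_current_model()].
#' @return An object of class `c("agif_params", "gif_params")`.
#' @export
agif_params <- function(C, g_l, E_l, eta, gamma, V_T_star, DeltaV,
                        V_reset, T_ref, k_currents = potassium_current_model(),
                        lambda_0 = 1) {
  stopifnot(inherits(k_currents, "k_current_model"))
  p <- gif_params(C, g_l, E_l, eta, gamma, V_T_star, DeltaV,
                  V_reset, T_ref, lambda_0)
  p$k_currents <- k_currents
  class(p) <- c("agif_params", "gif_params")
  p
}

#' Inactivation GIF (iGIF) parameter set
#'
#' A [gif_params()] with an extra threshold variable `theta` added to the
#' numerator of the escape-rate exponent.  `theta` relaxes toward a
#' piecewise-constant function of voltage,
#' \eqn{\theta_\infty(V) = \beta_j} for `V` in `[A_j, A_{j+1})`, with time
#' constant `tau_theta`.  With all steps at zero the model reduces
#' exactly to the GIF.
#'
#' @inheritParams gif_params
#' @param theta_steps Step values \eqn{\beta_j}, mV (default 5 bins).
#' @param bin_edges Bin edges \eqn{A_j}, mV, strictly increasing, of
#'   length `length(theta_steps) + 1`.  Voltages outside the covered
#'   range take the first/last step value.
#' @param tau_theta Relaxation time constant of `theta`, ms.
#' @return An object of class `c("igif_params", "gif_params")`.
#' @export
igif_params <- function(C, g_l, E_l, eta, gamma, V_T_star, DeltaV,
                        V_reset, T_ref, theta_steps, bin_edges,
                        tau_theta = 5, lambda_0 = 1) {
  stopifnot(length(bin_edges) == length(theta_steps) + 1,
            !is.unsorted(bin_edges, strictly = TRUE), tau_theta > 0)
  p <- gif_params(C, g_l, E_l, eta, gamma, V_T_star, DeltaV,
                  V_reset, T_ref, lambda_0)
  p$theta_steps <- as.numeric(theta_steps)
  p$bin_edges <- as.numeric(bin_edges)
  p$tau_theta <- tau_theta
  class(p) <- c("igif_params", "gif_params")
  p
}

#' Equilibrium threshold offset of the iGIF
#'
#' @param V Membrane potential, mV (vectorized).
#' @param model An [igif_params()] object.
#' @return `theta_inf(V)` in mV.
#' @export
theta_infinity <- function(V, model) {
  stopifnot(inherits(model, "igif_params"))
  edges <- model$bin_edges
  beta <- model$theta_steps
  idx <- findInterval(V, edges[-c(1, length(edges))]) + 1
  beta[pmin(pmax(idx, 1), length(beta))]
}

#' @export
print.gif_params <- function(x, ...) {
  kind <- if (inherits(x, "agif_params")) "aGIF"
          else if (inherits(x, "igif_params")) "iGIF" else "GIF"
  cat(sprintf("<%s> C = %.3g pF, g_l = %.3g nS (tau_mem = %.3g ms), E_l = %.3g mV\n",
              kind, x$C, x$g_l, x$C / x$g_l, x$E_l))
  cat(sprintf("  V_T* = %.3g mV, DeltaV = %.3g mV, V_reset = %.3g mV, T_ref = %.3g ms\n",
              x$V_T_star, x$DeltaV, x$V_reset, x$T_ref))
  cat(sprintf("  eta(0) = %.3g pA, gamma(0) = %.3g mV\n",
              sum(x$eta$weights), sum(x$gamma$weights)))
  if (inherits(x, "agif_params"))
    cat(sprintf("  g_A = %.3g nS, g_K = %.3g nS, E_K = %.3g mV, tau_h = %.3g ms\n",
                x$k_currents$g_A_bar, x$k_currents$g_K_bar,
                x$k_currents$E_K, x$k_currents$tau_h))
  invisible(x)
}

#' Toy nondimensional LIF with an inactivating potassium current
#'
#' A leaky integrate-and-fire neuron augmented with the A-type current,
#' nondimensionalized with respect to the membrane time constant and
#' leak conductance:
#' \deqn{dV/dt = E_l - V - \bar g_A' m_\infty(V) h (V - E_K) + V_{inj}(t)}
#' with time in units of `tau_mem`, conductance relative to `g_l`
#' (`g_A_eff = g_A / g_l`), inputs as effective voltages
#' (`V_inj = I / g_l`), and a deterministic threshold with instant reset.
#'
#' @param E_l,E_K Leak / potassium reversal potentials, mV.
#' @param g_A_eff Effective maximal A-type conductance, `g_A / g_l` (>= 0).
#' @param tau_h_eff Effective inactivation time constant, `tau_h / tau_mem`.
#' @param V_T Deterministic spike threshold, mV.
#' @param V_reset Post-spike reset voltage, mV.
#' @param m_gate,h_gate Activation / inactivation [gating_params()];
#'   defaults are the measured 5-HT curves.
#' @return An object of class `toy_lif_params`.
#' @export
toy_lif_params <- function(E_l = -60, E_K = -101, g_A_eff = 10,
                           tau_h_eff = 1.2, V_T = -45, V_reset = -70,
                           m_gate = serotonin_gates()$m,
                           h_gate = serotonin_gates()$h) {
  stopifnot(g_A_eff >= 0, tau_h_eff > 0, V_reset < V_T,
            inherits(m_gate, "gating_params"),
            inherits(h_gate, "gating_params"))
  structure(list(E_l = E_l, E_K = E_K, g_A_eff = g_A_eff,
                 tau_h_eff = tau_h_eff, V_T = V_T, V_reset = V_reset,
                 m_gate = m_gate, h_gate = h_gate),
            class = "toy_lif_params")
}

# Flatten a gif_params family object into the list layout the C++
# integrator expects.  GIF: zero conductances; iGIF: theta fields filled.
as_sim_pars <- function(p) {
  stopifnot(inherits(p, "gif_params"))
  kc <- if (inherits(p, "agif_params")) p$k_currents else NULL
  gates <- if (is.null(kc)) serotonin_gates() else
    list(m = kc$m_gate, h = kc$h_gate, n = kc$n_gate)
  list(
    C = p$C, g_l = p$g_l, E_l = p$E_l, V_T_star = p$V_T_star,
    DeltaV = p$DeltaV, lambda_0 = p$lambda_0, V_reset = p$V_reset,
    T_ref = p$T_ref,
    eta_w = p$eta$weights, eta_tau = p$eta$timescales,
    gamma_w = p$gamma$weights, gamma_tau = p$gamma$timescales,
    g_A = if (is.null(kc)) 0 else kc$g_A_bar,
    g_K = if (is.null(kc)) 0 else kc$g_K_bar,
    E_K = if (is.null(kc)) -101 else kc$E_K,
    tau_h = if (is.null(kc)) 42.9 else kc$tau_h,
    m_gate = unlist(gates$m[c("A", "k", "V_star")], use.names = FALSE),
    h_gate = unlist(gates$h[c("A", "k", "V_star")], use.names = FALSE),
    n_gate = unlist(gates$n[c("A", "k", "V_star")], use.names = FALSE),
    theta_beta = if (inherits(p, "igif_params")) p$theta_steps else numeric(0),
    theta_edges = if (inherits(p, "igif_params")) p$bin_edges else numeric(0),
    tau_theta = if (inherits(p, "igif_params")) p$tau_theta else 1
  )
}
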