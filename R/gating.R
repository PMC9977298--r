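#' Scaled-Boltzmann gating parameters
#'
#' Container for one equilibrium gating curve of the form
#' \deqn{x_\infty(V) = A / (1 + \exp[-k (V - V^*)])}
#' where `A` is a dimensionless scale factor, `k` the slope (1/mV) and
#' `V_star` the half-activation voltage (mV).  At `V = V_star` the gate
#' evaluates to `A / 2`; the curve is strictly increasing in `V` when
#' `k > 0` and strictly decreasing when `k < 0`.
#'
#' @param A Dimensionless scale factor (> 0).
#' @param k Slope, 1/mV.  Sign sets the direction of the curve.
#' @param V_star Half-activation voltage, mV.
#' @return An object of class `gating_params`.
#' @examples
#' m <- gating_params(1.61, 0.0985, -23.7)
#' equilibrium_gate(-23.7, m) # A / 2
#' @export
gating_params <- function(A, k, V_star) {
  stopifnot(is.numeric(A), length(A) == 1, A > 0,
            is.numeric(k), length(k) == 1, k != 0,
            is.numeric(V_star), length(V_star) == 1)
  structure(list(A = A, k = k, V_star = V_star), class = "gating_params")
}

#' @export
print.gating_params <- function(x, ...) {
  cat(sprintf("<gating_params> A = %.4g, k = %.4g mV^-1, V* = %.4g mV\n",
              x$A, x$k, x$V_star))
  invisible(x)
}

#' Measured gating curves of the serotonin-neuron potassium currents
#'
#' Equilibrium gate parameters for the activation (`m`), inactivation (`h`)
#' and steady-state activation (`n`) gates of the voltage-gated potassium
#' currents recorded in dorsal raphe 5-HT neurons.
#'
#' @return A named list of three [gating_params()] objects (`m`, `h`, `n`).
#' @export
serotonin_gates <- function() {
  list(m = gating_params(1.61, 0.0985, -23.7),
       h = gating_params(1.03, -0.165, -59.2),
       n = gating_params(1.55, 0.216, -24.3))
}

#' Evaluate an equilibrium gate
#'
#' @param V Membrane potential, mV (vectorized).
#' @param g A [gating_params()] object.
#' @return Gate fraction(s), dimensionless.
#' @export
equilibrium_gate <- function(V, g) {
  stopifnot(inherits(g, "gating_params"))
  g$A / (1 + exp(-g$k * (V - g$V_star)))
}

#' Potassium-current model of a 5-HT neuron
#'
#' Bundles the transient (inactivating) A-type current \eqn{I_A} and its
#' non-inactivating counterpart \eqn{I_K}:
#' \deqn{I_A = \bar g_A\, m_\infty(V)\, h\, (V - E_K), \qquad
#'       I_K = \bar g_K\, n_\infty(V)\, (V - E_K).}
#' The `m` and `n` gates are treated as instantaneous; the `h` gate
#' relaxes toward \eqn{h_\infty(V)} with a single voltage-independent
#' time constant `tau_h`.
#'
#' `E_K = -101` mV corresponds to room-temperature recording conditions;
#' use `-89.1` mV for near-physiological temperature.
#'
#' @param g_A_bar Maximal A-type conductance, nS (>= 0).
#' @param g_K_bar Maximal non-inactivating conductance, nS (>= 0).
#' @param E_K Potassium reversal potential, mV.
#' @param tau_h Inactivation time constant, ms (> 0).
#' @param m_gate,h_gate,n_gate [gating_params()] for the three gates;
#'   defaults are the measured 5-HT curves ([serotonin_gates()]).
#' @return An object of class `k_current_model`.
#' @export
potassium_current_model <- function(g_A_bar = 10, g_K_bar = 1.6,
                                    E_K = -101, tau_h = 42.9,
                                    m_gate = serotonin_gates()$m,
                                    h_gate = serotonin_gates()$h,
                                    n_gate = serotonin_gates()$n) {
  stopifnot(g_A_bar >= 0, g_K_bar >= 0, tau_h > 0,
            inherits(m_gate, "gating_params"),
            inherits(h_gate, "gating_params"),
            inherits(n_gate, "gating_params"))
  structure(list(g_A_bar = g_A_bar, g_K_bar = g_K_bar, E_K = E_K,
                 tau_h = tau_h, m_gate = m_gate, h_gate = h_gate,
                 n_gate = n_gate),
            class = "k_current_model")
}

#' Instantaneous potassium currents
#'
#' @param V Membrane potential, mV (vectorized).
#' @param h Inactivation state in \[0, A_h\] (scalar or same length as `V`).
#' @param model A [potassium_current_model()].
#' @return A tibble with columns `I_A` and `I_K` (pA).
#' @export
potassium_currents <- function(V, h, model) {
  stopifnot(inherits(model, "k_current_model"))
  drive <- V - model$E_K
  tibble(
    I_A = model$g_A_bar * equilibrium_gate(V, model$m_gate) * h * drive,
    I_K = model$g_K_bar * equilibrium_gate(V, model$n_gate) * drive
  )
}

#' One exponential-integrator update of the inactivation gate
#'
#' Advances `h` by `dt` at fixed voltage `V`:
#' `h' = h_inf(V) + (h - h_inf(V)) exp(-dt / tau_h)`.
#'
#' @param h Current inactivation state.
#' @param V Membrane potential, mV.
#' @param dt Time step, ms (> 0).
#' @param model A [potassium_current_model()].
#' @return Updated inactivation state.
#' @export
update_h <- function(h, V, dt, model) {
  stopifnot(dt > 0, inherits(model, "k_current_model"))
  hinf <- equilibrium_gate(V, model$h_gate)
  hinf + (h - hinf) * exp(-dt / model$tau_h)
}

#' Fit a scaled Boltzmann to a normalized conductance curve
#'
#' Least-squares fit of `A / (1 + exp[-k (V - V*)])` to samples of a
#' normalized equilibrium conductance, as used to characterize gating
#' curves from voltage-clamp families.  Initialization: the sign of `k`
#' is seeded from the empirical slope and `V*` from the half-range
#' crossing, to avoid local minima.
#'
#' @param V_grid Voltages, mV (>= 4 distinct values spanning the transition).
#' @param normalized_conductance Conductance samples normalized to a
#'   reference voltage (same length as `V_grid`).
#' @return An object of class `gating_fit`: a list with elements `params`
#'   (a [gating_params()] on success, `NULL` otherwise), `converged`,
#'   `residual_norm` and `diagnostics`.
#' @export
fit_gating_params <- function(V_grid, normalized_conductance) {
  stopifnot(length(V_grid) == length(normalized_conductance),
            length(unique(V_grid)) >= 4)
  y <- normalized_conductance
  if (sd(y) < sqrt(.Machine$double.eps) * max(1, abs(mean(y)))) {
    return(structure(list(params = NULL, converged = FALSE,
                          residual_norm = NA_real_,
                          diagnostics = "no transition: input samples have zero variance"),
                     class = "gating_fit"))
  }
  # initialize: slope sign from empirical trend, V* at the half-range crossing
  slope <- coef(lm.fit(cbind(1, V_grid), y))[2]
  k0 <- if (slope >= 0) 0.1 else -0.1
  half <- (max(y) + min(y)) / 2
  V0 <- V_grid[which.min(abs(y - half))]
  A0 <- if (slope >= 0) max(y) else max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A / (1 + exp(-k * (V_grid - Vs))),
      start = list(A = A0, k = k0, Vs = V0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(params = NULL, converged = FALSE,
                          residual_norm = NA_real_,
                          diagnostics = conditionMessage(fit)),
                     class = "gating_fit"))
  }
  cf <- coef(fit)
  structure(list(
    params = gating_params(unname(cf["A"]), unname(cf["k"]), unname(cf["Vs"])),
    converged = TRUE,
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    diagnostics = NULL), class = "gating_fit")
}

#' @export
tidy.gating_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(term = c("A", "k", "V_star"), estimate = NA_real_))
  }
  tibble(term = c("A", "k", "V_star"),
         estimate = c(x$params$A, x$params$k, x$params$V_star))
}

#' @export
glance.gating_fit <- function(x, ...) {
  tibble(converged = x$converged, residual_norm = x$residual_norm)
}

#' Summarize a transient (inactivating) current trace
#'
#' Extracts the peak, peak latency, steady-state amplitude and
#' inactivation time constant from a leak-subtracted current evoked by a
#' voltage step.  The steady state is the mean over the final 10% of the
#' trace; `tau_inact` comes from a monoexponential least-squares fit
#' `a * exp(-t / tau) + c` over the decay phase (peak sample to the end
#' of the step), with `c` seeded at the final-50 ms mean.  If the trace
#' does not decay (steady state >= peak) `tau_inact` is `NA`.
#'
#' @param trace Leak-subtracted current samples, pA.
#' @param step_onset Step onset, ms.
#' @param dt Sample interval, ms.
#' @return A one-row tibble: `peak_amplitude` (pA), `peak_latency` (ms,
#'   relative to onset), `steady_state_amplitude` (pA), `tau_inact` (ms).
#' @export
characterize_transient_current <- function(trace, step_onset, dt = 0.1) {
  stopifnot(dt > 0, step_onset >= 0)
  t <- (seq_along(trace) - 1) * dt
  post <- which(t >= step_onset)
  if (length(post) < 10) abort("trace too short after step onset")
  ipk <- post[which.max(trace[post])]
  peak <- trace[ipk]
  latency <- t[ipk] - step_onset
  n <- length(trace)
  steady_idx <- seq.int(max(post[1], n - ceiling(0.10 * length(post)) + 1), n)
  steady <- mean(trace[steady_idx])

  tau <- NA_real_
  if (peak > steady + sqrt(.Machine$double.eps) * max(1, abs(peak))) {
    decay_idx <- seq.int(ipk, n)
    td <- t[decay_idx] - t[ipk]
    yd <- trace[decay_idx]
    c0 <- mean(trace[t >= max(t) - 50])
    a0 <- peak - c0
    tau0 <- max(td[length(td)] / 5, dt)
    fit <- tryCatch(
      minpack.lm::nlsLM(yd ~ a * exp(-td / tau) + c,
                        start = list(a = a0, tau = tau0, c = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) tau <- unname(coef(fit)["tau"])
  }
  tibble(peak_amplitude = peak, peak_latency = latency,
         steady_state_amplitude = steady, tau_inact = tau)
}
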