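#' Template single-neuron model for a cell type
#'
#' Membrane parameters follow the measured population means (5-HT:
#' R = 1.16 GOhm, C = 67.0 pF; SOM: R = 1.07 GOhm, C = 43.5 pF; mPFC:
#' R = 0.188 GOhm, C = 160.6 pF).  5-HT templates are aGIFs whose
#' maximal potassium conductances derive from the measured
#' voltage-clamp amplitudes (transient 928 - 142 pA, steady 142 pA at
#' -20 mV from a -90 mV hold with E_K = -101 mV), giving roughly 10 nS
#' of A-type and 1.6 nS of steady-state conductance.  Adaptation filters
#' are potent and protracted in 5-HT neurons and weak in SOM neurons.
#'
#' @param cell_type One of `"5-HT"`, `"SOM"`, `"mPFC"`.
#' @return A [gif_params()] or [agif_params()] object.
#' @export
cell_type_template <- function(cell_type = c("5-HT", "SOM", "mPFC")) {
  cell_type <- match.arg(cell_type)
  taus <- default_filter_timescales()
  switch(cell_type,
    "5-HT" = agif_params(
      C = 67, g_l = 1 / 1.16, E_l = -70,
      eta = filter_coeffs(c(30, 20, 12, 6, 3, 2), taus),
      gamma = filter_coeffs(c(6, 4, 2.5, 1.5, 1, 0.5), taus),
      V_T_star = -45, DeltaV = 2, V_reset = -55, T_ref = 6.5,
      k_currents = potassium_current_model(g_A_bar = 10, g_K_bar = 1.6)),
    "SOM" = gif_params(
      C = 43.5, g_l = 1 / 1.07, E_l = -65,
      eta = filter_coeffs(c(25, 16, 8, 4, 2, 1), taus),
      gamma = filter_coeffs(c(3, 2, 1, 0.5, 0.3, 0.2), taus),
      V_T_star = -50, DeltaV = 2, V_reset = -60, T_ref = 4),
    "mPFC" = gif_params(
      C = 160.6, g_l = 1 / 0.188, E_l = -70,
      eta = filter_coeffs(c(40, 25, 12, 5, 2, 1), taus),
      gamma = filter_coeffs(c(8, 5, 3, 1, 0.5, 0.2), taus),
      V_T_star = -50, DeltaV = 1, V_reset = -60, T_ref = 4))
}

#' Heterogeneity specification for a synthetic model bank
#'
#' Coefficients of variation (lognormal jitter) for positive parameters
#' and standard deviations in mV (normal jitter) for potentials.  The
#' membrane CVs follow the measured population spreads (5-HT: R CV 0.47,
#' C CV 0.26; SOM: R CV 0.54, C CV 0.36); SOM neurons use larger CVs on
#' the excitability-related parameters, matching their reported
#' heterogeneity.
#'
#' @param cell_type One of `"5-HT"`, `"SOM"`, `"mPFC"`.
#' @return A named list with elements `R`, `C`, `g_A`, `g_K`, `eta`,
#'   `gamma` (CVs) and `E_l`, `V_T_star` (SDs, mV).
#' @export
heterogeneity_defaults <- function(cell_type = c("5-HT", "SOM", "mPFC")) {
  cell_type <- match.arg(cell_type)
  switch(cell_type,
    "5-HT" = list(R = 0.47, C = 0.26, g_A = 0.3, g_K = 0.3,
                  eta = 0.3, gamma = 0.3, E_l = 2, V_T_star = 2),
    "SOM"  = list(R = 0.54, C = 0.36, g_A = 0, g_K = 0,
                  eta = 0.6, gamma = 0.6, E_l = 5, V_T_star = 6),
    "mPFC" = list(R = 0.69, C = 0.30, g_A = 0, g_K = 0,
                  eta = 0.3, gamma = 0.3, E_l = 2, V_T_star = 2))
}

rlnorm_mean <- function(n, m, cv) {
  if (cv <= 0 || m == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic bank of single-neuron models
#'
#' Draws `n_models` parameter sets around the cell type's template by
#' jittering positive parameters lognormally (mean-preserving, at the
#' requested coefficient of variation) and potentials normally, then
#' checking validity (each draw must construct a valid parameter set;
#' invalid draws are retried up to 100 times).  Membrane resistance is
#' jittered (rather than the leak conductance) so the bank's mean R
#' matches the template's.  Adaptation filters are scaled by one
#' lognormal factor per filter, preserving their shape.
#'
#' @param cell_type One of `"5-HT"`, `"SOM"`, `"mPFC"`.
#' @param n_models Number of models.
#' @param heterogeneity A spec as returned by [heterogeneity_defaults()];
#'   an all-zero spec yields identical copies of the template.
#' @param seed Optional integer seed.
#' @return An object of class `model_bank`: list with `cell_type`,
#'   `models` (list of parameter sets) and `provenance`.
#' @export
generate_bank <- function(cell_type = c("5-HT", "SOM", "mPFC"),
                          n_models = 100,
                          heterogeneity = heterogeneity_defaults(cell_type),
                          seed = NULL) {
  cell_type <- match.arg(cell_type)
  tmpl <- cell_type_template(cell_type)
  hs <- heterogeneity
  models <- with_seed(seed, lapply(seq_len(n_models), function(i) {
    for (try in 1:100) {
      m <- tryCatch(jitter_model(tmpl, hs), error = function(e) NULL)
      if (!is.null(m)) return(m)
    }
    abort("no valid parameter draw after 100 retries")
  }))
  structure(list(cell_type = cell_type, models = models,
                 provenance = list(kind = "synthetic", seed = seed,
                                   heterogeneity = hs)),
            class = "model_bank")
}

jitter_model <- function(tmpl, hs) {
  R <- rlnorm_mean(1, 1 / tmpl$g_l, hs$R)
  C <- rlnorm_mean(1, tmpl$C, hs$C)
  eta <- filter_coeffs(tmpl$eta$weights * rlnorm_mean(1, 1, hs$eta),
                       tmpl$eta$timescales)
  gamma <- filter_coeffs(tmpl$gamma$weights * rlnorm_mean(1, 1, hs$gamma),
                         tmpl$gamma$timescales)
  E_l <- rnorm(1, tmpl$E_l, hs$E_l)
  V_T <- rnorm(1, tmpl$V_T_star, hs$V_T_star)
  if (V_T <= tmpl$V_reset + 2) abort("threshold drawn at or below reset")
  if (inherits(tmpl, "agif_params")) {
    kc <- tmpl$k_currents
    kc$g_A_bar <- rlnorm_mean(1, kc$g_A_bar, hs$g_A)
    kc$g_K_bar <- rlnorm_mean(1, kc$g_K_bar, hs$g_K)
    agif_params(C, 1 / R, E_l, eta, gamma, V_T, tmpl$DeltaV,
                tmpl$V_reset, tmpl$T_ref, k_currents = kc)
  } else {
    gif_params(C, 1 / R, E_l, eta, gamma, V_T, tmpl$DeltaV,
               tmpl$V_reset, tmpl$T_ref)
  }
}

#' @export
print.model_bank <- function(x, ...) {
  cat(sprintf("<model_bank> %d %s models (%s)\n", length(x$models),
              x$cell_type, x$provenance$kind))
  invisible(x)
}

#' @export
as_tibble.model_bank <- function(x, ...) {
  purrr::map_dfr(seq_along(x$models), function(i) {
    p <- x$models[[i]]
    tibble(model = i, C = p$C, g_l = p$g_l, R = 1 / p$g_l, E_l = p$E_l,
           tau_mem = p$C / p$g_l, V_T_star = p$V_T_star,
           DeltaV = p$DeltaV, V_reset = p$V_reset, T_ref = p$T_ref,
           g_A = if (inherits(p, "agif_params")) p$k_currents$g_A_bar else 0,
           g_K = if (inherits(p, "agif_params")) p$k_currents$g_K_bar else 0,
           eta_integral = filter_integral(p$eta),
           gamma_integral = filter_integral(p$gamma))
  })
}

#' Surrogate current-clamp recording from a known model
#'
#' Simulates a ground-truth model on each sweep of a stimulus protocol
#' (stochastic spiking) and packages the result as a [recording()],
#' optionally adding white Gaussian observation noise to the voltage.
#' Same seed, same recording, bitwise.
#'
#' @param model A [gif_params()]-family object.
#' @param protocol A stimulus tibble (`t`, `I`) or list of them (one per
#'   sweep; a single stimulus is repeated `n_sweeps` times as frozen
#'   noise, so sweeps differ only through spiking stochasticity).
#' @param n_sweeps Number of sweeps when `protocol` is a single stimulus.
#' @param obs_noise_sd Observation noise SD on V, mV.
#' @param cell_type Stored in the recording metadata.
#' @param spike_amp Voltage written at each spike sample (mV), standing in
#'   for the action-potential waveform so that threshold-crossing spike
#'   detection behaves as it does on experimental sweeps.
#' @param seed Optional integer seed.
#' @return A [recording()] whose metadata records the generator.
#' @export
generate_surrogate_recording <- function(model, protocol, n_sweeps = 1,
                                         obs_noise_sd = 0,
                                         cell_type = "5-HT",
                                         spike_amp = 30, seed = NULL) {
  stims <- if (is.data.frame(protocol)) rep(list(protocol), n_sweeps)
           else protocol
  dt <- stimulus_dt(stims[[1]])
  with_seed(seed, {
    sw <- purrr::map_dfr(seq_along(stims), function(s) {
      I <- stimulus_current(stims[[s]])
      sim <- simulate_neuron(model, I, dt = dt, record = TRUE)
      V <- sim$trace$V
      V[round(sim$spikes / dt) + 1] <- spike_amp
      if (obs_noise_sd > 0) V <- V + rnorm(length(V), 0, obs_noise_sd)
      tibble(sweep = s, t = sim$trace$t, V = V, I = I)
    })
    recording(sw, dt, cell_type,
              metadata = list(generator = class(model)[1], seed = seed,
                              obs_noise_sd = obs_noise_sd))
  })
}
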