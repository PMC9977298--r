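# Small parameter sets and spike-train generators shared across tests.

quick_gif <- function(DeltaV = 2, eta_w = rep(0, 6), gamma_w = rep(0, 6),
                      V_T_star = -45, E_l = -70, V_reset = -55) {
  gif_params(C = 67, g_l = 1 / 1.16, E_l = E_l,
             eta = filter_coeffs(eta_w),
             gamma = filter_coeffs(gamma_w),
             V_T_star = V_T_star, DeltaV = DeltaV,
             V_reset = V_reset, T_ref = 6.5)
}

quick_agif <- function(g_A = 10, g_K = 1.6, ...) {
  g <- quick_gif(...)
  agif_params(g$C, g$g_l, g$E_l, g$eta, g$gamma, g$V_T_star, g$DeltaV,
              g$V_reset, g$T_ref,
              k_currents = potassium_current_model(g_A, g_K))
}

poisson_trains <- function(rate_hz, duration_ms, n_sweeps) {
  spike_train_set(lapply(seq_len(n_sweeps), function(i) {
    n <- stats::rpois(1, rate_hz * duration_ms / 1000)
    sort(stats::runif(n, 0, duration_ms * (1 - 1e-9)))
  }), duration_ms)
}
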