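test_that("equilibrium gate evaluates the scaled Boltzmann", {
  m <- serotonin_gates()$m
  # half-activation symmetry point
  expect_equal(equilibrium_gate(m$V_star, m), m$A / 2)
  expect_equal(equilibrium_gate(-23.7, m), 1.61 / 2)
  # direct evaluation with the measured 5-HT activation gate
  expect_equal(equilibrium_gate(-20, m), 0.950, tolerance = 1e-3)
  # limits
  expect_equal(equilibrium_gate(-1e6, m), 0)
  expect_equal(equilibrium_gate(1e6, m), m$A)
})

test_that("gates are strictly monotone with the sign of k", {
  gates <- serotonin_gates()
  V <- seq(-120, 20, by = 0.5)
  for (g in gates) {
    d <- diff(equilibrium_gate(V, g))
    if (g$k > 0) expect_true(all(d > 0)) else expect_true(all(d < 0))
  }
})

test_that("potassium currents follow the two-conductance model", {
  km <- potassium_current_model(g_A_bar = 1, g_K_bar = 0)
  # zero driving force and closed inactivation gate
  expect_equal(unlist(potassium_currents(km$E_K, 0.5, km)),
               c(I_A = 0, I_K = 0))
  expect_equal(potassium_currents(-30, 0, km)$I_A, 0)
  # 1 nS, fully de-inactivated, -20 mV vs E_K = -101 mV
  expect_equal(potassium_currents(-20, 1, km)$I_A, 0.950 * 81,
               tolerance = 1e-3)
  # outward (non-negative) above E_K, continuous in V
  V <- seq(km$E_K, 0, by = 0.25)
  ia <- potassium_currents(V, 0.8, km)$I_A
  expect_true(all(ia >= 0))
  expect_true(max(abs(diff(ia))) < 1)
})

test_that("h-gate update is an exponential integrator", {
  km <- potassium_current_model(tau_h = 42.9)
  # fixed point
  hinf <- equilibrium_gate(-60, km$h_gate)
  expect_equal(update_h(hinf, -60, 5, km), hinf)
  # unit decay over one time constant toward h_inf = 0-ish at +40 mV
  km2 <- potassium_current_model(tau_h = 10)
  hinf2 <- equilibrium_gate(200, km2$h_gate) # effectively 0
  expect_equal(update_h(1, 200, 10, km2), hinf2 + (1 - hinf2) * exp(-1),
               tolerance = 1e-6)
  # long-time limit
  expect_equal(update_h(0.2, -60, 1e6, km), hinf)
})

test_that("Boltzmann fits recover generating parameters from noiseless curves", {
  V <- seq(-90, -20, by = 1)
  for (g in serotonin_gates()) {
    fit <- fit_gating_params(V, equilibrium_gate(V, g))
    expect_true(fit$converged)
    expect_equal(fit$params$A, g$A, tolerance = 1e-3)
    expect_equal(fit$params$k, g$k, tolerance = 1e-3)
    expect_equal(fit$params$V_star, g$V_star, tolerance = 1e-3)
  }
  # negative-slope (inactivation) gate recovers k < 0
  h <- serotonin_gates()$h
  fit_h <- fit_gating_params(V, equilibrium_gate(V, h))
  expect_lt(fit_h$params$k, 0)
  expect_equal(fit_h$params$k, -0.165, tolerance = 1e-3)
})

test_that("degenerate gating input yields a flagged non-convergence", {
  V <- seq(-90, -20, by = 5)
  fit <- fit_gating_params(V, rep(0.7, length(V)))
  expect_false(fit$converged)
  expect_null(fit$params)
  expect_match(fit$diagnostics, "transition")
  expect_true(all(is.na(tidy(fit)$estimate)))
})

test_that("transient-current summaries recover generating kinetics", {
  t <- seq(0, 299.9, by = 0.1)
  # decay built from the measured 5-HT peak/steady amplitudes and tau_h
  tr <- (928 - 142) * exp(-t / 42.9) + 142
  s <- characterize_transient_current(tr, step_onset = 0, dt = 0.1)
  expect_equal(s$tau_inact, 42.9, tolerance = 0.01)
  expect_equal(s$peak_amplitude, 928)
  expect_gte(s$peak_amplitude, s$steady_state_amplitude)
  # pure monoexponential, no offset
  t2 <- seq(0, 149.9, by = 0.1)
  s2 <- characterize_transient_current(50 * exp(-t2 / 10), 0, dt = 0.1)
  expect_equal(s2$tau_inact, 10, tolerance = 1e-4)
  # flat zero trace: no decay to fit
  s3 <- characterize_transient_current(rep(0, 3000), 0, dt = 0.1)
  expect_equal(s3$peak_amplitude, 0)
  expect_equal(s3$steady_state_amplitude, 0)
  expect_true(is.na(s3$tau_inact))
})
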