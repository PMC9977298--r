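test_that("spike-triggered filters evaluate as sums of exponentials", {
  f <- filter_coeffs(c(5, 3), c(10, 100))
  expect_equal(eval_filter(f, 0), 8)
  expect_equal(eval_filter(filter_coeffs(2, 50), 50), 2 * exp(-1))
  expect_equal(eval_filter(filter_coeffs(c(0, 0), c(10, 100)), c(0, 5, 500)),
               c(0, 0, 0))
  expect_error(eval_filter(f, -1), "non-negative")
  expect_error(filter_coeffs(c(1, 2), c(100, 10)))
  expect_equal(filter_integral(f), 5 * 10 + 3 * 100)
})

test_that("escape rate and per-bin spike probability match the Poisson rule", {
  expect_equal(spike_probability(0, 0.1), 0)
  # lambda * dt = ln 2 -> p = 0.5 (dt in ms, lambda in Hz)
  expect_equal(spike_probability(1000 * log(2) / 0.1, 0.1), 0.5)
  # at V = V_T* with no spike history the intensity is lambda_0 = 1 Hz
  g <- quick_gif()
  expect_equal(escape_rate(g$V_T_star, g), 1)
  # monotone in V
  V <- seq(-80, -30, by = 1)
  expect_true(all(diff(escape_rate(V, g)) > 0))
})

test_that("resting model stays at the leak reversal and never spikes", {
  g <- quick_gif(DeltaV = 0.5)
  sim <- simulate_neuron(g, rep(0, 20000), dt = 0.1, seed = 1)
  expect_equal(sim$trace$V, rep(g$E_l, 20000))
  expect_length(sim$spikes, 0)
})

test_that("simulation is deterministic given (model, input, seed)", {
  g <- quick_gif(eta_w = c(20, 10, 5, 2, 1, 0), gamma_w = c(4, 2, 1, 0, 0, 0))
  stim <- ou_noise(60, 60, 3, 5000, seed = 3)
  s1 <- simulate_neuron(g, stim, seed = 9)
  s2 <- simulate_neuron(g, stim, seed = 9)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trace, s2$trace)
})

test_that("aGIF with zero potassium conductances reproduces the GIF bitwise", {
  g <- quick_gif(eta_w = c(20, 10, 5, 2, 1, 0), gamma_w = c(4, 2, 1, 0, 0, 0))
  a <- agif_params(g$C, g$g_l, g$E_l, g$eta, g$gamma, g$V_T_star, g$DeltaV,
                   g$V_reset, g$T_ref,
                   k_currents = potassium_current_model(0, 0))
  stim <- ou_noise(60, 60, 3, 5000, seed = 4)
  s1 <- simulate_neuron(g, stim, seed = 11)
  s2 <- simulate_neuron(a, stim, seed = 11)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trace$V, s2$trace$V)
})

test_that("inter-spike intervals respect the absolute refractory period", {
  g <- quick_gif(DeltaV = 4, V_T_star = -55)
  sim <- simulate_neuron(g, rep(100, 50000), dt = 0.1, seed = 2)
  expect_gt(length(sim$spikes), 20)
  expect_true(all(diff(sim$spikes) >= g$T_ref))
})

test_that("clamped mode imposes the given spike times and integrates voltage", {
  g <- quick_gif(eta_w = c(20, 10, 5, 2, 1, 0))
  forced <- c(100, 250, 400)
  sim <- simulate_neuron(g, rep(30, 6000), dt = 0.1, mode = "clamped",
                         spike_times = forced)
  expect_equal(sim$spikes, forced)
  # voltage is reset and held after each forced spike
  expect_equal(sim$trace$V[sim$trace$t > 100 & sim$trace$t <= 106.5],
               rep(g$V_reset, 65))
})

test_that("iGIF theta dynamics reduce to the GIF when all steps are zero", {
  g <- quick_gif(eta_w = c(10, 5, 2, 1, 0, 0))
  ig <- igif_params(g$C, g$g_l, g$E_l, g$eta, g$gamma, g$V_T_star, g$DeltaV,
                    g$V_reset, g$T_ref, theta_steps = rep(0, 5),
                    bin_edges = c(-80, -70, -60, -55, -50, -40),
                    tau_theta = 5)
  stim <- ou_noise(60, 60, 3, 5000, seed = 6)
  s1 <- simulate_neuron(g, stim, seed = 13)
  s2 <- simulate_neuron(ig, stim, seed = 13)
  expect_equal(s1$spikes, s2$spikes)
  expect_equal(s1$trace$V, s2$trace$V)
})

test_that("theta_infinity returns the step value of the containing bin", {
  ig <- igif_params(67, 1, -70, filter_coeffs(rep(0, 6)),
                    filter_coeffs(rep(0, 6)), -45, 2, -55, 6.5,
                    theta_steps = c(1, 2, 3, 4, 5),
                    bin_edges = c(-80, -70, -60, -55, -50, -40))
  expect_equal(theta_infinity(-75, ig), 1)
  expect_equal(theta_infinity(-58, ig), 3)
  # clamped outside the covered range
  expect_equal(theta_infinity(-120, ig), 1)
  expect_equal(theta_infinity(0, ig), 5)
  # constant-V equilibrium: theta initialized at theta_inf stays there
  sim <- simulate_neuron(ig, rep(0, 1000), dt = 0.1)
  expect_equal(sim$trace$theta, rep(theta_infinity(-70, ig), 1000))
})
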