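test_that("spike detection finds upward crossings with a minimum separation", {
  dt <- 0.1
  V <- rep(-60, 5000)
  expect_length(detect_spikes(V, dt), 0)
  V[c(1001, 2501, 4001)] <- 30
  expect_equal(detect_spikes(V, dt), c(100, 250, 400))
  # two crossings 1 ms apart with a 2 ms minimum interval merge into one
  V2 <- rep(-60, 1000); V2[c(101, 111)] <- 30
  expect_equal(detect_spikes(V2, dt, min_interval = 2), 10)
})

test_that("subthreshold regression recovers a known GIF to within 1%", {
  truth <- quick_gif(eta_w = c(25, 15, 8, 4, 2, 1), DeltaV = 2,
                     V_T_star = -48)
  stim <- ou_noise(90, 70, 3, 30000, seed = 21)
  rec <- generate_surrogate_recording(truth, stim, n_sweeps = 2, seed = 22)
  expect_gt(length(unlist(recording_spikes(rec)$trains)), 100)
  sub <- fit_subthreshold(rec, "gif")
  e <- sub$estimates
  expect_equal(e$C, truth$C, tolerance = 0.01)
  expect_equal(e$g_l, truth$g_l, tolerance = 0.01)
  expect_equal(e$E_l, truth$E_l, tolerance = 0.01)
  expect_equal(e$eta$weights, truth$eta$weights, tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(sub$V_reset, truth$V_reset, tolerance = 1e-6)
  expect_gt(sub$r_squared, 0.99)
  # residuals mean-zero outside the exclusion windows
  expect_lt(abs(sub$residual_mean), 1e-6)
})

test_that("aGIF regression recovers conductances; GIF mis-specification loses fit", {
  truth <- quick_agif(g_A = 10, g_K = 1.6, eta_w = c(25, 15, 8, 4, 2, 1),
                      DeltaV = 2)
  stim <- ou_noise(100, 80, 3, 30000, seed = 31)
  rec <- generate_surrogate_recording(truth, stim, n_sweeps = 2, seed = 32)
  sub_a <- fit_subthreshold(rec, "agif")
  expect_equal(sub_a$estimates$g_A, 10, tolerance = 0.05)
  expect_equal(sub_a$estimates$g_K, 1.6, tolerance = 0.10)
  sub_g <- fit_subthreshold(rec, "gif")
  expect_lt(sub_g$r_squared, sub_a$r_squared)
})

test_that("zero-variance input triggers a rank-deficiency error", {
  g <- quick_gif(DeltaV = 4, V_T_star = -58, E_l = -60)
  rec <- generate_surrogate_recording(g, make_step(0, 0, 1, 2, 2000),
                                      n_sweeps = 1, seed = 2)
  rec$I <- 0
  attr(rec, "dt") <- 0.1
  expect_error(fit_subthreshold(rec, "gif"), "collinear")
})

test_that("threshold likelihood fit recovers V_T* and DeltaV", {
  truth <- quick_gif(eta_w = c(25, 15, 8, 4, 2, 1),
                     gamma_w = c(0, 0, 0, 0, 0, 0), DeltaV = 2,
                     V_T_star = -48)
  stim <- ou_noise(90, 70, 3, 60000, seed = 41)
  rec <- generate_surrogate_recording(truth, stim, n_sweeps = 2, seed = 42)
  sub <- fit_subthreshold(rec, "gif")
  thr <- fit_threshold(sub, rec, "gif")
  expect_true(thr$converged)
  expect_equal(thr$V_T_star, truth$V_T_star, tolerance = 1 / 48)  # 1 mV
  expect_equal(thr$DeltaV, truth$DeltaV, tolerance = 0.2)
  # generator had gamma = 0: fitted gamma integral is below the noise floor
  expect_lt(abs(filter_integral(thr$gamma)),
            0.05 * filter_integral(filter_coeffs(c(6, 4, 2.5, 1.5, 1, 0.5))))
  # accepted ascent iterations never decrease the log-likelihood
  expect_true(all(diff(thr$loglik_trace) >= -1e-8))
})

test_that("estimates are invariant to a constant time-stamp offset", {
  truth <- quick_gif(eta_w = c(25, 15, 8, 4, 2, 1), DeltaV = 2)
  stim <- ou_noise(90, 70, 3, 10000, seed = 51)
  rec <- generate_surrogate_recording(truth, stim, n_sweeps = 1, seed = 52)
  rec_shift <- rec
  rec_shift$t <- rec_shift$t + 5000
  s1 <- fit_subthreshold(rec, "gif")
  s2 <- fit_subthreshold(rec_shift, "gif")
  expect_identical(s1$estimates, s2$estimates)
})

test_that("iGIF threshold fit selects bins from data and reduces sensibly", {
  truth <- quick_gif(eta_w = c(25, 15, 8, 4, 2, 1), DeltaV = 2,
                     V_T_star = -48)
  stim <- ou_noise(90, 70, 3, 20000, seed = 61)
  rec <- generate_surrogate_recording(truth, stim, n_sweeps = 1, seed = 62)
  sub <- fit_subthreshold(rec, "gif")
  thr <- fit_threshold(sub, rec, "igif", tau_theta_grid = c(3, 30))
  expect_s3_class(thr$params, "igif_params")
  expect_length(thr$theta$steps, 5)
  expect_true(thr$theta$tau_theta %in% c(3, 30))
  # a GIF generator needs little voltage-coupled threshold movement
  expect_lt(max(abs(thr$theta$steps)) , 5)
})
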