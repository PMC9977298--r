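test_that("frozen OU noise has the requested stationary statistics", {
  stim <- ou_noise(20, 15, 3, 60000, dt = 0.1, seed = 42)
  n <- nrow(stim)
  se_mean <- 15 * sqrt(2 * 3 / 0.1) / sqrt(n) # effective sample correction
  expect_lt(abs(mean(stim$I) - 20), 3 * se_mean)
  expect_lt(abs(sd(stim$I) / 15 - 1), 0.05)
  # autocorrelation at one correlation time close to exp(-1)
  lag <- round(3 / 0.1)
  r <- cor(stim$I[-(1:lag)], stim$I[1:(n - lag)])
  expect_lt(abs(r / exp(-1) - 1), 0.05)
})

test_that("OU noise is reproducible from its seed and leaves the RNG alone", {
  a <- ou_noise(0, 10, 3, 1000, seed = 7)
  b <- ou_noise(0, 10, 3, 1000, seed = 7)
  expect_identical(a, b)
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(ou_noise(0, 10, 3, 100, seed = 7)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("ramps and steps produce the stated currents", {
  r <- make_ramp(40, 100, 1000, dt = 0.1)
  expect_equal(r$I[r$t == 500], 90) # 40 pA + 100 pA/s * 0.5 s
  expect_equal(make_ramp(5, 0, 100)$I, rep(5, 1000))
  expect_true(all(diff(make_ramp(0, -50, 500)$I) < 0))
  s <- make_step(10, 50, 100, 300, 500, dt = 0.1)
  expect_equal(unique(s$I[s$t < 100]), 10)
  expect_equal(unique(s$I[s$t >= 100 & s$t < 300]), 60)
})

test_that("training/validation protocol uses distinct frozen stimuli", {
  p <- training_validation_protocol("5-HT", seed = 3)
  expect_equal(nrow(p$train) * 0.1, 60000)
  expect_equal(nrow(p$validation) * 0.1, 10000)
  expect_gte(p$R_val, 9)
  expect_false(isTRUE(all.equal(p$train$I[1:1000], p$validation$I[1:1000])))
})

test_that("surrogate recordings are seed-reproducible with frozen stimuli", {
  g <- quick_gif(DeltaV = 4, V_T_star = -55)
  stim <- ou_noise(40, 40, 3, 2000, seed = 5)
  r1 <- generate_surrogate_recording(g, stim, n_sweeps = 3, seed = 8)
  r2 <- generate_surrogate_recording(g, stim, n_sweeps = 3, seed = 8)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # sweeps share the stimulus and differ only via spiking stochasticity
  sw <- split(r1$I, r1$sweep)
  expect_identical(sw[[1]], sw[[2]])
  trains <- recording_spikes(r1)$trains
  expect_false(identical(trains[[1]], trains[[2]]))
})
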