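test_that("rectified-linear IO fits recover exact synthetic curves", {
  amps <- seq(0, 120, length.out = 8)
  rates <- 0.05 * pmax(0, amps - 35) # gain 50 Hz/nA, threshold 35 pA
  io <- io_function(amps, rates)
  expect_equal(io$gain, 50, tolerance = 1e-4)
  expect_equal(io$threshold, 35, tolerance = 1e-3)
  # purely linear data: threshold at/below the smallest amplitude
  io_lin <- io_function(amps, 0.02 * amps + 1)
  expect_lte(io_lin$threshold, min(amps) + 1e-6)
  # constant rates
  io_const <- io_function(amps, rep(0, 8))
  expect_equal(io_const$gain, 0)
  expect_true(is.na(io_const$threshold))
  expect_error(io_function(1:3, 1:3), "4")
})

test_that("divisive and subtractive components are decomposed correctly", {
  amps <- seq(0, 120, length.out = 8)
  io0 <- io_function(amps, 0.05 * pmax(0, amps - 30))
  expect_equal(unlist(divisive_subtractive(io0, io0)),
               c(slope_ratio = 1, threshold_shift = 0))
  io_half <- io_function(amps, 0.025 * pmax(0, amps - 30))
  ds <- divisive_subtractive(io_half, io0)
  expect_equal(ds$slope_ratio, 0.5, tolerance = 1e-4)
  expect_equal(ds$threshold_shift, 0, tolerance = 0.1)
  io_shift <- io_function(amps, 0.05 * pmax(0, amps - 50))
  ds2 <- divisive_subtractive(io_shift, io0)
  expect_equal(ds2$slope_ratio, 1, tolerance = 1e-3)
  expect_equal(ds2$threshold_shift, 20, tolerance = 0.05)
  expect_error(divisive_subtractive(io0, tibble::tibble(gain = NA_real_,
                                                        threshold = 1)))
})

test_that("time-resolved gain summarizes synthetic responses consistently", {
  # synthetic adapting population: rate = a(t) * max(0, I - 20) with a(t)
  # decaying from 0.1 to 0.025 after onset
  amps <- seq(0, 120, length.out = 6)
  tgrid <- seq(0, 999, by = 1)
  onset <- 200
  a_t <- ifelse(tgrid < onset, 0,
                0.025 + 0.075 * exp(-(tgrid - onset) / 80))
  resp <- purrr::map_dfr(amps, function(A)
    tibble::tibble(amplitude = A, t = tgrid,
                   rate = a_t * pmax(0, A - 20)))
  g <- time_resolved_gain(resp, onset = onset, gain_bin = 10)
  expect_equal(g$transient, 100, tolerance = 0.05)   # 0.1 Hz/pA = 100 Hz/nA
  expect_equal(g$stationary, 25, tolerance = 0.05)
  expect_equal(g$gain_ratio, 4, tolerance = 0.1)
  # gain threshold recovered per bin
  expect_equal(median(g$gain_t$threshold), 20, tolerance = 0.05)
  # consistent rescaling of rates leaves the ratio unchanged
  resp2 <- dplyr::mutate(resp, rate = rate * 3.7)
  g2 <- time_resolved_gain(resp2, onset = onset, gain_bin = 10)
  expect_equal(g2$gain_ratio, g$gain_ratio, tolerance = 1e-6)
  expect_equal(g2$transient, 3.7 * g$transient, tolerance = 1e-6)
  # a memoryless population has ratio 1
  resp3 <- purrr::map_dfr(amps, function(A)
    tibble::tibble(amplitude = A, t = tgrid,
                   rate = ifelse(tgrid < onset, 0, 0.04) * pmax(0, A - 20)))
  g3 <- time_resolved_gain(resp3, onset = onset, gain_bin = 10)
  expect_equal(g3$gain_ratio, 1, tolerance = 1e-6)
})

test_that("model JSON round-trips byte-identically", {
  m <- quick_agif(g_A = 9.3, eta_w = c(25.5, 15, 8, 4, 2, 1))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f1)
  m2 <- read_model_json(f1)
  expect_equal(m2, m, ignore_attr = FALSE)
  write_model_json(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # recording CSV round trip
  g <- quick_gif(DeltaV = 4, V_T_star = -55)
  rec <- generate_surrogate_recording(g, ou_noise(40, 40, 3, 500, seed = 1),
                                      n_sweeps = 2, seed = 2)
  fr <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, fr)
  rec2 <- read_recording_csv(fr)
  expect_equal(attr(rec2, "dt"), attr(rec, "dt"))
  expect_equal(as.data.frame(rec2), as.data.frame(rec), tolerance = 1e-12)
})

test_that("run manifests capture configuration and seeds", {
  f <- withr::local_tempfile(fileext = ".json")
  run_manifest(config = list(stage = "synth", duration = 100),
               seeds = list(master = 42), path = f)
  m <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(m$package, "raphenet")
  expect_equal(m$seeds$master, 42)
  expect_equal(m$config$stage, "synth")
})
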