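test_that("Md* endpoints: identity is exactly 1, empty predictions score 0", {
  set.seed(101)
  A <- poisson_trains(5, 10000, 9)
  expect_identical(md_star(A, A), 1)
  # any nonempty set with >= 2 sweeps scores 1 against itself
  B <- poisson_trains(2, 3000, 3)
  expect_identical(md_star(B, B), 1)
  empty <- spike_train_set(rep(list(numeric(0)), 9), 10000)
  expect_equal(md_star(A, empty), 0)
})

test_that("Md* requires comparable sets", {
  set.seed(102)
  A <- poisson_trains(5, 10000, 9)
  expect_error(md_star(A, poisson_trains(5, 5000, 9)), "duration")
  expect_error(md_star(A, poisson_trains(5, 10000, 1)), "2 sweeps")
  expect_error(spike_train_set(list(c(-1, 5)), 10), "\\[0, duration\\)")
})

test_that("independent Poisson predictions score near chance (0)", {
  set.seed(103)
  v <- replicate(40, {
    md_star(poisson_trains(5, 10000, 9), poisson_trains(5, 10000, 9))
  })
  expect_lt(abs(mean(v)), 0.05)
})

test_that("Md* is non-decreasing in the coincidence window for jittered data", {
  set.seed(104)
  base <- sort(runif(60, 0, 9999))
  jit <- function(sd) spike_train_set(lapply(1:9, function(i)
    sort(pmin(pmax(base + rnorm(60, 0, sd), 0), 9999.9))), 10000)
  d <- jit(3); m <- jit(3)
  md <- vapply(c(2, 4, 8, 16), function(p) md_star(d, m, precision = p), 0)
  expect_true(all(diff(md) >= 0))
})

test_that("intrinsic reliability separates reliable from random sweeps", {
  set.seed(105)
  ident <- spike_train_set(rep(list(c(100, 450, 720)), 5), 1000)
  expect_equal(intrinsic_reliability(ident), 1)
  pois <- replicate(40, intrinsic_reliability(poisson_trains(5, 10000, 6)))
  expect_lt(abs(mean(pois)), 0.05)
  expect_error(intrinsic_reliability(poisson_trains(5, 1000, 1)), "2 sweeps")
  # reliability degrades monotonically with added jitter
  base <- sort(runif(60, 0, 9999))
  rel <- vapply(c(0.5, 2, 6, 15), function(sd) {
    intrinsic_reliability(spike_train_set(lapply(1:8, function(i)
      sort(pmin(pmax(base + rnorm(60, 0, sd), 0), 9999.9))), 10000))
  }, 0)
  expect_true(all(diff(rel) < 0))
})

test_that("spike-window-excluded R squared behaves at its endpoints", {
  set.seed(106)
  obs <- rnorm(5000)
  expect_equal(r_squared_subthreshold(obs, obs, c(100, 300), dt = 0.1), 1)
  pred0 <- rep(mean(obs), 5000)
  expect_equal(r_squared_subthreshold(pred0, obs, numeric(0), dt = 0.1), 0)
  # no spikes: identical to the plain R squared
  pred <- obs + rnorm(5000, 0, 0.5)
  plain <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  expect_equal(r_squared_subthreshold(pred, obs, numeric(0), dt = 0.1), plain)
  # zero-variance observations are reported as absent
  expect_true(is.na(r_squared_subthreshold(rep(1, 100), rep(2, 100),
                                           numeric(0), dt = 0.1)))
  # excluded windows actually remove samples around spikes
  obs2 <- obs; obs2[1001:1066] <- 100 # artifact at 100-106.5 ms
  r_with <- r_squared_subthreshold(pred, obs2, 100, window = c(1.5, 6.5),
                                   dt = 0.1)
  r_wo <- r_squared_subthreshold(pred, obs2, numeric(0), dt = 0.1)
  expect_gt(r_with, r_wo)
})

test_that("recording QC applies the drift and reliability criteria", {
  set.seed(107)
  # stable counts, reliable timing -> include
  base <- sort(runif(40, 0, 9990))
  good <- spike_train_set(lapply(1:4, function(i)
    sort(pmin(pmax(base + rnorm(40, 0, 1), 0), 9999.9))), 10000)
  q <- qc_recording(good)
  expect_true(q$include)
  expect_identical(q$reasons, "")
  # monotone count drift -> exclude
  drifting <- spike_train_set(lapply(c(20, 40, 60, 80), function(n)
    sort(runif(n, 0, 9999))), 10000)
  qd <- qc_recording(drifting)
  expect_false(qd$include)
  expect_match(qd$reasons, "drift")
  expect_gt(qd$drift_r, 0.9)
  # independent Poisson sweeps -> unreliable
  qp <- qc_recording(poisson_trains(5, 10000, 6))
  expect_false(qp$include)
  expect_match(qp$reasons, "unreliable")
  expect_error(qc_recording(poisson_trains(5, 1000, 2)), "3 validation")
})
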