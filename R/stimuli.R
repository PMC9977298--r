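#' Frozen Ornstein-Uhlenbeck noise current
#'
#' Exact-discretization OU process
#' \eqn{dI = -(I - \mu)/\tau\,dt + \sigma \sqrt{2/\tau}\,dW}, sampled at
#' `dt` and started from its stationary distribution.  With a fixed
#' `seed` the trace is "frozen": every call reproduces it bitwise, so
#' repeated sweeps share the stimulus and trial-to-trial variability
#' reflects intrinsic stochasticity only.
#'
#' @param mu Mean, pA.
#' @param sigma Stationary standard deviation, pA.
#' @param tau Correlation time constant, ms (> 0).
#' @param duration Trace length, ms.
#' @param dt Sample interval, ms.
#' @param seed Integer seed; `NULL` uses (and advances) the session RNG.
#' @return A tibble with columns `t` (ms) and `I` (pA); attribute `dt`.
#' @export
ou_noise <- function(mu, sigma, tau, duration, dt = 0.1, seed = NULL) {
  stopifnot(tau > 0, duration > 0, dt > 0)
  n <- floor(duration / dt)
  z <- with_seed(seed, rnorm(n))
  a <- exp(-dt / tau)
  innov <- sigma * sqrt(1 - a^2) * z
  innov[1] <- sigma * z[1] # stationary start
  x <- mu + as.numeric(stats::filter(innov, a, method = "recursive"))
  out <- tibble(t = (seq_len(n) - 1) * dt, I = x)
  attr(out, "dt") <- dt
  out
}

#' Step current
#'
#' @param baseline Pre/post-step current, pA.
#' @param amplitude Step increment above baseline, pA.
#' @param onset,offset Step onset/offset, ms.
#' @param duration Total trace length, ms.
#' @param dt Sample interval, ms.
#' @return A tibble with columns `t` and `I`; attribute `dt`.
#' @export
make_step <- function(baseline, amplitude, onset, offset, duration, dt = 0.1) {
  stopifnot(duration > 0, onset < offset)
  t <- seq(0, duration - dt, by = dt)
  out <- tibble(t = t, I = baseline + amplitude * (t >= onset & t < offset))
  attr(out, "dt") <- dt
  out
}

#' Ramp current
#'
#' `I(t) = baseline + slope * t`, with `slope` in pA/s.
#'
#' @param baseline Starting current, pA.
#' @param slope Rate of change, pA/s.
#' @param duration Trace length, ms.
#' @param dt Sample interval, ms.
#' @return A tibble with columns `t` and `I`; attribute `dt`.
#' @export
make_ramp <- function(baseline, slope, duration, dt = 0.1) {
  stopifnot(duration > 0, dt > 0)
  t <- seq(0, duration - dt, by = dt)
  out <- tibble(t = t, I = baseline + slope * t / 1000)
  attr(out, "dt") <- dt
  out
}

#' Cell-type stimulus parameters for model training
#'
#' Per-cell-type OU noise parameters used for the frozen-noise training
#' and validation protocols.  The means follow the cell types' relative
#' excitability; the standard deviations are set so that model neurons
#' fire in the 2-10 Hz range; the correlation time is 3 ms.
#'
#' @param cell_type One of `"5-HT"`, `"SOM"`, `"mPFC"`.
#' @return A list with `mu`, `sigma`, `tau` (pA, pA, ms).
#' @export
stimulus_defaults <- function(cell_type = c("5-HT", "SOM", "mPFC")) {
  cell_type <- match.arg(cell_type)
  switch(cell_type,
         "5-HT" = list(mu = 60, sigma = 60, tau = 3),
         "SOM"  = list(mu = 10, sigma = 60, tau = 3),
         "mPFC" = list(mu = 60, sigma = 250, tau = 3))
}

#' Training / validation frozen-noise protocol
#'
#' Builds the two frozen OU stimuli used to fit and evaluate single-neuron
#' models: a 60 s training trace and a distinct 10 s validation trace
#' (different frozen seeds), with per-cell-type OU parameters from
#' [stimulus_defaults()].  The validation stimulus is intended to be
#' repeated (`R_val` sweeps >= 9 by default) so that the pairwise terms
#' of Md* and intrinsic reliability are defined.
#'
#' @param cell_type One of `"5-HT"`, `"SOM"`, `"mPFC"`.
#' @param seed Integer master seed for the two frozen traces.
#' @param dt Sample interval, ms.
#' @param R_val Number of validation repetitions (metadata only).
#' @param train_duration,validation_duration Durations, ms.
#' @return A list with elements `train`, `validation` (stimulus tibbles),
#'   `R_val` and `ou` (the OU parameters used).
#' @export
training_validation_protocol <- function(cell_type = c("5-HT", "SOM", "mPFC"),
                                         seed = 1, dt = 0.1, R_val = 9,
                                         train_duration = 60000,
                                         validation_duration = 10000) {
  cell_type <- match.arg(cell_type)
  ou <- stimulus_defaults(cell_type)
  list(
    train = ou_noise(ou$mu, ou$sigma, ou$tau, train_duration, dt,
                     seed = seed),
    validation = ou_noise(ou$mu, ou$sigma, ou$tau, validation_duration, dt,
                          seed = seed + 104729L),
    R_val = R_val, ou = ou)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Accept either a stimulus tibble (t, I) or a bare numeric vector.
stimulus_current <- function(stim) {
  if (is.data.frame(stim)) {
    stopifnot("I" %in% names(stim))
    stim$I
  } else {
    as.numeric(stim)
  }
}

stimulus_dt <- function(stim, dt = NULL) {
  if (!is.null(dt)) return(dt)
  d <- attr(stim, "dt")
  if (is.null(d) && is.data.frame(stim) && nrow(stim) > 1)
    d <- stim$t[2] - stim$t[1]
  if (is.null(d)) abort("supply `dt` or a stimulus with a `dt` attribute")
  d
}
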