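#' Rectified-linear input-output function
#'
#' Least-squares fit of `rate = gain * max(0, I - threshold)` to
#' population rates observed at a set of input amplitudes (the
#' population input-output functions are approximately rectified
#' linear).  The threshold is found by one-dimensional search; for a
#' given threshold the gain has a closed form.
#'
#' @param input_amplitudes Input amplitudes, pA (>= 4 values).
#' @param rates Population rates at those amplitudes, Hz/neuron.
#' @return A one-row tibble: `gain` (Hz/nA), `threshold` (pA; `NA` when
#'   the rates are all zero), `sse`.
#' @export
io_function <- function(input_amplitudes, rates) {
  stopifnot(length(input_amplitudes) == length(rates),
            length(input_amplitudes) >= 4)
  x <- as.numeric(input_amplitudes); y <- as.numeric(rates)
  if (all(abs(y) < .Machine$double.eps)) {
    return(tibble(gain = 0, threshold = NA_real_, sse = 0))
  }
  sse_at <- function(i0) {
    z <- pmax(0, x - i0)
    if (sum(z^2) == 0) return(sum(y^2))
    a <- sum(z * y) / sum(z^2)
    sum((y - a * z)^2)
  }
  opt <- optimize(sse_at, range(x))
  # the optimum can sit at the boundary when there is no rectification
  cands <- c(opt$minimum, min(x))
  i0 <- cands[which.min(vapply(cands, sse_at, 0))]
  z <- pmax(0, x - i0)
  a <- if (sum(z^2) == 0) 0 else sum(z * y) / sum(z^2)
  # gain reported in Hz/nA (amplitudes in pA)
  tibble(gain = a * 1000, threshold = i0, sse = sse_at(i0))
}

#' Step-response experiment over input amplitudes
#'
#' Simulates the network for a family of step inputs (the same step
#' applied to both populations) and returns the tidy 5-HT population
#' rates, ready for [time_resolved_gain()].
#'
#' @param net A [drn_network()].
#' @param amplitudes Step amplitudes, pA (default 8 steps spanning
#'   0-120 pA).
#' @param baseline Pre-step current, pA.
#' @param onset Step onset, ms.
#' @param duration Total trace duration, ms.
#' @param population Which population's rate to collect.
#' @param ... Passed to [simulate_network()] (`n_trials`, `noise_sd`,
#'   `seed`, ...).
#' @return A tibble with columns `amplitude`, `t`, `rate`; attribute
#'   `onset`.
#' @export
step_response_experiment <- function(net, amplitudes = seq(0, 120, length.out = 8),
                                     baseline = 0, onset = 250,
                                     duration = 1500,
                                     population = "5-HT", ...) {
  out <- purrr::map_dfr(amplitudes, function(a) {
    stim <- make_step(baseline, a, onset, duration, duration)
    sim <- simulate_network(net, stim, stim, ...)
    sim$rates |>
      dplyr::filter(.data$population == !!population) |>
      dplyr::transmute(amplitude = a, t = .data$t, rate = .data$rate)
  })
  attr(out, "onset") <- onset
  out
}

#' Time-resolved gain of the population response
#'
#' Fits a rectified-linear input-output function to the population rate
#' at each time bin after step onset and summarizes the result as
#' gain-versus-time, the transient gain (maximum within the first
#' 100 ms after onset), the stationary gain (mean over the final 25% of
#' the response) and the adaptation ratio `gain_ratio` of the peak gain
#' to the steady-state gain — a measure of how strongly the population
#' emphasizes the onset of a sustained input.
#'
#' @param responses A tibble with columns `amplitude`, `t`, `rate`
#'   (e.g. from [step_response_experiment()]).
#' @param onset Step onset, ms (taken from the attribute if present).
#' @param gain_bin Width of the time bins for the IO fits, ms.
#' @param transient_window Length of the post-onset window searched for
#'   the transient peak, ms.
#' @param stationary_frac Final fraction of the response treated as
#'   stationary.
#' @return An object of class `gain_analysis`: list with `gain_t`
#'   (tibble `t`, `gain`, `threshold`), `transient`, `stationary`,
#'   `gain_ratio` (`NA` when the minimum gain is not positive), and the
#'   windows used.
#' @export
time_resolved_gain <- function(responses, onset = attr(responses, "onset"),
                               gain_bin = 10, transient_window = 100,
                               stationary_frac = 0.25) {
  stopifnot(all(c("amplitude", "t", "rate") %in% names(responses)),
            !is.null(onset))
  tmax <- max(responses$t)
  gain_t <- responses |>
    dplyr::filter(.data$t >= onset) |>
    dplyr::mutate(bin = floor((.data$t - onset) / gain_bin) * gain_bin + onset) |>
    dplyr::group_by(.data$bin, .data$amplitude) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop") |>
    dplyr::group_by(.data$bin) |>
    dplyr::group_modify(~ io_function(.x$amplitude, .x$rate)) |>
    dplyr::ungroup() |>
    dplyr::rename(t = "bin")
  transient <- gain_t |>
    dplyr::filter(.data$t < onset + transient_window) |>
    dplyr::pull(.data$gain) |>
    max()
  stat_start <- tmax - stationary_frac * (tmax - onset)
  stationary <- gain_t |>
    dplyr::filter(.data$t >= stat_start) |>
    dplyr::pull(.data$gain) |>
    mean()
  # adaptation ratio: peak gain over steady-state gain (the stationary
  # mean is a stable estimator of the post-peak minimum, and the
  # build-up of the response does not masquerade as adaptation);
  # 1 for a memoryless population
  gmax <- max(gain_t$gain)
  ratio <- if (stationary > 0) gmax / stationary else NA_real_
  structure(list(gain_t = gain_t, transient = transient,
                 stationary = stationary, gain_ratio = ratio,
                 onset = onset, transient_window = transient_window,
                 stationary_frac = stationary_frac),
            class = "gain_analysis")
}

#' @export
print.gain_analysis <- function(x, ...) {
  cat(sprintf("<gain_analysis> transient %.3g, stationary %.3g Hz/nA; max/min ratio %.3g\n",
              x$transient, x$stationary, x$gain_ratio))
  invisible(x)
}

#' @export
tidy.gain_analysis <- function(x, ...) x$gain_t

#' @export
glance.gain_analysis <- function(x, ...) {
  tibble(transient = x$transient, stationary = x$stationary,
         gain_ratio = x$gain_ratio)
}

#' Input-output fit over a response epoch
#'
#' Averages the population rate over a time window per amplitude and
#' fits the rectified-linear input-output function — used to compare
#' transient or stationary IO curves across conditions.
#'
#' @param responses A tibble with columns `amplitude`, `t`, `rate`.
#' @param window Time window `(from, to)`, ms.
#' @return A one-row tibble as from [io_function()].
#' @export
epoch_io <- function(responses, window) {
  stopifnot(length(window) == 2)
  responses |>
    dplyr::filter(.data$t >= window[1], .data$t < window[2]) |>
    dplyr::group_by(.data$amplitude) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop") |>
    (\(d) io_function(d$amplitude, d$rate))()
}

#' Divisive vs subtractive decomposition of inhibition
#'
#' Compares rectified-linear input-output fits with and without
#' feedforward inhibition: the divisive component is the gain
#' (slope) ratio, the subtractive component is the rightward threshold
#' shift.  Pure gain scaling gives `(ratio, 0)`, a pure rightward shift
#' gives `(1, shift)`.
#'
#' @param io_with,io_without One-row IO fits ([io_function()]) with and
#'   without inhibition.
#' @return A one-row tibble: `slope_ratio`, `threshold_shift` (pA).
#' @export
divisive_subtractive <- function(io_with, io_without) {
  need <- function(io) {
    if (!all(c("gain", "threshold") %in% names(io)) || nrow(io) != 1 ||
        !is.finite(io$gain))
      abort("need valid one-row IO fits with `gain` and `threshold`")
  }
  need(io_with); need(io_without)
  tibble(slope_ratio = io_with$gain / io_without$gain,
         threshold_shift = io_with$threshold - io_without$threshold)
}

#' Ramp derivative-encoding experiment
#'
#' Applies ramp stimuli over a grid of baselines and slopes (the same
#' ramp to both populations), extracts the peak trial-averaged 5-HT
#' population rate from a boxcar-smoothed rate trace, and fits, per
#' baseline, a linear model of peak rate versus ramp slope.  Every ramp
#' rises from the baseline to the same target (`baseline + amplitude`)
#' and then holds, so the final intensity is identical across slopes
#' and only the temporal derivative of the input varies: a high
#' linearity R-squared means the population's peak output reports the
#' derivative of its input rather than its intensity.
#'
#' @param net A [drn_network()].
#' @param baselines Baseline currents, pA.
#' @param slopes Ramp slopes, pA/s (> 0).
#' @param amplitude Ramp height above baseline, pA.
#' @param hold Time the stimulus is held at the target after the ramp,
#'   ms.
#' @param lead Pre-ramp time at baseline, ms.
#' @param smooth Boxcar width for the rate trace, ms.
#' @param ... Passed to [simulate_network()].
#' @return An object of class `derivative_encoding`: list with `peaks`
#'   (tibble `baseline`, `slope`, `peak_rate`) and `linearity` (tibble
#'   `baseline`, `r_squared`, `slope_gain`).
#' @export
derivative_encoding <- function(net, baselines = c(0, 20, 40),
                                slopes = seq(50, 250, length.out = 5),
                                amplitude = 100, hold = 300, lead = 200,
                                smooth = 5, ...) {
  stopifnot(all(slopes > 0))
  grid <- tidyr::expand_grid(baseline = baselines, slope = slopes)
  peaks <- purrr::pmap_dfr(grid, function(baseline, slope) {
    rise <- 1000 * amplitude / slope
    duration <- lead + rise + hold
    stim <- make_ramp(baseline - slope * lead / 1000, slope, duration)
    stim$I <- pmin(pmax(stim$I, baseline), baseline + amplitude)
    sim <- simulate_network(net, stim, stim, ...)
    sm <- population_rate(
      sim$spikes$time[sim$spikes$population == "5-HT"],
      sim$n_ht, sim$n_trials, sim$duration, bin = sim$rate_bin,
      smooth = smooth)
    tibble(baseline = baseline, slope = slope, peak_rate = max(sm$rate))
  })
  linearity <- peaks |>
    dplyr::group_by(.data$baseline) |>
    dplyr::group_modify(~ {
      if (nrow(.x) >= 3 && sd(.x$peak_rate) > 0 && sd(.x$slope) > 0) {
        f <- stats::lm(peak_rate ~ slope, data = .x)
        tibble(r_squared = summary(f)$r.squared,
               slope_gain = stats::coef(f)[["slope"]])
      } else {
        tibble(r_squared = NA_real_, slope_gain = NA_real_)
      }
    }) |>
    dplyr::ungroup()
  structure(list(peaks = peaks, linearity = linearity, smooth = smooth),
            class = "derivative_encoding")
}

#' @export
print.derivative_encoding <- function(x, ...) {
  cat("<derivative_encoding>\n")
  print(x$linearity)
  invisible(x)
}

#' @export
tidy.derivative_encoding <- function(x, ...) x$peaks

#' @export
glance.derivative_encoding <- function(x, ...) x$linearity
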