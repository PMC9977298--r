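#' Spike-train set
#'
#' A set of spike-time vectors from repeated sweeps of the same frozen
#' stimulus, used by the Md* and intrinsic-reliability metrics.
#'
#' @param trains List of numeric spike-time vectors, ms; each sorted and
#'   within `[0, duration)`.
#' @param duration Sweep duration, ms.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, duration) {
  stopifnot(is.list(trains), duration > 0)
  trains <- lapply(trains, function(x) sort(as.numeric(x)))
  ok <- vapply(trains, function(x)
    length(x) == 0 || (min(x) >= 0 && max(x) < duration), TRUE)
  if (!all(ok)) abort("spike times must lie in [0, duration)")
  structure(list(trains = trains, duration = duration,
                 n_sweeps = length(trains)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- vapply(x$trains, length, 0L)
  cat(sprintf("<spike_train_set> %d sweeps of %.4g ms, %.1f spikes/sweep (%.2f Hz)\n",
              x$n_sweeps, x$duration, mean(n), 1000 * mean(n) / x$duration))
  invisible(x)
}

#' @export
as_tibble.spike_train_set <- function(x, ...) {
  tibble(sweep = rep(seq_along(x$trains), lengths(x$trains)),
         time = unlist(x$trains) %||% numeric(0))
}

# Coincidence count between two sorted spike trains as the boxcar-kernel
# inner product: the number of (x_i, y_j) pairs with |x_i - y_j| <=
# precision.  For independent Poisson trains its expectation is exactly
# the analytic chance count 2 nu_x nu_y Delta T, which makes the chance
# correction unbiased.
count_coincidences <- function(x, y, precision) {
  if (length(x) == 0 || length(y) == 0) return(0)
  sum(findInterval(x + precision, y) -
        findInterval(x - precision - 1e-12, y))
}

# Mean coincidence count over ordered sweep pairs of two sets.
# include_self: count pairs (i, i) as well (used for the within-set terms,
# where the self pair contributes the sweep's own spike count).
mean_pair_coincidences <- function(a, b, precision, include_self) {
  ra <- length(a); rb <- length(b)
  tot <- 0; np <- 0L
  for (i in seq_len(ra)) {
    for (j in seq_len(rb)) {
      if (!include_self && identical(a, b) && i == j) next
      tot <- tot + count_coincidences(a[[i]], b[[j]], precision)
      np <- np + 1L
    }
  }
  tot / np
}

# Analytic expected chance coincidences between two independent Poisson
# trains of rates nu_x, nu_y (spikes/ms) over duration T: 2 nu_x nu_y Delta T.
chance_coincidences <- function(nu_x, nu_y, precision, duration) {
  2 * nu_x * nu_y * precision * duration
}

#' Md* spike-train similarity
#'
#' Chance-corrected coincidence similarity between a set of recorded
#' ("data") spike trains and a set of model-predicted spike trains over
#' repeated sweeps of the same frozen stimulus:
#' \deqn{Md^* = \frac{2 (n_{dm} - c_{dm})}{(n_{dd} - c_{dd}) + (n_{mm} - c_{mm})}}
#' where each `n` is the mean boxcar-kernel coincidence count (number of
#' spike pairs within `precision`) over ordered sweep pairs (self-pairs
#' included for the within-set terms) and each `c` is the analytic
#' expected chance count for independent Poisson trains at the sets'
#' mean rates
#' (\eqn{2 \nu_x \nu_y \Delta T}).  A model set identical to the data
#' scores exactly 1; predictions statistically independent of the data
#' score 0 in expectation.
#'
#' @param data,model [spike_train_set()]s of equal duration, each with
#'   at least 2 sweeps.
#' @param precision Coincidence window, ms (spike-timing precision).
#' @return The Md* score (dimensionless; `NA` if the denominator is not
#'   positive, i.e. neither set carries supra-chance structure).
#' @export
md_star <- function(data, model, precision = 8) {
  stopifnot(inherits(data, "spike_train_set"),
            inherits(model, "spike_train_set"))
  if (!isTRUE(all.equal(data$duration, model$duration)))
    abort("data and model sets must have equal durations")
  if (data$n_sweeps < 2 || model$n_sweeps < 2)
    abort("Md* needs at least 2 sweeps on each side (pairwise terms)")
  Tdur <- data$duration
  nu_d <- mean(lengths(data$trains)) / Tdur
  nu_m <- mean(lengths(model$trains)) / Tdur

  n_dm <- mean_pair_coincidences(data$trains, model$trains, precision,
                                 include_self = TRUE)
  n_dd <- mean_pair_coincidences(data$trains, data$trains, precision,
                                 include_self = TRUE)
  n_mm <- mean_pair_coincidences(model$trains, model$trains, precision,
                                 include_self = TRUE)

  num <- n_dm - chance_coincidences(nu_d, nu_m, precision, Tdur)
  den <- (n_dd - chance_coincidences(nu_d, nu_d, precision, Tdur)) +
         (n_mm - chance_coincidences(nu_m, nu_m, precision, Tdur))
  if (den <= 0) return(NA_real_)
  2 * num / den
}

#' Intrinsic reliability of repeated sweeps
#'
#' Mean pairwise chance-corrected coincidence factor across distinct
#' sweep pairs of the same data set at the stated precision:
#' \deqn{\Gamma_{ij} = \frac{c_{ij} - e_{ij}}{\sqrt{c_{ii} c_{jj}} - e_{ij}}}
#' with `c` the boxcar-kernel coincidence count (spike pairs within the
#' precision window) and `e` the analytic Poisson chance count for the
#' pair.  Identical sweeps give 1; independent Poisson sweeps give
#' approximately 0.
#'
#' @param data A [spike_train_set()] with at least 2 sweeps.
#' @param precision Coincidence window, ms.
#' @return Reliability score (<= 1; chance level 0).
#' @export
intrinsic_reliability <- function(data, precision = 8) {
  stopifnot(inherits(data, "spike_train_set"))
  R <- data$n_sweeps
  if (R < 2) abort("intrinsic reliability needs at least 2 sweeps")
  Tdur <- data$duration
  gam <- c()
  for (i in seq_len(R - 1)) {
    for (j in seq.int(i + 1, R)) {
      x <- data$trains[[i]]; y <- data$trains[[j]]
      e <- chance_coincidences(length(x) / Tdur, length(y) / Tdur,
                               precision, Tdur)
      den <- sqrt(count_coincidences(x, x, precision) *
                    count_coincidences(y, y, precision)) - e
      if (!is.finite(den) || den <= 0) next
      gam <- c(gam, (count_coincidences(x, y, precision) - e) / den)
    }
  }
  if (length(gam) == 0) return(NA_real_)
  mean(gam)
}

#' Spike-window-excluded R-squared on dV/dt
#'
#' Coefficient of determination between predicted and observed voltage
#' derivatives, computed over samples outside a window around each spike
#' (`window[1]` ms before to `window[2]` ms after; 1.5/6.5 ms for 5-HT
#' neurons, 1.5/4.0 ms for SOM and mPFC).  The excluded windows remove
#' the action-potential waveform, which the subthreshold model does not
#' describe.
#'
#' @param predicted,observed Aligned dV/dt traces (same `dt`).
#' @param spike_times Spike times, ms.
#' @param window Exclusion window `(pre, post)`, ms.
#' @param dt Sample interval, ms.
#' @return R-squared over the retained samples (`NA` if the retained
#'   observations have zero variance).
#' @export
r_squared_subthreshold <- function(predicted, observed, spike_times,
                                   window = c(1.5, 6.5), dt = 0.1) {
  stopifnot(length(predicted) == length(observed), length(window) == 2)
  keep <- !spike_window_mask(length(observed), spike_times, window, dt)
  obs <- observed[keep]; pred <- predicted[keep]
  sst <- sum((obs - mean(obs))^2)
  if (sst <= 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

# Logical mask of samples falling inside any per-spike exclusion window.
spike_window_mask <- function(n, spike_times, window, dt) {
  mask <- logical(n)
  for (ts in spike_times) {
    a <- max(1L, floor((ts - window[1]) / dt) + 1L)
    b <- min(n, ceiling((ts + window[2]) / dt) + 1L)
    if (a <= b) mask[a:b] <- TRUE
  }
  mask
}

#' Exclusion window and refractory period by cell type
#'
#' 5-HT neurons use a (1.5, 6.5) ms window around each spike; SOM and
#' mPFC use (1.5, 4.0) ms.  The post-spike width doubles as the absolute
#' refractory period of fitted models.
#'
#' @param cell_type One of `"5-HT"`, `"SOM"`, `"mPFC"`.
#' @return Numeric `(pre, post)` in ms.
#' @export
exclusion_window <- function(cell_type = c("5-HT", "SOM", "mPFC")) {
  cell_type <- match.arg(cell_type)
  if (cell_type == "5-HT") c(1.5, 6.5) else c(1.5, 4.0)
}
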