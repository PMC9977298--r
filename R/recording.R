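#' Current-clamp recording container
#'
#' A recording is a tidy table of paired voltage/current sweeps: columns
#' `sweep` (integer), `t` (ms), `V` (mV) and `I` (pA), with the sample
#' interval, cell type and free-form metadata carried as attributes.
#' Surrogate recordings produced by [generate_surrogate_recording()] use
#' the same container as parsed experimental data.
#'
#' @param sweeps A data frame with columns `sweep`, `t`, `V`, `I`.
#' @param dt Sample interval, ms.
#' @param cell_type One of `"5-HT"`, `"SOM"`, `"mPFC"`.
#' @param metadata Optional named list (protocol, seeds, ...).
#' @return A tibble of class `recording`.
#' @export
recording <- function(sweeps, dt, cell_type = "5-HT", metadata = list()) {
  stopifnot(all(c("sweep", "t", "V", "I") %in% names(sweeps)), dt > 0)
  out <- as_tibble(sweeps)
  attr(out, "dt") <- dt
  attr(out, "cell_type") <- cell_type
  attr(out, "metadata") <- metadata
  class(out) <- c("recording", class(out))
  out
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s, %d sweeps at dt = %g ms\n",
              attr(x, "cell_type"), length(unique(x$sweep)), attr(x, "dt")))
  NextMethod()
}

rec_dt <- function(rec) {
  d <- attr(rec, "dt")
  if (is.null(d)) abort("recording has no `dt` attribute")
  d
}

rec_sweeps <- function(rec) {
  split(as.data.frame(rec)[c("t", "V", "I")], rec$sweep)
}

#' Spike times in a recording
#'
#' Detected upward threshold crossings per sweep (see [detect_spikes()]).
#'
#' @param rec A [recording()].
#' @param threshold Detection threshold, mV.
#' @param min_interval Minimum separation between detected spikes, ms.
#' @return A [spike_train_set()].
#' @export
recording_spikes <- function(rec, threshold = 0, min_interval = 2) {
  dt <- rec_dt(rec)
  sw <- rec_sweeps(rec)
  trains <- lapply(sw, function(s)
    detect_spikes(s$V, dt, threshold, min_interval))
  spike_train_set(trains, duration = max(lengths(lapply(sw, `[[`, "V"))) * dt)
}

#' Detect spikes as upward threshold crossings
#'
#' A spike is recorded at each sample where the voltage crosses
#' `threshold` from below, with successive detections separated by at
#' least `min_interval`.
#'
#' @param V Voltage trace, mV.
#' @param dt Sample interval, ms.
#' @param threshold Detection threshold, mV.
#' @param min_interval Minimum inter-spike separation, ms.
#' @return Spike times, ms (crossing-sample times).
#' @export
detect_spikes <- function(V, dt, threshold = 0, min_interval = 2) {
  stopifnot(dt > 0)
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold)
  if (length(V) > 0 && V[1] >= threshold) up <- c(0L, up)
  t <- up * dt
  if (length(t) <= 1) return(t)
  keep <- c(TRUE, diff(t) >= min_interval)
  # enforce separation sequentially (a run of close crossings keeps the first)
  out <- t[1]
  for (ti in t[-1]) if (ti - out[length(out)] >= min_interval) out <- c(out, ti)
  out
}

#' Recording quality control
#'
#' Flags recordings with non-stationary firing (Pearson correlation
#' between validation sweep spike count and sweep number above 0.9,
#' indicating drift) or unreliable spike timing (intrinsic reliability
#' below 0.1).  Both criteria are always reported.
#'
#' @param validation_trains A [spike_train_set()] of at least 3
#'   validation sweeps.
#' @param precision Coincidence window for reliability, ms.
#' @return A one-row tibble: `include`, `drift_r`, `reliability`,
#'   `reasons` (empty string when included).
#' @export
qc_recording <- function(validation_trains, precision = 8) {
  stopifnot(inherits(validation_trains, "spike_train_set"))
  if (validation_trains$n_sweeps < 3)
    abort("QC requires at least 3 validation sweeps")
  counts <- lengths(validation_trains$trains)
  drift_r <- if (sd(counts) == 0) 0 else cor(counts, seq_along(counts))
  rel <- intrinsic_reliability(validation_trains, precision)
  reasons <- c(
    if (is.finite(drift_r) && drift_r > 0.9) "drift" else NULL,
    if (!is.na(rel) && rel < 0.1) "unreliable" else NULL)
  tibble(include = length(reasons) == 0, drift_r = drift_r,
         reliability = rel, reasons = paste(reasons, collapse = ";"))
}
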