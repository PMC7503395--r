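# Protocol-level firing analysis: spike detection, rheobase, f-I curve,
# input-output gain and maximal firing frequency.

#' Detect action potentials in a voltage trace
#'
#' A spike is an upward crossing of `threshold_mV` (default 0 mV) that is
#' followed by a local maximum within `max_peak_latency_ms`, with a
#' prominence of at least `prominence_mV` above the minimum voltage in the
#' 2 ms preceding the crossing. Crossings within `refractory_ms` of the
#' previous accepted spike are discarded. Only crossings inside the step
#' window count; an empty train is a valid result.
#'
#' @param tr A voltage [trace()].
#' @param threshold_mV Crossing level, mV.
#' @param prominence_mV Minimum peak prominence, mV.
#' @param max_peak_latency_ms Maximum crossing-to-peak latency, ms.
#' @param refractory_ms Refractory period, ms.
#' @return An object of class `"spike_train"`: `spike_times` (s, crossing
#'   times), `spike_peak_indices`, `peak_times`, `step_amplitude`.
#' @export
detect_spikes <- function(tr, threshold_mV = 0, prominence_mV = 20,
                          max_peak_latency_ms = 2, refractory_ms = 1) {
  stopifnot(inherits(tr, "trace"))
  if (tr$signal_kind != "voltage") {
    stop("spike detection requires a voltage trace", call. = FALSE)
  }
  v <- tr$samples
  dt <- tr$sampling_interval
  tt <- trace_time(tr)
  n <- length(v)
  up <- which(v[-1] >= threshold_mV & v[-n] < threshold_mV) + 1L
  if (!is.null(tr$step_window)) {
    # spikes initiated at the very end of the step peak just after it; allow
    # one peak-latency of margin beyond the window
    w <- tr$step_window
    margin <- max_peak_latency_ms * 1e-3
    up <- up[tt[up] >= w[1] - dt / 2 & tt[up] <= w[2] + margin]
  }
  lat <- max(1L, as.integer(round(max_peak_latency_ms * 1e-3 / dt)))
  pre <- max(1L, as.integer(round(2e-3 / dt)))
  times <- numeric(0); peaks <- integer(0)
  last_t <- -Inf
  for (k in up) {
    if (tt[k] - last_t < refractory_ms * 1e-3) next
    hi <- min(n, k + lat)
    seg <- v[k:hi]
    pk_rel <- which.max(seg)
    pk <- k + pk_rel - 1L
    # must be a genuine local maximum inside the latency window
    if (pk == hi && hi < n && v[hi + 1L] > v[hi]) next
    lo <- max(1L, k - pre)
    prom <- v[pk] - min(v[lo:k])
    if (prom < prominence_mV) next
    # interpolated crossing time of the detection threshold
    tc <- tt[k - 1L] + dt * (threshold_mV - v[k - 1L]) / (v[k] - v[k - 1L])
    times <- c(times, tc)
    peaks <- c(peaks, pk)
    last_t <- tc
  }
  structure(list(spike_times = times, spike_peak_indices = peaks,
                 peak_times = tt[peaks],
                 step_amplitude = tr$step_amplitude),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes at %g pA\n",
              length(x$spike_times), x$step_amplitude))
  invisible(x)
}

spike_counts <- function(steps, ...) {
  vapply(steps$traces,
         function(tr) length(detect_spikes(tr, ...)$spike_times),
         integer(1))
}

#' Rheobase of a step protocol
#'
#' The smallest injected amplitude whose trace contains at least one
#' detected spike (the protocol's amplitude resolution, e.g. 5 pA, bounds
#' the quantization error from above).
#'
#' @param steps A [step_protocol_set()].
#' @param ... Passed to [detect_spikes()].
#' @return Rheobase in pA, with attribute `"n_spikes"` at that step. The
#'   first step already spiking raises a lower-bound warning.
#' @export
find_rheobase <- function(steps, ...) {
  stopifnot(inherits(steps, "step_protocol_set"))
  counts <- spike_counts(steps, ...)
  firing <- which(counts > 0L)
  if (!length(firing)) {
    stop("rheobase not found: no step elicited a spike", call. = FALSE)
  }
  k <- firing[1]
  if (k == 1L) {
    warning("first step already spiking: rheobase is only an upper bound")
  }
  out <- steps$injected_amplitudes[k]
  attr(out, "n_spikes") <- counts[k]
  out
}

#' Frequency-current (f-I) curve
#'
#' Firing frequency per step, defined as spike count divided by step
#' duration; zero-frequency (including hyperpolarizing) steps are retained.
#'
#' @param steps A [step_protocol_set()].
#' @param ... Passed to [detect_spikes()].
#' @return An object of class `"fi_curve"`: data.frame-like list with
#'   `currents` (pA) and `frequencies` (Hz).
#' @export
fi_curve <- function(steps, ...) {
  stopifnot(inherits(steps, "step_protocol_set"))
  counts <- spike_counts(steps, ...)
  structure(list(currents = steps$injected_amplitudes,
                 frequencies = counts / steps$step_duration),
            class = "fi_curve")
}

#' Input-output gain of an f-I curve
#'
#' The differential of firing frequency over injected current, estimated by
#' finite differences between consecutive protocol points; the gain is the
#' maximum slope and `current_at_max_gain` the midpoint of the maximizing
#' interval. Optional 3-point moving-average smoothing of the frequencies.
#'
#' @param curve An [fi_curve()] with at least 3 points.
#' @param smooth Apply 3-point smoothing before differencing.
#' @return List with `gain` (Hz/pA) and `current_at_max_gain` (pA).
#' @export
io_gain <- function(curve, smooth = FALSE) {
  stopifnot(inherits(curve, "fi_curve"))
  f <- curve$frequencies
  x <- curve$currents
  if (length(f) < 3L) {
    stop("insufficient data: io_gain needs at least 3 points", call. = FALSE)
  }
  if (smooth) {
    sm <- stats::filter(f, rep(1 / 3, 3), sides = 2)
    f <- ifelse(is.na(sm), f, as.numeric(sm))
  }
  slopes <- diff(f) / diff(x)
  k <- which.max(slopes)
  list(gain = slopes[k], current_at_max_gain = (x[k] + x[k + 1L]) / 2)
}

#' Maximal firing frequency across a step protocol
#'
#' @param steps A [step_protocol_set()].
#' @param ... Passed to [detect_spikes()].
#' @return Maximum of the f-I frequencies, Hz (0 for an all-silent set).
#' @export
max_firing_frequency <- function(steps, ...) {
  max(fi_curve(steps, ...)$frequencies)
}
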