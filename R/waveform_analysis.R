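# Single-AP phase-plane analysis: threshold at the 20 V/s criterion, dV/dt
# extrema, half-width, initial-segment (IS) vs somatodendritic (SD) rising
# phase components, and after-potential (AHP/ADP) classification.

#' Phase plot (dV/dt against V) around one action potential
#'
#' dV/dt is computed by central differences on the raw voltage (mV/ms,
#' i.e. V/s), optionally after Savitzky-Golay pre-smoothing of the voltage,
#' and paired with the voltage samples in time order.
#'
#' @param tr A voltage [trace()].
#' @param peak_index Sample index of the AP peak (e.g. from
#'   [detect_spikes()]`$spike_peak_indices`).
#' @param window_ms Length-2: milliseconds before and after the peak.
#' @param smooth Savitzky-Golay smoothing (window 7, order 3) of the voltage
#'   before differencing.
#' @return An object of class `"phase_plot"`: `voltage` (mV), `dvdt` (V/s),
#'   `time` (s), `peak_idx` (index within the window), `dt`.
#' @export
phase_plot <- function(tr, peak_index, window_ms = c(3, 8), smooth = FALSE) {
  stopifnot(inherits(tr, "trace"))
  dt <- tr$sampling_interval
  n <- length(tr$samples)
  i0 <- peak_index - as.integer(round(window_ms[1] * 1e-3 / dt))
  i1 <- peak_index + as.integer(round(window_ms[2] * 1e-3 / dt))
  if (i0 < 2L || i1 > n - 1L) {
    stop("boundary error: phase-plot window is clipped by the trace",
         call. = FALSE)
  }
  v <- tr$samples
  if (smooth) v <- sgolay_smooth(v)
  idx <- i0:i1
  dvdt <- (v[idx + 1L] - v[idx - 1L]) / (2 * dt * 1e3)  # mV/ms = V/s
  structure(list(voltage = v[idx], dvdt = dvdt,
                 time = trace_time(tr)[idx],
                 peak_idx = peak_index - i0 + 1L, dt = dt),
            class = "phase_plot")
}

sgolay_smooth <- function(x, p = 3, n = 7) {
  if (length(x) < n) return(x)
  as.numeric(signal::sgolayfilt(x, p = p, n = n))
}

#' AP threshold from the dV/dt criterion
#'
#' Voltage at the first upward crossing of `criterion_vps` (default 20 V/s)
#' before the AP peak, linearly interpolated between samples.
#'
#' @param pp A [phase_plot()].
#' @param criterion_vps Slope criterion, V/s. A criterion of 0 degenerates
#'   to the first positive slope.
#' @return Threshold voltage, mV.
#' @export
ap_threshold <- function(pp, criterion_vps = 20) {
  stopifnot(inherits(pp, "phase_plot"))
  d <- pp$dvdt; v <- pp$voltage
  upto <- pp$peak_idx
  cross <- which(d[seq_len(upto)][-1] >= criterion_vps &
                   d[seq_len(upto - 1L)] < criterion_vps) + 1L
  if (!length(cross)) {
    if (criterion_vps <= 0 && any(d[seq_len(upto)] > 0)) {
      return(v[which(d[seq_len(upto)] > 0)[1]])
    }
    stop(sprintf("no-AP error: dV/dt never exceeds %g V/s before the peak",
                 criterion_vps), call. = FALSE)
  }
  k <- cross[1]
  frac <- (criterion_vps - d[k - 1L]) / (d[k] - d[k - 1L])
  v[k - 1L] + frac * (v[k] - v[k - 1L])
}

#' Extrema of dV/dt within a phase plot
#'
#' @param pp A [phase_plot()].
#' @return List with `max_dvdt` and `min_dvdt`, V/s.
#' @export
slope_extrema <- function(pp) {
  stopifnot(inherits(pp, "phase_plot"))
  list(max_dvdt = max(pp$dvdt), min_dvdt = min(pp$dvdt))
}

#' AP half-width
#'
#' Duration at half amplitude, where the 50% level is referenced from
#' threshold to peak; both flank crossings are linearly interpolated.
#'
#' @param tr A voltage [trace()].
#' @param threshold Threshold voltage, mV (see [ap_threshold()]).
#' @param peak_index Sample index of the AP peak.
#' @return Half-width in ms.
#' @export
ap_half_width <- function(tr, threshold, peak_index) {
  stopifnot(inherits(tr, "trace"))
  v <- tr$samples
  dt <- tr$sampling_interval
  vpk <- v[peak_index]
  if (threshold >= vpk) {
    stop("threshold must lie below the peak voltage", call. = FALSE)
  }
  vhalf <- threshold + (vpk - threshold) / 2
  # rising flank: last upward crossing before the peak
  pre <- seq_len(peak_index)
  ups <- which(v[pre][-1] >= vhalf & v[pre[-length(pre)]] < vhalf) + 1L
  if (!length(ups)) {
    stop("shape error: rising flank never crosses the half-amplitude level",
         call. = FALSE)
  }
  k <- ups[length(ups)]
  t_rise <- (k - 1L + (vhalf - v[k - 1L]) / (v[k] - v[k - 1L]) - 1L) * dt
  # falling flank: first downward crossing after the peak
  post <- peak_index:length(v)
  dns <- which(v[post][-1] <= vhalf & v[post[-length(post)]] > vhalf) + 1L
  if (!length(dns)) {
    stop("shape error: repolarization never reaches the half-amplitude level",
         call. = FALSE)
  }
  j <- peak_index + dns[1] - 1L
  t_fall <- (j - 1L + (vhalf - v[j - 1L]) / (v[j] - v[j - 1L]) - 1L) * dt
  (t_fall - t_rise) * 1e3
}

# Topographic prominence of local maxima in a numeric vector. Returns a
# data.frame(idx, height, prominence), time-ordered.
local_maxima_prominence <- function(x) {
  n <- length(x)
  if (n < 3L) {
    return(data.frame(idx = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  is_max <- which(diff(sign(diff(x))) < 0) + 1L
  # plateau-tolerant: also treat flat-topped maxima
  if (!length(is_max)) {
    return(data.frame(idx = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(is_max, function(i) {
    h <- x[i]
    # walk left until a higher point or the boundary
    left <- x[seq_len(i - 1L)]
    hi_l <- which(left > h)
    base_l <- if (length(hi_l)) min(x[(max(hi_l) + 1L):(i - 1L)]) else min(left)
    right <- x[(i + 1L):n]
    hi_r <- which(right > h)
    base_r <- if (length(hi_r)) min(x[(i + 1L):(i + min(hi_r) - 1L)]) else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  data.frame(idx = is_max, height = x[is_max], prominence = prom)
}

#' Initial-segment and somatodendritic components of the AP upstroke
#'
#' Local maxima of dV/dt over the rising phase (threshold to peak) are
#' located after mild Savitzky-Golay smoothing. With two or more maxima of
#' prominence at least `min_prominence` V/s, the first (lower-voltage)
#' maximum is the initial-segment (IS) component and the absolute maximum
#' the somatodendritic (SD) component; with a single maximum the AP is
#' monophasic and the IS component is that maximum (as in immature neurons
#' whose AP carries only the AIS phase).
#'
#' @param pp A [phase_plot()].
#' @param min_prominence Minimum peak prominence, V/s.
#' @param smooth Smooth dV/dt before peak-finding (default on).
#' @param criterion_vps Slope criterion isolating the rising phase.
#' @return An object of class `"issd_components"`: `is_peak`, `sd_peak`
#'   (V/s; `NA` when monophasic), `ratio` (IS/SD), `biphasic`, `n_peaks`,
#'   and the voltages at which the component peaks occur.
#' @export
is_sd_components <- function(pp, min_prominence = 10, smooth = TRUE,
                             criterion_vps = 20) {
  stopifnot(inherits(pp, "phase_plot"))
  d <- pp$dvdt
  if (smooth) d <- sgolay_smooth(d)
  upto <- pp$peak_idx
  seg_start <- which(d[seq_len(upto)] >= criterion_vps)
  if (!length(seg_start)) {
    stop("shape error: no rising phase above the slope criterion",
         call. = FALSE)
  }
  idx <- seg_start[1]:upto
  seg <- d[idx]
  pk <- local_maxima_prominence(seg)
  # the segment end (voltage peak, dvdt ~ 0) is never a maximum; the global
  # maximum may sit at the segment boundary on strongly asymmetric upstrokes
  if (!nrow(pk)) {
    gm <- which.max(seg)
    pk <- data.frame(idx = gm, height = seg[gm], prominence = max(seg) -
                       min(seg))
  }
  qual <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (!nrow(qual)) {
    qual <- pk[which.max(pk$prominence), , drop = FALSE]
  }
  volt <- pp$voltage[idx]
  if (nrow(qual) >= 2L) {
    is_peak <- qual$height[1]
    sd_peak <- max(seg)
    structure(list(is_peak = is_peak, sd_peak = sd_peak,
                   ratio = is_peak / sd_peak, biphasic = TRUE,
                   n_peaks = nrow(qual),
                   is_voltage = volt[qual$idx[1]],
                   sd_voltage = volt[which.max(seg)]),
              class = "issd_components")
  } else {
    structure(list(is_peak = qual$height[1], sd_peak = NA_real_,
                   ratio = NA_real_, biphasic = FALSE, n_peaks = 1L,
                   is_voltage = volt[qual$idx[1]], sd_voltage = NA_real_),
              class = "issd_components")
  }
}

#' @export
print.issd_components <- function(x, ...) {
  if (x$biphasic) {
    cat(sprintf("<issd_components> biphasic: IS = %.1f, SD = %.1f V/s (ratio %.3f)\n",
                x$is_peak, x$sd_peak, x$ratio))
  } else {
    cat(sprintf("<issd_components> monophasic: IS = %.1f V/s\n", x$is_peak))
  }
  invisible(x)
}

#' After-potential profile (AHP/ADP) of one action potential
#'
#' The window runs from the downward threshold crossing after the spike peak
#' to `window_ms` later (or until the next spike). Amplitudes are signed and
#' referenced to the AP threshold. The profile is tri-phasic when a fast AHP
#' (local minimum), an after-depolarization (local maximum) and a later slow
#' AHP (minimum) all occur with prominence at least `min_prominence_mv`;
#' otherwise it is mono-phasic and `ahp_slow_mono` is the deepest excursion.
#'
#' @param tr A voltage [trace()].
#' @param peak_index Sample index of the AP peak.
#' @param threshold AP threshold, mV.
#' @param window_ms After-potential window, ms.
#' @param min_prominence_mv Minimum extremum prominence, mV.
#' @param next_spike_index Optional sample index of the next spike's onset;
#'   truncates the window. A window shorter than 5 ms sets the `unresolved`
#'   flag.
#' @return An object of class `"after_potential_profile"`: `shape_class`
#'   (`"mono"` or `"tri"`), `ahp_slow_mono`, `ahp_fast`, `adp` (mV relative
#'   to threshold; `NA` where absent), `unresolved`.
#' @export
ahp_adp_profile <- function(tr, peak_index, threshold, window_ms = 100,
                            min_prominence_mv = 0.5,
                            next_spike_index = NULL) {
  stopifnot(inherits(tr, "trace"))
  v <- tr$samples
  dt <- tr$sampling_interval
  n <- length(v)
  post <- peak_index:n
  dn <- which(v[post][-1] <= threshold & v[post[-length(post)]] > threshold)
  if (!length(dn)) {
    stop("voltage never recrosses threshold after the peak", call. = FALSE)
  }
  i0 <- peak_index + dn[1]
  i1 <- min(n, i0 + as.integer(round(window_ms * 1e-3 / dt)))
  if (!is.null(next_spike_index)) i1 <- min(i1, next_spike_index - 1L)
  unresolved <- (i1 - i0) * dt < 5e-3
  rel <- v[i0:i1] - threshold
  minima <- local_maxima_prominence(-rel)
  minima$height <- -minima$height
  maxima <- local_maxima_prominence(rel)
  qmin <- minima[minima$prominence >= min_prominence_mv, , drop = FALSE]
  qmax <- maxima[maxima$prominence >= min_prominence_mv, , drop = FALSE]
  tri <- FALSE
  if (nrow(qmin) >= 1L && nrow(qmax) >= 1L) {
    fast_i <- qmin$idx[1]
    adp_after <- qmax[qmax$idx > fast_i, , drop = FALSE]
    if (nrow(adp_after)) {
      adp_i <- adp_after$idx[1]
      later <- which(seq_along(rel) > adp_i)
      if (length(later)) {
        slow_i <- later[which.min(rel[later])]
        if (rel[slow_i] < rel[adp_i]) {
          tri <- TRUE
          out <- list(shape_class = "tri",
                      ahp_slow_mono = rel[slow_i],
                      ahp_fast = rel[fast_i],
                      adp = rel[adp_i],
                      unresolved = unresolved)
        }
      }
    }
  }
  if (!tri) {
    out <- list(shape_class = "mono", ahp_slow_mono = min(rel),
                ahp_fast = NA_real_, adp = NA_real_,
                unresolved = unresolved)
  }
  structure(out, class = "after_potential_profile")
}
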