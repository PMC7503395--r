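#' Calibrated single-channel trace
#'
#' Container for one calibrated time series as acquired in a patch-clamp
#' experiment: a current response to a voltage-clamp seal-test step, or a
#' voltage response to a current-clamp step. Units are fixed at the API
#' boundary: voltage in mV, current in pA, time in seconds internally.
#'
#' @param samples Numeric vector of samples (mV for voltage, pA for current).
#' @param sampling_interval Sampling interval in seconds (> 0).
#' @param signal_kind Either `"voltage"` or `"current"`.
#' @param baseline_window Length-2 numeric, `[t0, t1]` in seconds, used for
#'   baseline estimation. `NULL` if not applicable.
#' @param step_window Length-2 numeric, `[t_on, t_off]` in seconds: when the
#'   command step is applied. `NULL` if no step.
#' @param step_amplitude Step amplitude: mV for voltage-clamp commands, pA for
#'   current-clamp injections.
#' @param holding_level Holding level before/after the step (mV or pA).
#' @param meta Free-form list of metadata; synthetic generators store their
#'   ground truth here.
#'
#' @return An object of class `"trace"`.
#' @export
trace <- function(samples, sampling_interval, signal_kind,
                  baseline_window = NULL, step_window = NULL,
                  step_amplitude = NA_real_, holding_level = NA_real_,
                  meta = list()) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop("`samples` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      sampling_interval <= 0) {
    stop("`sampling_interval` must be a single positive number", call. = FALSE)
  }
  signal_kind <- match.arg(signal_kind, c("voltage", "current"))
  t_end <- length(samples) * sampling_interval
  check_window <- function(w, name) {
    if (is.null(w)) return(NULL)
    if (length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2]) {
      stop(sprintf("`%s` must be [t0, t1] with t0 < t1", name), call. = FALSE)
    }
    if (w[1] < 0 || w[2] > t_end + sampling_interval / 2) {
      stop(sprintf("`%s` must lie within the trace duration", name),
           call. = FALSE)
    }
    as.numeric(w)
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_interval = as.numeric(sampling_interval),
         signal_kind = signal_kind,
         baseline_window = check_window(baseline_window, "baseline_window"),
         step_window = check_window(step_window, "step_window"),
         step_amplitude = as.numeric(step_amplitude),
         holding_level = as.numeric(holding_level),
         meta = meta),
    class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s, %d samples @ %g kHz (%.1f ms)\n",
              x$signal_kind, length(x$samples),
              1e-3 / x$sampling_interval,
              length(x$samples) * x$sampling_interval * 1e3))
  if (!is.null(x$step_window)) {
    cat(sprintf("  step: %g %s over [%g, %g] s\n", x$step_amplitude,
                if (x$signal_kind == "current") "mV (command)" else "pA",
                x$step_window[1], x$step_window[2]))
  }
  invisible(x)
}

#' Time axis of a trace
#'
#' @param tr A [trace()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
trace_time <- function(tr) {
  (seq_along(tr$samples) - 1L) * tr$sampling_interval
}

# Index range of a [t0, t1] window (seconds), clamped to the trace.
window_idx <- function(tr, w) {
  n <- length(tr$samples)
  i0 <- max(1L, 1L + as.integer(ceiling(w[1] / tr$sampling_interval - 1e-9)))
  i1 <- min(n, 1L + as.integer(floor(w[2] / tr$sampling_interval + 1e-9)))
  if (i1 < i0) stop("window contains no samples", call. = FALSE)
  i0:i1
}

#' Ordered set of current-clamp step responses
#'
#' One trace per injected amplitude, as acquired by a stepwise
#' current-injection protocol (e.g. 5 pA or 20 pA increments, 500 ms steps).
#'
#' @param traces List of voltage [trace()] objects, one per amplitude.
#' @param injected_amplitudes Numeric vector of injected currents (pA),
#'   strictly increasing, one per trace.
#' @param step_duration Step duration in seconds (default 0.5).
#' @param inter_step_hold Inter-step holding duration in seconds.
#' @param meta Free-form metadata list (ground truth for synthetic sets).
#'
#' @return An object of class `"step_protocol_set"`.
#' @export
step_protocol_set <- function(traces, injected_amplitudes,
                              step_duration = 0.5, inter_step_hold = 0.5,
                              meta = list()) {
  if (length(traces) != length(injected_amplitudes)) {
    stop("one amplitude per trace is required", call. = FALSE)
  }
  if (length(injected_amplitudes) > 1L &&
      any(diff(injected_amplitudes) <= 0)) {
    stop("`injected_amplitudes` must be strictly increasing", call. = FALSE)
  }
  if (step_duration <= 0) stop("`step_duration` must be > 0", call. = FALSE)
  ok <- vapply(traces, inherits, logical(1), what = "trace")
  if (!all(ok)) stop("`traces` must be a list of trace objects", call. = FALSE)
  structure(
    list(traces = traces,
         injected_amplitudes = as.numeric(injected_amplitudes),
         step_duration = as.numeric(step_duration),
         inter_step_hold = as.numeric(inter_step_hold),
         meta = meta),
    class = "step_protocol_set")
}

#' @export
print.step_protocol_set <- function(x, ...) {
  amps <- x$injected_amplitudes
  cat(sprintf("<step_protocol_set> %d steps, %g..%g pA, %g ms each\n",
              length(amps), min(amps), max(amps), x$step_duration * 1e3))
  invisible(x)
}

#' Read a trace from a CSV table plus JSON sidecar
#'
#' The on-disk format is a comma-separated table with a `time_s` and a
#' `signal` column (names remappable through `schema`), optional
#' `#`-prefixed comment/unit header lines, and a JSON sidecar
#' (`<path>.json`) declaring `signal_kind`, `step_amplitude`, `step_on_s`,
#' `step_off_s` and `holding`. Sampling must be uniform: rows are required to
#' be time-ordered and jitter beyond half a sampling interval is rejected
#' rather than silently interpolated (set `resample = TRUE` to opt in to
#' linear resampling onto a uniform grid).
#'
#' @param path CSV file path.
#' @param schema Named list mapping `time` and `signal` to column names.
#' @param sidecar Path of the JSON sidecar; defaults to `<path>.json`.
#' @param resample Permit linear resampling of jittered time bases.
#' @return A [trace()].
#' @export
read_trace_table <- function(path,
                             schema = list(time = "time_s", signal = "signal"),
                             sidecar = paste0(path, ".json"),
                             resample = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  for (col in c(schema$time, schema$signal)) {
    if (!col %in% names(df)) {
      stop(sprintf("schema error: column '%s' not found in %s", col, path),
           call. = FALSE)
    }
  }
  tt <- as.numeric(df[[schema$time]])
  y <- as.numeric(df[[schema$signal]])
  if (length(tt) < 2L) stop("format error: fewer than 2 rows", call. = FALSE)
  dts <- diff(tt)
  if (any(dts <= 0)) {
    stop("format error: time column is not strictly increasing", call. = FALSE)
  }
  dt <- stats::median(dts)
  jitter <- max(abs(dts - dt))
  if (jitter > 0.5 * dt) {
    if (!resample) {
      stop("format error: non-uniform sampling (jitter > 0.5 sample); ",
           "pass resample = TRUE to permit resampling", call. = FALSE)
    }
    grid <- seq(tt[1], tt[length(tt)], by = dt)
    y <- stats::approx(tt, y, xout = grid)$y
    tt <- grid
  }
  side <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    stop("unit error: sidecar not found (units/protocol undeclared): ",
         sidecar, call. = FALSE)
  }
  if (is.null(side$signal_kind)) {
    stop("unit error: sidecar lacks `signal_kind`", call. = FALSE)
  }
  step_window <- if (!is.null(side$step_on_s)) {
    c(side$step_on_s, side$step_off_s)
  }
  baseline_window <- if (!is.null(side$baseline_on_s)) {
    c(side$baseline_on_s, side$baseline_off_s)
  } else if (!is.null(step_window) && step_window[1] > 0) {
    c(max(0, step_window[1] - 0.01), step_window[1])
  }
  trace(samples = y,
        sampling_interval = dt,
        signal_kind = side$signal_kind,
        baseline_window = baseline_window,
        step_window = step_window,
        step_amplitude = side$step_amplitude %||% NA_real_,
        holding_level = side$holding %||% NA_real_,
        meta = side$meta %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trace to CSV plus JSON sidecar
#'
#' Inverse of [read_trace_table()]: full-precision comma-separated values
#' (round trips are bit-faithful to 1e-9 relative tolerance) with a
#' `#`-prefixed unit header, and a sidecar JSON carrying the protocol
#' metadata and any generator ground truth.
#'
#' @param tr A [trace()].
#' @param path Output CSV path; sidecar goes to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(tr, path) {
  stopifnot(inherits(tr, "trace"))
  unit <- if (tr$signal_kind == "voltage") "mV" else "pA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# time_s [s], signal [%s]", unit), con)
  writeLines("time_s,signal", con)
  writeLines(paste(format_num(trace_time(tr)), format_num(tr$samples),
                   sep = ","), con)
  side <- list(signal_kind = tr$signal_kind,
               step_amplitude = tr$step_amplitude,
               holding = tr$holding_level)
  if (!is.null(tr$step_window)) {
    side$step_on_s <- tr$step_window[1]
    side$step_off_s <- tr$step_window[2]
  }
  if (!is.null(tr$baseline_window)) {
    side$baseline_on_s <- tr$baseline_window[1]
    side$baseline_off_s <- tr$baseline_window[2]
  }
  if (length(tr$meta)) side$meta <- tr$meta
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

format_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write keyed feature records to a results CSV
#'
#' One row per record, stable column order taken from the first record, and
#' a `#`-prefixed unit header when units are supplied. All records must share
#' the same key set.
#'
#' @param records List of named lists (or a data.frame) sharing one key set.
#' @param path Output CSV path.
#' @param units Optional named character vector mapping columns to units.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(records, path, units = NULL) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (length(records)) {
      keys <- names(records[[1]])
      same <- vapply(records, function(r) identical(sort(names(r)), sort(keys)),
                     logical(1))
      if (!all(same)) {
        stop("schema error: records do not share a key set", call. = FALSE)
      }
      rows <- lapply(records, function(r) as.data.frame(r[keys]))
      df <- do.call(rbind, rows)
    } else {
      df <- data.frame()
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units) && ncol(df)) {
    u <- ifelse(names(df) %in% names(units), units[names(df)], "-")
    writeLines(paste0("# units: ", paste(names(df), u, sep = "=",
                                         collapse = ", ")), con)
  }
  if (!ncol(df) && !is.null(attr(records, "keys"))) {
    writeLines(paste(attr(records, "keys"), collapse = ","), con)
  } else {
    utils::write.table(format_df(df), con, sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

format_df <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) format_num(col) else col
  }), check.names = FALSE, optional = TRUE, stringsAsFactors = FALSE)
}

#' Read a results CSV written by [write_results_table()]
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}
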