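# Passive membrane properties from the voltage-clamp membrane test.
#
# The estimators implement the field's standard membrane-test arithmetic:
#   Rs  = |step| / |Imax|        (capacitive peak)
#   Rin = |step| / |Imem|        (steady-state leak; includes Rs)
#   Cm  = tau / Rs               (tau from a single-exponential fit)
# These are deliberately the "as-printed" estimators: on a true RC cell with
# membrane resistance Rm, Rin recovers Rs + Rm and Cm carries the known bias
# factor Rm/(Rs + Rm). `corrected = TRUE` removes both biases.

#' Analyze a seal-test (membrane test) current transient
#'
#' Baseline is the mean current over 10 ms immediately pre-step (or the
#' trace's `baseline_window`). `Imax` is the extremum of the
#' baseline-subtracted current after step onset; `Imem` the mean over the
#' final 20% of the step; `tau` comes from a single-exponential fit of the
#' decay from the capacitive peak toward `Imem` (log-linear initialization
#' refined by Levenberg-Marquardt least squares).
#'
#' @param tr A current [trace()] with a defined `step_window`.
#' @param step_mV Command step amplitude, mV; defaults to the trace's
#'   `step_amplitude`.
#' @param corrected If `TRUE`, additionally report bias-corrected values:
#'   `Rin_corrected = Rin - Rs` (the membrane resistance) and
#'   `Cm_corrected = tau * (1/Rs + 1/(Rin - Rs))`.
#' @param fit_r2_min Minimum accepted r-squared of the exponential fit.
#' @param steady_state_fraction Final fraction of the step averaged for
#'   `Imem`.
#' @return An object of class `"passive_properties"`: `Rs`, `Rin` (MOhm),
#'   `Cm` (pF), `tau` (ms), `Imax`, `Imem` (pA, baseline-subtracted),
#'   `fit_r2`, optional corrected values, and `flags`.
#' @export
analyze_seal_test <- function(tr, step_mV = NULL, corrected = FALSE,
                              fit_r2_min = 0.9, steady_state_fraction = 0.2) {
  stopifnot(inherits(tr, "trace"))
  if (tr$signal_kind != "current") {
    stop("seal-test analysis requires a current trace", call. = FALSE)
  }
  if (is.null(tr$step_window)) {
    stop("trace has no step_window", call. = FALSE)
  }
  if (is.null(step_mV)) step_mV <- tr$step_amplitude
  if (!is.finite(step_mV) || step_mV == 0) {
    stop("step amplitude (mV) is required", call. = FALSE)
  }
  dt <- tr$sampling_interval
  w <- tr$step_window
  if (w[2] - w[1] < 2e-3) {
    stop("need at least 2 ms of post-step data", call. = FALSE)
  }
  bw <- tr$baseline_window %||% c(max(0, w[1] - 0.01), w[1])
  base_idx <- window_idx(tr, bw)
  base_idx <- base_idx[trace_time(tr)[base_idx] < w[1] - dt / 2]
  if (!length(base_idx)) base_idx <- 1L
  baseline <- mean(tr$samples[base_idx])
  noise_sd <- stats::sd(tr$samples[base_idx])
  if (!is.finite(noise_sd)) noise_sd <- 0
  i <- tr$samples - baseline
  tt <- trace_time(tr)

  step_idx <- window_idx(tr, w)
  ss_idx <- window_idx(tr, c(w[2] - steady_state_fraction * (w[2] - w[1]),
                             w[2]))
  imem <- mean(i[ss_idx])
  pk_rel <- which.max(abs(i[step_idx]))
  pk <- step_idx[pk_rel]
  imax <- i[pk]
  if (abs(imax) < abs(imem)) imax <- imem  # invariant |Imax| >= |Imem|

  flags <- list()
  if (abs(imem) < 3 * noise_sd) flags$rin_unreliable <- TRUE

  # Exponential fit of the transient decay
  amp0 <- imax - imem
  fit <- fit_transient_decay(tt, i, pk, imem, amp0, dt, step_idx)
  if (is.null(fit)) {
    # no resolvable transient: resistive limit (Cm -> 0)
    tau_ms <- 0; r2 <- 1; flags$no_transient <- TRUE
  } else {
    tau_ms <- fit$tau_ms; r2 <- fit$r2
    if (r2 < fit_r2_min) {
      stop(sprintf("quality error: exponential fit r2 = %.3f < %.2f",
                   r2, fit_r2_min), call. = FALSE)
    }
  }

  rs <- 1000 * abs(step_mV) / abs(imax)       # mV/pA -> GOhm; *1000 -> MOhm
  rin <- 1000 * abs(step_mV) / abs(imem)
  cm <- 1000 * tau_ms / rs                    # ms/MOhm = nF -> pF

  out <- list(Rs = rs, Rin = rin, Cm = cm, tau = tau_ms,
              Imax = imax, Imem = imem, fit_r2 = r2, Erest = NA_real_,
              flags = flags)
  if (corrected) {
    rm_est <- rin - rs
    out$Rin_corrected <- rm_est
    out$Cm_corrected <- if (rm_est > 0) 1000 * tau_ms * (1 / rs + 1 / rm_est)
                        else NA_real_
  }
  structure(out, class = "passive_properties")
}

# Single-exponential fit of the capacitive decay: window from two samples
# after the peak until the transient has decayed to 5% of its amplitude
# above the steady state. Returns NULL when no transient is resolvable.
fit_transient_decay <- function(tt, i, pk, imem, amp0, dt, step_idx) {
  if (abs(amp0) < max(1e-12, 4 * stats::sd(i[seq_len(max(pk - 2, 1))]) / 2,
                      0.02 * abs(imem))) {
    return(NULL)
  }
  y_all <- i - imem
  end_rel <- which(abs(y_all[pk:max(step_idx)]) <= 0.05 * abs(amp0))
  i_end <- if (length(end_rel)) pk + end_rel[1] - 1L else max(step_idx)
  i0 <- min(pk + 2L, i_end)
  idx <- i0:i_end
  same_sign <- sign(y_all[idx]) == sign(amp0) & abs(y_all[idx]) > 0
  idx <- idx[same_sign]
  if (length(idx) < 3L) {
    # fall back to everything between peak and decay end
    idx <- pk:i_end
    idx <- idx[sign(y_all[idx]) == sign(amp0) & abs(y_all[idx]) > 0]
    if (length(idx) < 3L) return(NULL)
  }
  tloc <- tt[idx] - tt[pk]
  ylog <- log(abs(y_all[idx]))
  ll <- stats::lm.fit(cbind(1, tloc), ylog)
  tau_s <- unname(-1 / ll$coefficients[2])
  a0 <- unname(sign(amp0) * exp(ll$coefficients[1]))
  if (!is.finite(tau_s) || tau_s <= 0) return(NULL)
  y <- y_all[idx]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-tloc / tau),
                      start = list(A = a0, tau = tau_s),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (is.finite(cf[["tau"]]) && cf[["tau"]] > 0) {
      tau_s <- cf[["tau"]]
      pred <- cf[["A"]] * exp(-tloc / tau_s)
    } else {
      pred <- a0 * exp(-tloc / tau_s)
    }
  } else {
    pred <- a0 * exp(-tloc / tau_s)
  }
  ssr <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  list(tau_ms = tau_s * 1e3, r2 = r2)
}

#' @export
print.passive_properties <- function(x, ...) {
  cat(sprintf(paste0("<passive_properties> Rs = %.2f MOhm, Rin = %.1f MOhm, ",
                     "Cm = %.1f pF, tau = %.3f ms (r2 = %.3f)\n"),
              x$Rs, x$Rin, x$Cm, x$tau, x$fit_r2))
  invisible(x)
}

#' Resting membrane potential from a current-clamp baseline
#'
#' Mean voltage over the trace's baseline window (>= 50 ms with zero
#' injected current). A linear drift larger than 2 mV across the window
#' raises a stability warning and sets the `"drift_warning"` attribute.
#'
#' @param tr A voltage [trace()] with a `baseline_window` of at least 50 ms.
#' @return Erest in mV, with attributes `"drift_mV"` and `"drift_warning"`.
#' @export
measure_erest <- function(tr) {
  stopifnot(inherits(tr, "trace"))
  if (tr$signal_kind != "voltage") {
    stop("Erest is measured on a voltage trace", call. = FALSE)
  }
  bw <- tr$baseline_window
  if (is.null(bw) || (bw[2] - bw[1]) < 0.05) {
    stop("baseline_window of at least 50 ms is required", call. = FALSE)
  }
  idx <- window_idx(tr, bw)
  v <- tr$samples[idx]
  tt <- trace_time(tr)[idx]
  erest <- mean(v)
  slope <- stats::cov(tt, v) / stats::var(tt)
  drift <- slope * (bw[2] - bw[1])
  out <- erest
  attr(out, "drift_mV") <- drift
  attr(out, "drift_warning") <- abs(drift) > 2
  if (abs(drift) > 2) {
    warning(sprintf("baseline drift %.2f mV exceeds 2 mV across the window",
                    drift))
  }
  out
}

#' Extract a current-voltage relationship from voltage-clamp steps
#'
#' Per step: peak inward current = minimum of the baseline-subtracted
#' current within the early window after step onset; steady state = mean
#' over the final 10% of the step. Optional linear leak subtraction uses the
#' two most hyperpolarized steps to define the leak line.
#'
#' @param traces List of current [trace()] objects, one per command voltage
#'   (taken from each trace's `step_amplitude`, mV), strictly increasing.
#' @param leak `"none"` (default) or `"linear"`.
#' @param early_window_s Length of the window searched for the peak inward
#'   current, s.
#' @return An object of class `"iv_curve"`: `command_voltages`,
#'   `peak_inward`, `steady_state`.
#' @export
extract_iv <- function(traces, leak = c("none", "linear"),
                       early_window_s = 0.05) {
  leak <- match.arg(leak)
  if (!length(traces)) stop("protocol error: empty trace set", call. = FALSE)
  v_cmd <- vapply(traces, function(tr) tr$step_amplitude, numeric(1))
  if (any(!is.finite(v_cmd))) {
    stop("protocol error: missing command voltages", call. = FALSE)
  }
  if (length(v_cmd) > 1L && any(diff(v_cmd) <= 0)) {
    stop("protocol error: command voltages must be strictly increasing",
         call. = FALSE)
  }
  one <- function(tr) {
    w <- tr$step_window
    bw <- tr$baseline_window %||% c(max(0, w[1] - 0.01), w[1])
    bidx <- window_idx(tr, bw)
    bidx <- bidx[trace_time(tr)[bidx] < w[1] - tr$sampling_interval / 2]
    if (!length(bidx)) bidx <- 1L
    baseline <- mean(tr$samples[bidx])
    i <- tr$samples - baseline
    early <- window_idx(tr, c(w[1], min(w[2], w[1] + early_window_s)))
    ss <- window_idx(tr, c(w[2] - 0.1 * (w[2] - w[1]), w[2]))
    c(peak = min(i[early]), ss = mean(i[ss]))
  }
  m <- vapply(traces, one, numeric(2))
  peak <- m["peak", ]; ss <- m["ss", ]
  if (leak == "linear" && length(v_cmd) >= 2L) {
    g <- (ss[2] - ss[1]) / (v_cmd[2] - v_cmd[1])
    lk <- ss[1] + g * (v_cmd - v_cmd[1])
    peak <- peak - lk
    ss <- ss - lk
  }
  structure(list(command_voltages = v_cmd, peak_inward = unname(peak),
                 steady_state = unname(ss)),
            class = "iv_curve")
}
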