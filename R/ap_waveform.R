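# Analytic action-potential waveform generator: a voltage trace built by
# integrating a designed dV/dt profile, so that phase-plane ground truth
# (threshold, IS/SD component amplitudes, after-potential shape) is known by
# construction. Used by the cohort generator for per-cell waveform metrics;
# the two-compartment model (simulate_two_compartment) provides the
# mechanistic counterpart.

#' Simulate a single action potential with prescribed phase-plane structure
#'
#' The rising phase is one (monophasic) or two (biphasic) Gaussian dV/dt
#' bumps whose amplitudes equal the initial-segment (IS) and somatodendritic
#' (SD) components; bump widths are set so the upstroke spans
#' `threshold -> peak_mV`. A sub-criterion depolarizing ramp (max 12 V/s)
#' brings the membrane from rest to threshold, so the 20 V/s criterion
#' crosses at the prescribed threshold (to within a fraction of a mV).
#' After-potentials are mono-phasic (single slow AHP) or tri-phasic
#' (fast AHP, ADP, slow AHP), with amplitudes in mV relative to threshold;
#' the trace then relaxes exponentially back to rest.
#'
#' @param erest Resting potential, mV.
#' @param threshold AP threshold, mV (> `erest`).
#' @param is_vps IS component (first rising-phase dV/dt maximum), V/s.
#' @param sd_vps SD component (absolute rising-phase maximum), V/s;
#'   `NULL` for a monophasic AP.
#' @param peak_mV AP peak, mV.
#' @param min_dvdt_vps Repolarization dV/dt minimum, V/s (negative);
#'   defaults to -45% of the largest rising component.
#' @param ahp_shape `"mono"` or `"tri"`.
#' @param ahp_slow Slow/mono AHP amplitude rel. threshold, mV (negative;
#'   its magnitude must exceed `threshold - erest` so the AHP undershoots
#'   rest). Defaults to `-(depol + 4)`.
#' @param ahp_fast,adp Tri-phasic fast AHP and ADP amplitudes rel.
#'   threshold, mV.
#' @param is_fraction Fraction of the upstroke voltage carried by the IS
#'   bump in biphasic APs.
#' @param dt_ms Sampling interval, ms (default 0.005 = 200 kHz; AP upstrokes
#'   need this resolution for faithful dV/dt).
#' @param baseline_ms Pre-AP baseline at rest, ms.
#' @param total_ms Total duration, ms.
#' @param noise_sd Additive voltage noise, mV.
#' @param seed Integer seed.
#' @return A voltage [trace()]; `meta$truth` holds all prescribed values.
#' @export
simulate_ap_waveform <- function(erest = -70, threshold = -54,
                                 is_vps = 150, sd_vps = NULL, peak_mV = 30,
                                 min_dvdt_vps = NULL,
                                 ahp_shape = c("mono", "tri"),
                                 ahp_slow = NULL, ahp_fast = NULL,
                                 adp = NULL, is_fraction = 0.35,
                                 dt_ms = 0.005, baseline_ms = 20,
                                 total_ms = 150, noise_sd = 0, seed = NULL) {
  ahp_shape <- match.arg(ahp_shape)
  depol <- threshold - erest
  if (depol <= 0) stop("threshold must be above erest", call. = FALSE)
  if (is_vps <= 20) stop("is_vps must exceed the 20 V/s criterion",
                         call. = FALSE)
  if (is.null(ahp_slow)) ahp_slow <- -(depol + 4)
  if (-ahp_slow <= depol) {
    stop("|ahp_slow| must exceed the rest-to-threshold depolarization",
         call. = FALSE)
  }
  if (ahp_shape == "tri") {
    if (is.null(ahp_fast)) ahp_fast <- -0.5 * depol
    if (is.null(adp)) adp <- -0.2 * depol
    if (!(ahp_fast < adp && adp < 0)) {
      stop("tri-phasic shape needs ahp_fast < adp < 0", call. = FALSE)
    }
  }
  tt <- seq(0, total_ms, by = dt_ms)
  d <- numeric(length(tt))          # dV/dt in V/s (= mV/ms)

  # approach ramp: 0 -> 12 V/s, area = depol
  ramp_ms <- depol / 6
  t_thr <- baseline_ms + ramp_ms
  in_ramp <- tt >= baseline_ms & tt < t_thr
  d[in_ramp] <- 12 * (tt[in_ramp] - baseline_ms) / ramp_ms

  gauss <- function(amp, center, sigma) amp * exp(-(tt - center)^2 /
                                                    (2 * sigma^2))
  rise <- peak_mV - threshold
  if (is.null(sd_vps)) {
    s1 <- rise / (is_vps * sqrt(2 * pi))
    t1 <- t_thr + 4 * s1
    d <- d + gauss(is_vps, t1, s1)
    t_rise_end <- t1 + 4 * s1
    max_rise <- is_vps
  } else {
    if (sd_vps < is_vps) stop("sd_vps must be >= is_vps", call. = FALSE)
    s1 <- is_fraction * rise / (is_vps * sqrt(2 * pi))
    s2 <- (1 - is_fraction) * rise / (sd_vps * sqrt(2 * pi))
    t1 <- t_thr + 4 * s1
    t2 <- t1 + 4 * (s1 + s2)
    d <- d + gauss(is_vps, t1, s1) + gauss(sd_vps, t2, s2)
    t_rise_end <- t2 + 4 * s2
    max_rise <- sd_vps
  }
  if (is.null(min_dvdt_vps)) min_dvdt_vps <- -0.45 * max_rise
  first_after <- if (ahp_shape == "tri") ahp_fast else ahp_slow
  drop <- rise - first_after                      # mV from peak down
  s3 <- drop / (abs(min_dvdt_vps) * sqrt(2 * pi))
  t3 <- t_rise_end + 4 * s3
  d <- d + gauss(min_dvdt_vps, t3, s3)
  t_last <- t3 + 4 * s3
  if (ahp_shape == "tri") {
    s4 <- 3; s5 <- 8
    t4 <- t_last + 2 * s4
    a4 <- (adp - ahp_fast) / (s4 * sqrt(2 * pi))
    t5 <- t4 + 3 * (s4 + s5)
    a5 <- (ahp_slow - adp) / (s5 * sqrt(2 * pi))
    d <- d + gauss(a4, t4, s4) + gauss(a5, t5, s5)
    t_last <- t5 + 3 * s5
  }
  v <- erest + cumsum(d) * dt_ms
  # exponential tail back to rest (the AHP undershoots rest, so the last
  # extremum stays a genuine local minimum)
  tail_idx <- which(tt > t_last)
  if (length(tail_idx)) {
    v0 <- v[tail_idx[1] - 1L]
    v[tail_idx] <- erest + (v0 - erest) *
      exp(-(tt[tail_idx] - t_last) / 25)
  }
  if (noise_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(v), sd = noise_sd))
  }
  trace(samples = v, sampling_interval = dt_ms * 1e-3,
        signal_kind = "voltage",
        baseline_window = c(0, baseline_ms * 1e-3),
        step_window = c(baseline_ms * 1e-3, total_ms * 1e-3),
        step_amplitude = NA_real_, holding_level = 0,
        meta = list(truth = list(erest = erest, threshold = threshold,
                                 is_vps = is_vps, sd_vps = sd_vps,
                                 peak_mV = peak_mV,
                                 min_dvdt_vps = min_dvdt_vps,
                                 ahp_shape = ahp_shape,
                                 ahp_slow = ahp_slow,
                                 ahp_fast = if (ahp_shape == "tri") ahp_fast,
                                 adp = if (ahp_shape == "tri") adp)))
}
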