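# Synthetic-data generators. Every generator embeds its ground truth in the
# returned object's `meta$truth`, so recovery tests never have to re-derive
# truth from the signal itself, and takes one explicit `seed` argument with
# no reliance on global RNG state.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' RC-circuit parameters for a seal test
#'
#' Equivalent circuit of the whole-cell membrane test: pipette series
#' resistance `Rs` in series with the parallel pair of membrane resistance
#' `Rm` and membrane capacitance `Cm_true`.
#'
#' @param Rs Series resistance, MOhm.
#' @param Rm Membrane resistance, MOhm.
#' @param Cm_true Membrane capacitance, pF.
#' @return A list of class `"rc_circuit_params"`.
#' @export
rc_circuit_params <- function(Rs, Rm, Cm_true) {
  if (any(c(Rs, Rm, Cm_true) <= 0)) {
    stop("parameter error: Rs, Rm and Cm_true must all be > 0", call. = FALSE)
  }
  if (Rm <= Rs) {
    warning("Rm <= Rs: membrane test operates outside its usual regime")
  }
  structure(list(Rs = Rs, Rm = Rm, Cm_true = Cm_true),
            class = "rc_circuit_params")
}

#' Simulate a voltage-clamp seal-test current transient
#'
#' Closed-form response of the series-RC circuit to a voltage step `step_mV`
#' (default -5 mV) applied at `t_on`: an instantaneous capacitive peak
#' `V/Rs` relaxing with time constant `tau = Cm * Rs*Rm/(Rs+Rm)` to the
#' steady-state leak `V/(Rs+Rm)`. The first sample of the step falls exactly
#' at `t_on` and carries the unfiltered peak. Gaussian current noise of
#' standard deviation `noise_sd` pA is added on top.
#'
#' @param params [rc_circuit_params()].
#' @param step_mV Command step amplitude in mV.
#' @param duration Total trace duration, s.
#' @param sampling_interval Sampling interval, s. The default (2 us) resolves
#'   time constants down to tens of microseconds.
#' @param t_on Step onset, s. Baseline occupies `[0, t_on)`.
#' @param noise_sd Additive current noise, pA.
#' @param seed Integer seed; the only source of randomness.
#' @return A current [trace()] with ground truth in `meta$truth`
#'   (`Rs`, `Rm`, `Cm_true`, `tau_ms`, `Imax_pA`, `Imem_pA`).
#' @export
simulate_seal_test <- function(params, step_mV = -5, duration = 0.06,
                               sampling_interval = 2e-6, t_on = 0.01,
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "rc_circuit_params"))
  Rs <- params$Rs; Rm <- params$Rm; Cm <- params$Cm_true
  tau_s <- Cm * (Rs * Rm / (Rs + Rm)) * 1e-6   # pF * MOhm = us
  # mV / MOhm = nA; work in pA
  i_ss <- 1000 * step_mV / (Rs + Rm)
  i_peak <- 1000 * step_mV / Rs
  short <- (duration - t_on) < 5 * tau_s
  if (short) warning("step shorter than 5*tau: steady state not reached")
  tt <- seq(0, duration - sampling_interval / 2, by = sampling_interval)
  i <- numeric(length(tt))
  on <- tt >= t_on - sampling_interval / 2
  if (tau_s < 0.01 * sampling_interval) {
    # capacitor effectively removed: the transient is unresolvable at this
    # sampling and the response is an instantaneous step to the leak level
    i[on] <- i_ss
  } else {
    i[on] <- i_ss + (i_peak - i_ss) * exp(-(tt[on] - t_on) / tau_s)
  }
  if (noise_sd > 0) {
    i <- i + with_seed(seed, stats::rnorm(length(i), sd = noise_sd))
  }
  trace(samples = i, sampling_interval = sampling_interval,
        signal_kind = "current",
        baseline_window = c(max(0, t_on - 0.01), t_on),
        step_window = c(t_on, duration),
        step_amplitude = step_mV, holding_level = 0,
        meta = list(truth = list(Rs = Rs, Rm = Rm, Cm_true = Cm,
                                 tau_ms = tau_s * 1e3, Imax_pA = i_peak,
                                 Imem_pA = i_ss,
                                 duration_short = short)))
}

# Stereotyped spike pasted into LIF traces: linear rise to +30 mV in 1 ms,
# linear fall back to the reset level in 2 ms. The LIF is used for
# rheobase/f-I logic only, never for waveform kinetics.
lif_spike_ms <- c(rise = 1, fall = 2)

#' Simulate a current-clamp step protocol with a leaky integrate-and-fire cell
#'
#' Subthreshold dynamics follow the closed form
#' `V(t) = Erest + I*Rin*(1 - exp(-t/tau))` (I in pA, Rin in MOhm, V in mV).
#' Whenever the membrane crosses `Erest + threshold_depol`, a stereotyped
#' action potential (1 ms linear rise to +30 mV, 2 ms fall) is pasted and the
#' membrane resets to `Erest`. The continuous-current rheobase
#' `I* = threshold_depol / (Rin * (1 - exp(-T/tau)))` is stored as ground
#' truth along with the pasted spike times per step.
#'
#' @param Rin Input resistance, MOhm.
#' @param tau_m Membrane time constant, ms.
#' @param Erest Resting potential, mV.
#' @param threshold_depol Depolarization from rest needed to fire, mV.
#' @param amplitudes Injected step amplitudes, pA, strictly increasing.
#' @param step_duration Step length, s (default 0.5).
#' @param sampling_interval Sampling interval, s (default 1e-4, i.e. 10 kHz).
#' @param t_on Step onset, s; the pre-step baseline sits at `Erest`.
#' @param noise_sd Additive voltage noise, mV.
#' @param seed Integer seed.
#' @return A [step_protocol_set()] with `meta$truth$rheobase_pA` and
#'   per-step true spike times.
#' @export
simulate_lif_steps <- function(Rin, tau_m, Erest = -70, threshold_depol = 16,
                               amplitudes = seq(5, 250, by = 5),
                               step_duration = 0.5, sampling_interval = 1e-4,
                               t_on = 0.1, noise_sd = 0, seed = NULL) {
  if (tau_m <= 0 || Rin <= 0) {
    stop("parameter error: Rin and tau_m must be > 0", call. = FALSE)
  }
  if (threshold_depol <= 0) {
    stop("parameter error: threshold_depol must be > 0", call. = FALSE)
  }
  tau_s <- tau_m * 1e-3
  thr <- Erest + threshold_depol
  t_off <- t_on + step_duration
  duration <- t_off + 0.05
  tt <- seq(0, duration - sampling_interval / 2, by = sampling_interval)
  rise_s <- lif_spike_ms[["rise"]] * 1e-3
  fall_s <- lif_spike_ms[["fall"]] * 1e-3

  sim_one <- function(I) {
    v <- rep(Erest, length(tt))
    target <- Erest + I * Rin / 1000
    spike_times <- numeric(0)
    t0 <- t_on; v0 <- Erest
    paste_end <- t_on
    while (t0 < t_off) {
      seg <- tt >= t0 - 1e-12 & tt < t_off
      if (target > thr && v0 < thr) {
        t_cross <- t0 + tau_s * log((target - v0) / (target - thr))
      } else {
        t_cross <- Inf
      }
      seg_end <- min(t_cross, t_off)
      in_seg <- seg & tt < seg_end
      v[in_seg] <- target + (v0 - target) * exp(-(tt[in_seg] - t0) / tau_s)
      if (!is.finite(t_cross) || t_cross >= t_off) break
      spike_times <- c(spike_times, t_cross)
      # paste the stereotyped AP
      ap <- tt >= t_cross & tt < t_cross + rise_s
      v[ap] <- thr + (30 - thr) * (tt[ap] - t_cross) / rise_s
      fa <- tt >= t_cross + rise_s & tt < t_cross + rise_s + fall_s
      v[fa] <- 30 + (Erest - 30) * (tt[fa] - t_cross - rise_s) / fall_s
      t0 <- t_cross + rise_s + fall_s
      paste_end <- t0
      v0 <- Erest
    }
    # relaxation back to rest; a spike initiated just before step offset is
    # allowed to complete first
    t_relax <- max(t_off, paste_end)
    post <- tt >= t_relax
    pre_idx <- which(tt < t_relax)
    v_at_off <- if (length(pre_idx)) v[max(pre_idx)] else Erest
    v[post] <- Erest + (v_at_off - Erest) * exp(-(tt[post] - t_relax) / tau_s)
    list(v = v, spike_times = spike_times)
  }

  sims <- lapply(amplitudes, sim_one)
  noise <- if (noise_sd > 0) {
    with_seed(seed, lapply(seq_along(sims), function(i)
      stats::rnorm(length(tt), sd = noise_sd)))
  }
  traces <- lapply(seq_along(sims), function(i) {
    v <- sims[[i]]$v
    if (!is.null(noise)) v <- v + noise[[i]]
    trace(samples = v, sampling_interval = sampling_interval,
          signal_kind = "voltage",
          baseline_window = c(0, t_on), step_window = c(t_on, t_off),
          step_amplitude = amplitudes[i], holding_level = 0,
          meta = list(truth = list(spike_times = sims[[i]]$spike_times)))
  })
  rheo <- threshold_depol * 1000 /
    (Rin * (1 - exp(-step_duration / tau_s)))
  step_protocol_set(
    traces, amplitudes, step_duration = step_duration,
    meta = list(truth = list(Rin = Rin, tau_m = tau_m, Erest = Erest,
                             threshold_depol = threshold_depol,
                             rheobase_pA = rheo)))
}

#' Two-compartment conductance-based model parameters
#'
#' Minimal soma + axon-initial-segment model that reproduces the biphasic
#' rising phase of somatically recorded action potentials: a small,
#' sodium-dense AIS compartment coupled to the soma through an axial
#' conductance. Sodium activation is instantaneous (`m_inf^3`), inactivation
#' `h` and potassium activation `n` are first-order. AIS sodium activation
#' is shifted by `ais_na_shift` mV (hyperpolarized, as for Nav1.6 at the
#' AIS).
#'
#' @param C_soma,C_ais Compartment capacitances, pF.
#' @param g_leak_soma,g_leak_ais Leak conductances, nS.
#' @param E_leak Leak reversal, mV.
#' @param g_axial Axial (coupling) conductance, nS.
#' @param gNa_soma,gNa_ais,gK_soma,gK_ais Maximal conductances, nS.
#' @param E_Na,E_K Reversal potentials, mV.
#' @param na_half,na_slope Na activation half-voltage and slope, mV.
#' @param h_half,h_slope Na inactivation half-voltage and slope, mV.
#' @param tau_h Na inactivation time constant, ms.
#' @param n_half,n_slope K activation half-voltage and slope, mV.
#' @param tau_n K activation time constant, ms.
#' @param ais_na_shift Voltage shift of AIS Na gating, mV (negative =
#'   hyperpolarized activation).
#' @param v_init Initial voltage of both compartments, mV.
#' @return A list of class `"two_compartment_params"`.
#' @export
two_compartment_params <- function(C_soma = 150, C_ais = 5,
                                   g_leak_soma = 10, g_leak_ais = 1,
                                   E_leak = -75, g_axial = 80,
                                   gNa_soma = 500, gNa_ais = 600,
                                   gK_soma = 250, gK_ais = 150,
                                   E_Na = 55, E_K = -90,
                                   na_half = -25, na_slope = 5,
                                   h_half = -35, h_slope = 6, tau_h = 2.5,
                                   n_half = -10, n_slope = 6, tau_n = 1.5,
                                   ais_na_shift = -18, v_init = -72) {
  p <- as.list(environment())
  caps <- c(p$C_soma, p$C_ais)
  gs <- c(p$g_leak_soma, p$g_leak_ais, p$gNa_soma, p$gNa_ais,
          p$gK_soma, p$gK_ais)
  if (any(caps <= 0) || any(gs < 0)) {
    stop("parameter error: capacitances must be > 0, conductances >= 0",
         call. = FALSE)
  }
  if (p$g_axial <= 0) stop("parameter error: g_axial must be > 0",
                           call. = FALSE)
  if (p$na_slope == 0 || p$h_slope == 0 || p$n_slope == 0) {
    stop("parameter error: kinetics slopes must be nonzero", call. = FALSE)
  }
  structure(p, class = "two_compartment_params")
}

logistic <- function(v, half, slope) 1 / (1 + exp(-(v - half) / slope))

two_comp_deriv <- function(t, y, p, I_of_t) {
  vs <- y[1]; va <- y[2]; hs <- y[3]; ha <- y[4]; ns <- y[5]; na <- y[6]
  m_s <- logistic(vs, p$na_half, p$na_slope)
  m_a <- logistic(va, p$na_half + p$ais_na_shift, p$na_slope)
  ina_s <- p$gNa_soma * m_s^3 * hs * (vs - p$E_Na)
  ina_a <- p$gNa_ais * m_a^3 * ha * (va - p$E_Na)
  ik_s <- p$gK_soma * ns * (vs - p$E_K)
  ik_a <- p$gK_ais * na * (va - p$E_K)
  il_s <- p$g_leak_soma * (vs - p$E_leak)
  il_a <- p$g_leak_ais * (va - p$E_leak)
  iax <- p$g_axial * (va - vs)                      # into soma
  # nS * mV = pA; pA / pF = V/s = mV/ms
  dvs <- (-ina_s - ik_s - il_s + iax + I_of_t(t)) / p$C_soma
  dva <- (-ina_a - ik_a - il_a - iax) / p$C_ais
  h_inf_s <- 1 - logistic(vs, p$h_half, p$h_slope)
  h_inf_a <- 1 - logistic(va, p$h_half, p$h_slope)
  n_inf_s <- logistic(vs, p$n_half, p$n_slope)
  n_inf_a <- logistic(va, p$n_half, p$n_slope)
  list(c(dvs, dva,
         (h_inf_s - hs) / p$tau_h, (h_inf_a - ha) / p$tau_h,
         (n_inf_s - ns) / p$tau_n, (n_inf_a - na) / p$tau_n))
}

#' Simulate current-clamp steps with the two-compartment model
#'
#' Deterministic fixed-step RK4 integration (via \pkg{deSolve}) of the
#' soma + AIS model; the somatic voltage is returned as one [trace()] per
#' injected amplitude. With dense AIS sodium (`gNa_ais >> gNa_soma`) the
#' somatic phase plot exhibits the two rising-phase dV/dt maxima seen in
#' mature pyramidal neurons; with `gNa_soma = 0` only the initial-segment
#' maximum remains.
#'
#' @param params [two_compartment_params()].
#' @param amplitudes Injected somatic current steps, pA, strictly increasing.
#' @param step_duration Step length, s.
#' @param dt Integration and sampling step, ms; must be <= 0.01.
#' @param t_on Step onset, s.
#' @param keep_states Store the full state trajectory (both voltages and
#'   gating variables) in each trace's `meta$states`, e.g. for conservation
#'   checks.
#' @return A [step_protocol_set()] of somatic voltage traces; each trace's
#'   `meta` carries the AIS voltage for inspection.
#' @export
simulate_two_compartment <- function(params, amplitudes = 300,
                                     step_duration = 0.05, dt = 0.01,
                                     t_on = 0.01, keep_states = FALSE) {
  stopifnot(inherits(params, "two_compartment_params"))
  if (dt > 0.01 + 1e-12) {
    stop("stability error: dt must be <= 0.01 ms", call. = FALSE)
  }
  if (length(amplitudes) > 1L && any(diff(amplitudes) <= 0)) {
    stop("`amplitudes` must be strictly increasing", call. = FALSE)
  }
  t_on_ms <- t_on * 1e3
  t_off_ms <- t_on_ms + step_duration * 1e3
  t_end_ms <- t_off_ms + 10
  times <- seq(0, t_end_ms, by = dt)
  v0 <- params$v_init
  y0 <- c(vs = v0, va = v0,
          hs = 1 - logistic(v0, params$h_half, params$h_slope),
          ha = 1 - logistic(v0, params$h_half, params$h_slope),
          ns = logistic(v0, params$n_half, params$n_slope),
          na = logistic(v0, params$n_half, params$n_slope))
  traces <- lapply(amplitudes, function(amp) {
    I_of_t <- function(t) if (t >= t_on_ms && t < t_off_ms) amp else 0
    sol <- deSolve::rk4(y0, times, two_comp_deriv, params, I_of_t = I_of_t)
    vs <- sol[, "vs"]
    if (any(!is.finite(vs)) || max(abs(vs)) > 200) {
      stop(sprintf("stability error: |V| exceeded 200 mV at dt = %g ms", dt),
           call. = FALSE)
    }
    meta <- list(v_ais = sol[, "va"], dt_ms = dt)
    if (keep_states) meta$states <- sol
    trace(samples = vs, sampling_interval = dt * 1e-3,
          signal_kind = "voltage",
          baseline_window = c(0, t_on), step_window = c(t_on, t_on +
                                                          step_duration),
          step_amplitude = amp, holding_level = 0,
          meta = meta)
  })
  step_protocol_set(traces, amplitudes, step_duration = step_duration,
                    meta = list(truth = unclass(params)))
}

#' Ground-truth geometry for a synthetic AIS intensity profile
#'
#' @param start_um,end_um True proximal and distal AIS boundaries along the
#'   profile, um (`end > start >= 0`).
#' @param diameter_um True AIS diameter, um.
#' @param plateau_intensity,background_intensity Plateau and background
#'   levels, arbitrary units (`plateau > background >= 0`).
#' @param psf_sigma_um Gaussian point-spread-function sigma, um (0 = no blur).
#' @param pixel_size_um Sampling pitch along the profile, um.
#' @param noise_sd Additive Gaussian intensity noise (clipped at 0).
#' @return A list of class `"ais_geometry_truth"`.
#' @export
ais_geometry_truth <- function(start_um, end_um, diameter_um = 1.2,
                               plateau_intensity = 1, background_intensity = 0.05,
                               psf_sigma_um = 0.4, pixel_size_um = 0.2,
                               noise_sd = 0) {
  if (!(end_um > start_um && start_um >= 0)) {
    stop("geometry error: need end_um > start_um >= 0", call. = FALSE)
  }
  if (!(plateau_intensity > background_intensity &&
        background_intensity >= 0)) {
    stop("geometry error: need plateau > background >= 0", call. = FALSE)
  }
  if (pixel_size_um <= 0) stop("geometry error: pixel_size_um must be > 0",
                               call. = FALSE)
  structure(as.list(environment()), class = "ais_geometry_truth")
}

# Smoothed plateau edge: Phi((x - e)/sigma), with the sigma -> 0 limit
# H(x - e) taking value 1/2 exactly at the edge.
edge_cdf <- function(x, e, sigma) {
  if (sigma > 0) stats::pnorm((x - e) / sigma) else (x > e) + 0.5 * (x == e)
}

#' Generate a synthetic AIS fluorescence line profile
#'
#' Ideal plateau between the true boundaries, convolved with a Gaussian PSF
#' (error-function edges), sampled at pixel centers, plus additive Gaussian
#' noise clipped at zero:
#' `I(x) = bg + (plateau - bg) * (Phi((x-start)/sigma) - Phi((x-end)/sigma))`.
#'
#' @param truth [ais_geometry_truth()].
#' @param n_pixels Number of pixels; defaults to covering
#'   `end_um + 3*sigma + 2 um`.
#' @param seed Integer seed for the noise.
#' @return An object of class `"intensity_profile"` with fields `positions`
#'   (um, starting at 0), `intensities`, `pixel_size` and `meta$truth`.
#' @export
generate_ais_profile <- function(truth, n_pixels = NULL, seed = NULL) {
  stopifnot(inherits(truth, "ais_geometry_truth"))
  px <- truth$pixel_size_um
  sigma <- truth$psf_sigma_um
  if (is.null(n_pixels)) {
    n_pixels <- ceiling((truth$end_um + 3 * sigma + 2) / px) + 1L
  }
  x <- (seq_len(n_pixels) - 1L) * px
  if (truth$start_um - 3 * sigma < -px / 2 ||
      x[n_pixels] < truth$end_um + 3 * sigma) {
    stop("geometry error: profile span does not cover [start-3sigma, end+3sigma]",
         call. = FALSE)
  }
  shape <- edge_cdf(x, truth$start_um, sigma) - edge_cdf(x, truth$end_um, sigma)
  y <- truth$background_intensity +
    (truth$plateau_intensity - truth$background_intensity) * shape
  if (truth$noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(n_pixels, sd = truth$noise_sd))
    y <- pmax(y, 0)
  }
  intensity_profile(positions = x, intensities = y, pixel_size = px,
                    meta = list(truth = unclass(truth)))
}

#' Render a synthetic 2-D image containing one straight AIS
#'
#' Horizontal AIS centered on row `y0_px`; the longitudinal intensity profile
#' follows the same edge model as [generate_ais_profile()] and the
#' cross-section is Gaussian with full width at half maximum equal to the
#' true diameter.
#'
#' @param truth [ais_geometry_truth()].
#' @param nrow_px,ncol_px Image size in pixels; `ncol_px` defaults to the
#'   span used by [generate_ais_profile()].
#' @param y0_px Row (1-based, can be fractional) of the AIS axis.
#' @param seed Integer seed for pixel noise.
#' @return A numeric matrix (rows y, columns x) with attributes
#'   `pixel_size_um` and `truth`.
#' @export
generate_ais_image <- function(truth, nrow_px = 41, ncol_px = NULL,
                               y0_px = 21, seed = NULL) {
  stopifnot(inherits(truth, "ais_geometry_truth"))
  px <- truth$pixel_size_um
  if (is.null(ncol_px)) {
    ncol_px <- ceiling((truth$end_um + 3 * truth$psf_sigma_um + 2) / px) + 1L
  }
  x <- (seq_len(ncol_px) - 1L) * px
  shape <- edge_cdf(x, truth$start_um, truth$psf_sigma_um) -
    edge_cdf(x, truth$end_um, truth$psf_sigma_um)
  sigma_y_px <- truth$diameter_um / (2 * sqrt(2 * log(2))) / px
  yrel <- (seq_len(nrow_px) - y0_px)
  cross <- exp(-yrel^2 / (2 * sigma_y_px^2))
  img <- truth$background_intensity +
    (truth$plateau_intensity - truth$background_intensity) *
    outer(cross, shape)
  if (truth$noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img),
                                                     sd = truth$noise_sd),
                                        nrow = nrow_px))
    img <- pmax(img, 0)
  }
  attr(img, "pixel_size_um") <- px
  attr(img, "truth") <- unclass(truth)
  img
}
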