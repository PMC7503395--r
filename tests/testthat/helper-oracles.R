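# Independent closed-form oracles used across the suite. These are written
# against the physics, not against the implementation paths they check.

# Series-RC membrane test: exact current response to a voltage step.
rc_oracle <- function(Rs, Rm, Cm, step_mV = -5) {
  tau_ms <- Cm * (Rs * Rm / (Rs + Rm)) * 1e-3   # pF*MOhm = us
  list(i_peak = 1000 * step_mV / Rs,
       i_ss = 1000 * step_mV / (Rs + Rm),
       tau_ms = tau_ms,
       rin = Rs + Rm,
       cm_biased = Cm * Rm / (Rs + Rm))
}

# Continuous-current rheobase of a leaky integrator for a finite step.
lif_rheobase_oracle <- function(Rin, tau_m_ms, threshold_depol,
                                step_duration_s = 0.5) {
  threshold_depol * 1000 / (Rin * (1 - exp(-step_duration_s /
                                             (tau_m_ms * 1e-3))))
}

# Expected measured AIS length for a plateau [start, end] blurred with a
# Gaussian PSF, thresholded at fraction f of the (background-subtracted)
# plateau: each boundary moves outward by sigma * |qnorm(f)|.
erf_length_oracle <- function(start, end, sigma, f) {
  (end - start) + 2 * sigma * abs(stats::qnorm(f))
}

# Build a minimal phase_plot object from paired (voltage, dvdt) arrays.
fake_phase_plot <- function(voltage, dvdt, peak_idx = length(voltage),
                            dt = 1e-5) {
  structure(list(voltage = voltage, dvdt = dvdt,
                 time = seq_along(voltage) * dt, peak_idx = peak_idx,
                 dt = dt),
            class = "phase_plot")
}

# Voltage trace with a triangular spike and a designed after-potential,
# assembled sample by sample (10 kHz).
fake_ap_trace <- function(after_rel, threshold = -54, erest = -70,
                          dt = 1e-4) {
  # rise erest -> +30 over 1 ms, fall +30 -> threshold over 1 ms,
  # then the supplied after-potential course (mV relative to threshold)
  rise <- seq(erest, 30, length.out = 11)[-1]
  fall <- seq(30, threshold, length.out = 11)[-1]
  v <- c(rep(erest, 50), rise, fall, threshold + after_rel)
  trace(v, sampling_interval = dt, signal_kind = "voltage",
        baseline_window = c(0, 50 * dt))
}
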