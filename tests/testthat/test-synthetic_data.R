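test_that("seal-test simulator matches the RC closed form", {
  orc <- rc_oracle(10, 190, 100)
  tr <- simulate_seal_test(rc_circuit_params(10, 190, 100))
  i_on <- tr$samples[window_start <- which(trace_time(tr) >=
                                             tr$step_window[1])[1]]
  expect_equal(i_on, -500, tolerance = 1e-12)        # peak V/Rs
  expect_equal(orc$i_peak, -500)
  n <- length(tr$samples)
  expect_equal(mean(tr$samples[(n - 100):n]), -25, tolerance = 1e-6)
  expect_equal(tr$meta$truth$tau_ms, 0.95, tolerance = 1e-12)
})

test_that("removing the capacitor removes the transient", {
  tr <- simulate_seal_test(rc_circuit_params(10, 190, 1e-9))
  on <- trace_time(tr) >= tr$step_window[1]
  expect_lt(diff(range(tr$samples[on])), 1e-6)
  expect_equal(tr$samples[on][1], -25, tolerance = 1e-6)
})

test_that("generators are deterministic under a fixed seed", {
  p <- rc_circuit_params(8, 300, 150)
  a <- simulate_seal_test(p, noise_sd = 5, seed = 11)
  b <- simulate_seal_test(p, noise_sd = 5, seed = 11)
  expect_identical(a$samples, b$samples)
  c <- simulate_seal_test(p, noise_sd = 5, seed = 12)
  expect_false(identical(a$samples, c$samples))

  pr1 <- generate_ais_profile(ais_geometry_truth(4, 12, noise_sd = 0.05),
                              seed = 3)
  pr2 <- generate_ais_profile(ais_geometry_truth(4, 12, noise_sd = 0.05),
                              seed = 3)
  expect_identical(pr1$intensities, pr2$intensities)
})

test_that("LIF ground-truth rheobase follows the closed form", {
  s <- simulate_lif_steps(Rin = 200, tau_m = 20, Erest = -70,
                          threshold_depol = 16)
  expect_equal(s$meta$truth$rheobase_pA,
               lif_rheobase_oracle(200, 20, 16), tolerance = 1e-12)
  expect_equal(s$meta$truth$rheobase_pA, 80, tolerance = 1e-6)
  # doubling Rin halves the continuous rheobase
  s2 <- simulate_lif_steps(Rin = 400, tau_m = 20, Erest = -70,
                           threshold_depol = 16)
  expect_equal(s2$meta$truth$rheobase_pA, s$meta$truth$rheobase_pA / 2,
               tolerance = 1e-12)
})

test_that("LIF subthreshold response matches the closed form", {
  s <- simulate_lif_steps(Rin = 250, tau_m = 15, Erest = -68,
                          threshold_depol = 16, amplitudes = c(-20, 20),
                          sampling_interval = 1e-5)
  for (k in 1:2) {
    tr <- s$traces[[k]]
    I <- s$injected_amplitudes[k]
    tt <- trace_time(tr)
    on <- tt >= tr$step_window[1] & tt < tr$step_window[2]
    expected <- -68 + I * 250 / 1000 *
      (1 - exp(-(tt[on] - tr$step_window[1]) / 15e-3))
    expect_equal(tr$samples[on], expected, tolerance = 1e-6)
    expect_length(tr$meta$truth$spike_times, 0)
  }
  # zero current: flat at rest
  s0 <- simulate_lif_steps(Rin = 250, tau_m = 15, Erest = -68,
                           threshold_depol = 16, amplitudes = 0)
  expect_equal(range(s0$traces[[1]]$samples), c(-68, -68))
})

test_that("two-compartment model: biphasic by default, monophasic without somatic Na", {
  s <- simulate_two_compartment(two_compartment_params(), amplitudes = 400,
                                step_duration = 0.04)
  tr <- s$traces[[1]]
  pp <- phase_plot(tr, which.max(tr$samples), window_ms = c(3, 6))
  issd <- is_sd_components(pp)
  expect_true(issd$biphasic)
  expect_lt(issd$is_peak, issd$sd_peak)

  s0 <- simulate_two_compartment(two_compartment_params(gNa_soma = 0),
                                 amplitudes = 400, step_duration = 0.04)
  tr0 <- s0$traces[[1]]
  pp0 <- phase_plot(tr0, which.max(tr0$samples), window_ms = c(3, 6))
  issd0 <- is_sd_components(pp0)
  expect_false(issd0$biphasic)
  expect_true(is.na(issd0$sd_peak))
})

test_that("two-compartment integration is converged at the default step", {
  p <- two_compartment_params()
  f <- function(dt) {
    s <- simulate_two_compartment(p, amplitudes = 400,
                                  step_duration = 0.04, dt = dt)
    tr <- s$traces[[1]]
    max(phase_plot(tr, which.max(tr$samples), window_ms = c(3, 6))$dvdt)
  }
  expect_equal(f(0.01), f(0.005), tolerance = 0.01)
  expect_error(simulate_two_compartment(p, dt = 0.05), "dt must be")
})

test_that("two-compartment integration conserves charge per compartment", {
  # conservation holds in the dt -> 0 limit; 1 us steps resolve the fast
  # AIS spike well enough for the trapezoidal charge integral
  p <- two_compartment_params()
  s <- simulate_two_compartment(p, amplitudes = 400, step_duration = 0.04,
                                dt = 0.001, keep_states = TRUE)
  sol <- s$traces[[1]]$meta$states
  tt <- sol[, "time"]
  t_on_ms <- 10; t_off_ms <- 50
  i_inj <- ifelse(tt >= t_on_ms & tt < t_off_ms, 400, 0)
  m_s <- 1 / (1 + exp(-(sol[, "vs"] - p$na_half) / p$na_slope))
  m_a <- 1 / (1 + exp(-(sol[, "va"] - p$na_half - p$ais_na_shift) /
                        p$na_slope))
  i_soma <- -p$gNa_soma * m_s^3 * sol[, "hs"] * (sol[, "vs"] - p$E_Na) -
    p$gK_soma * sol[, "ns"] * (sol[, "vs"] - p$E_K) -
    p$g_leak_soma * (sol[, "vs"] - p$E_leak) +
    p$g_axial * (sol[, "va"] - sol[, "vs"]) + i_inj
  i_ais <- -p$gNa_ais * m_a^3 * sol[, "ha"] * (sol[, "va"] - p$E_Na) -
    p$gK_ais * sol[, "na"] * (sol[, "va"] - p$E_K) -
    p$g_leak_ais * (sol[, "va"] - p$E_leak) -
    p$g_axial * (sol[, "va"] - sol[, "vs"])
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2) * diff(tt)[1]
  dq_soma <- p$C_soma * (sol[nrow(sol), "vs"] - sol[1, "vs"])
  dq_ais <- p$C_ais * (sol[nrow(sol), "va"] - sol[1, "va"])
  scale_soma <- trapz(abs(i_soma))
  scale_ais <- trapz(abs(i_ais))
  expect_lt(abs(trapz(i_soma) - dq_soma) / scale_soma, 0.001)
  expect_lt(abs(trapz(i_ais) - dq_ais) / scale_ais, 0.001)
})

test_that("AIS profile generator realizes the edge model", {
  # sharp edges: plateau exactly between the true boundaries
  tr0 <- ais_geometry_truth(4, 12, psf_sigma_um = 0, pixel_size_um = 0.2,
                            plateau_intensity = 1,
                            background_intensity = 0.05, noise_sd = 0)
  pr <- generate_ais_profile(tr0)
  inside <- pr$positions > 4.05 & pr$positions < 11.95
  outside <- pr$positions < 3.95 | pr$positions > 12.05
  expect_true(all(pr$intensities[inside] == 1))
  expect_true(all(pr$intensities[outside] == 0.05))

  # blurred edge equals the error-function profile
  trb <- ais_geometry_truth(4, 12, psf_sigma_um = 0.4, pixel_size_um = 0.2,
                            noise_sd = 0)
  prb <- generate_ais_profile(trb)
  x <- prb$positions
  expected <- 0.05 + 0.95 * (pnorm((x - 4) / 0.4) - pnorm((x - 12) / 0.4))
  expect_equal(prb$intensities, expected, tolerance = 1e-12)

  # span precondition
  expect_error(generate_ais_profile(trb, n_pixels = 40), "geometry error")
})

test_that("synthetic AIS image has the prescribed cross-section", {
  tr <- ais_geometry_truth(4, 12, diameter_um = 1.2, psf_sigma_um = 0.2,
                           pixel_size_um = 0.2, background_intensity = 0,
                           noise_sd = 0)
  img <- generate_ais_image(tr, nrow_px = 41, y0_px = 21)
  col <- img[, which.min(abs((0:(ncol(img) - 1)) * 0.2 - 8))]
  # FWHM of the Gaussian cross-section equals the true diameter
  half <- max(col) / 2
  above <- which(col >= half)
  fwhm_px <- max(above) - min(above)
  expect_equal(fwhm_px * 0.2, 1.2, tolerance = 0.2)
})

test_that("cohort generation is counted, directional, and reproducible", {
  spec <- cohort_spec(list(
    age_group_spec("young", 2, 3, params = list(Cm_true = c(60, 10))),
    age_group_spec("adult", 2, 3, params = list(Cm_true = c(180, 20)))),
    seed = 5, signals = "ais")
  co <- generate_cohort(spec)
  expect_equal(nrow(co$manifest), 12)
  expect_length(co$cells, 12)
  means <- tapply(co$manifest$Cm_true, co$manifest$group, mean)
  expect_gt(means[["adult"]], means[["young"]])
  co2 <- generate_cohort(spec)
  expect_identical(co$manifest, co2$manifest)
})
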