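test_that("phase plot of a sine is an ellipse with dV/dt extrema A*omega", {
  A <- 50; f <- 100; dt <- 1e-5
  tt <- seq(0, 0.02, by = dt)
  v <- -A * cos(2 * pi * f * tt)     # voltage peak at 5 ms, mid-trace
  tr <- trace(v, dt, "voltage")
  pk <- which.max(v)
  pp <- phase_plot(tr, pk, window_ms = c(3, 3))
  ex <- slope_extrema(pp)
  expect_equal(ex$max_dvdt, A * 2 * pi * f / 1000, tolerance = 0.005)
  expect_equal(ex$min_dvdt, -A * 2 * pi * f / 1000, tolerance = 0.005)
  r <- (pp$voltage / A)^2 + (pp$dvdt / (A * 2 * pi * f / 1000))^2
  expect_true(all(abs(r - 1) < 0.01))
  # constant trace: all-zero derivative
  const <- trace(rep(-60, 1000), dt, "voltage")
  expect_true(all(phase_plot(const, 500, c(1, 1))$dvdt == 0))
  expect_error(phase_plot(const, 5, c(1, 1)), "boundary error")
})

test_that("threshold criterion crossing matches the exponential closed form", {
  # dV/dt = a (V - Vb) with a = 1/ms, Vb = -70: criterion 20 V/s crosses at
  # V = Vb + 20/a = -50 mV
  dt <- 1e-6
  tt <- seq(0, 9.5e-3, by = dt)
  v <- -70 + 0.01 * exp(tt * 1000)
  v <- pmin(v, 30)
  n_up <- sum(v < 30)
  v <- c(v[1:n_up], seq(30, -70, length.out = 200))
  tr <- trace(v, dt, "voltage")
  pp <- phase_plot(tr, n_up, window_ms = c(8, 0.1))
  expect_equal(ap_threshold(pp, 20), -50, tolerance = 0.1)
  # degenerate criterion 0: first positive slope
  expect_lt(ap_threshold(pp, 0), -69)
  # subthreshold trace: no crossing
  flat <- trace(seq(-70, -69, length.out = 2000), 1e-4, "voltage")
  expect_error(ap_threshold(phase_plot(flat, 1000, c(50, 50)), 20), "no-AP")
})

test_that("half-width matches Gaussian and triangular closed forms", {
  dt <- 1e-5
  thr <- -54; A <- 84; sigma <- 0.3e-3
  tt <- seq(0, 0.02, by = dt)
  v <- thr + A * exp(-(tt - 0.01)^2 / (2 * sigma^2))
  tr <- trace(v, dt, "voltage")
  hw <- ap_half_width(tr, thr, which.max(v))
  expect_equal(hw, 2 * sigma * sqrt(2 * log(2)) * 1e3, tolerance = dt * 1e3)

  # wider Gaussian: strictly wider
  v2 <- thr + A * exp(-(tt - 0.01)^2 / (2 * (2 * sigma)^2))
  hw2 <- ap_half_width(trace(v2, dt, "voltage"), thr, which.max(v2))
  expect_gt(hw2, hw)

  # triangle, 1 ms rise / 1 ms fall: half-width 1 ms
  vt <- c(rep(-70, 100), seq(-70, 30, length.out = 101)[-1],
          seq(30, -70, length.out = 101)[-1], rep(-70, 100))
  trt <- trace(vt, 1e-5, "voltage")
  expect_equal(ap_half_width(trt, -70, which.max(vt)), 1, tolerance = 0.01)

  # no repolarization to the half level
  vs <- c(rep(-70, 100), seq(-70, 30, length.out = 100),
          rep(20, 300))
  expect_error(ap_half_width(trace(vs, 1e-5, "voltage"), -70, 200),
               "shape error")
})

test_that("IS/SD decomposition identifies constructed rising-phase bumps", {
  v <- seq(-60, 30, length.out = 2001)
  d <- 1 + 80 * exp(-((v + 45) / 2.5)^2) + 300 * exp(-((v + 20) / 4)^2)
  pp <- fake_phase_plot(v, d)
  issd <- is_sd_components(pp, smooth = FALSE)
  expect_true(issd$biphasic)
  expect_equal(issd$is_peak, 81, tolerance = 0.02)
  expect_equal(issd$sd_peak, 301, tolerance = 0.02)
  expect_equal(issd$ratio, 81 / 301, tolerance = 0.01)
  expect_lt(abs(issd$is_voltage - -45), 1)
  expect_lt(abs(issd$sd_voltage - -20), 1)
})

test_that("raising the prominence cutoff can only merge components", {
  v <- seq(-60, 30, length.out = 2001)
  d <- 1 + 80 * exp(-((v + 45) / 2.5)^2) + 300 * exp(-((v + 20) / 4)^2)
  pp <- fake_phase_plot(v, d)
  bi <- vapply(c(10, 50, 200), function(mp) {
    is_sd_components(pp, min_prominence = mp, smooth = FALSE)$biphasic
  }, logical(1))
  expect_true(all(diff(as.integer(bi)) <= 0))
  expect_true(bi[1])
  expect_false(bi[3])
})

test_that("after-potential classification follows the extremum taxonomy", {
  mono <- fake_ap_trace(c(seq(0, -8, length.out = 200),
                          seq(-8, -0.5, length.out = 600)))
  prof <- ahp_adp_profile(mono, which.max(mono$samples), -54)
  expect_identical(prof$shape_class, "mono")
  expect_equal(prof$ahp_slow_mono, -8, tolerance = 0.05)
  expect_true(is.na(prof$ahp_fast))

  tri <- fake_ap_trace(c(seq(0, -6, length.out = 100),
                         seq(-6, -2, length.out = 100),
                         seq(-2, -9, length.out = 300),
                         seq(-9, -4, length.out = 300)))
  prof <- ahp_adp_profile(tri, which.max(tri$samples), -54)
  expect_identical(prof$shape_class, "tri")
  expect_equal(prof$ahp_fast, -6, tolerance = 0.05)
  expect_equal(prof$adp, -2, tolerance = 0.05)
  expect_equal(prof$ahp_slow_mono, -9, tolerance = 0.05)

  # a 0.3 mV rebound is below the 0.5 mV prominence rule: mono
  weak <- fake_ap_trace(c(seq(0, -6, length.out = 100),
                          seq(-6, -5.7, length.out = 60),
                          seq(-5.7, -9, length.out = 300),
                          seq(-9, -4, length.out = 300)))
  prof <- ahp_adp_profile(weak, which.max(weak$samples), -54)
  expect_identical(prof$shape_class, "mono")
  expect_equal(prof$ahp_slow_mono, -9, tolerance = 0.05)

  # truncation by the next spike is flagged
  tr <- fake_ap_trace(c(seq(0, -8, length.out = 200),
                        seq(-8, -0.5, length.out = 600)))
  pk <- which.max(tr$samples)
  prof <- ahp_adp_profile(tr, pk, -54, next_spike_index = pk + 25L)
  expect_true(prof$unresolved)
})

test_that("waveform metrics are invariant to time shift and track voltage offset", {
  dt <- 1e-5
  tt <- seq(0, 0.03, by = dt)
  mk <- function(t0, dv) {
    v <- -70 + dv + 84 * exp(-(tt - t0)^2 / (2 * (0.4e-3)^2))
    trace(v, dt, "voltage")
  }
  a <- mk(0.010, 0); b <- mk(0.018, 0)
  ppa <- phase_plot(a, which.max(a$samples), c(3, 3))
  ppb <- phase_plot(b, which.max(b$samples), c(3, 3))
  expect_equal(ap_threshold(ppa), ap_threshold(ppb), tolerance = 1e-9)
  expect_equal(slope_extrema(ppa), slope_extrema(ppb), tolerance = 1e-9)
  # a uniform voltage offset shifts the threshold by exactly that offset
  c_ <- mk(0.010, 7)
  ppc <- phase_plot(c_, which.max(c_$samples), c(3, 3))
  expect_equal(ap_threshold(ppc), ap_threshold(ppa) + 7, tolerance = 1e-6)
  hw_a <- ap_half_width(a, ap_threshold(ppa), which.max(a$samples))
  hw_c <- ap_half_width(c_, ap_threshold(ppc), which.max(c_$samples))
  expect_equal(hw_a, hw_c, tolerance = 1e-6)
})

test_that("metrics agree between 10 kHz and 50 kHz sampling", {
  thr_at <- function(dt) {
    tt <- seq(0, 0.03, by = dt)
    v <- -70 + 84 * exp(-(tt - 0.015)^2 / (2 * (0.5e-3)^2))
    tr <- trace(v, dt, "voltage")
    pk <- which.max(v)
    pp <- phase_plot(tr, pk, c(3, 3))
    c(thr = ap_threshold(pp), hw = ap_half_width(tr, ap_threshold(pp), pk),
      mx = slope_extrema(pp)$max_dvdt)
  }
  a <- thr_at(1e-4); b <- thr_at(2e-5)
  expect_lt(abs(a[["hw"]] - b[["hw"]]), 0.1)       # one 10 kHz interval
  expect_lt(abs(a[["thr"]] - b[["thr"]]), 1.5)
  expect_lt(abs(a[["mx"]] - b[["mx"]]) / b[["mx"]], 0.05)
})

test_that("strengthening the AIS hyperpolarizes threshold and speeds the upstroke", {
  vals <- t(vapply(c(400, 600, 800), function(g) {
    s <- simulate_two_compartment(two_compartment_params(gNa_ais = g),
                                  amplitudes = 400, step_duration = 0.04)
    tr <- s$traces[[1]]
    pp <- phase_plot(tr, which.max(tr$samples), window_ms = c(3, 6))
    c(thr = ap_threshold(pp), mx = slope_extrema(pp)$max_dvdt)
  }, numeric(2)))
  expect_true(all(diff(vals[, "thr"]) < 0))
  expect_true(all(diff(vals[, "mx"]) > 0))
})
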