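test_that("sharp-edged plateau is recovered exactly", {
  tr <- ais_geometry_truth(4, 12, psf_sigma_um = 0, pixel_size_um = 0.2,
                           noise_sd = 0)
  m <- measure_ais(generate_ais_profile(tr), 0.3, smooth = FALSE)
  expect_equal(m$start_um, 4, tolerance = 0.02)  # < pixel/10
  expect_equal(m$end_um, 12, tolerance = 0.02)
  expect_equal(m$length_um, 8, tolerance = 0.02)
})

test_that("blurred boundaries match the error-function oracle", {
  for (sg in c(0.2, 0.4, 0.6)) {
    for (f in c(0.1, 0.3)) {
      tr <- ais_geometry_truth(4, 12, psf_sigma_um = sg,
                               pixel_size_um = 0.2, noise_sd = 0)
      m <- measure_ais(generate_ais_profile(tr), f, smooth = FALSE)
      expect_equal(m$length_um, erf_length_oracle(4, 12, sg, f),
                   tolerance = 0.2)   # one pixel
    }
  }
  # without background subtraction, the 0.3 threshold of the raw profile
  # moves each boundary out by qnorm((0.3-0.05)/0.95) * sigma = 0.634 sigma
  tr <- ais_geometry_truth(4, 12, psf_sigma_um = 0.4, pixel_size_um = 0.05,
                           plateau_intensity = 1,
                           background_intensity = 0.05, noise_sd = 0)
  m <- measure_ais(generate_ais_profile(tr), 0.3, smooth = FALSE,
                   background_subtract = FALSE)
  shift <- abs(qnorm((0.3 - 0.05) / 0.95))
  expect_equal(m$length_um, 8 + 2 * 0.4 * shift, tolerance = 0.05)
  expect_equal(shift, 0.634, tolerance = 1e-3)
})

test_that("measured length is monotone in threshold and scale-invariant", {
  tr <- ais_geometry_truth(4, 12, psf_sigma_um = 0.4, pixel_size_um = 0.2,
                           noise_sd = 0.03)
  pr <- generate_ais_profile(tr, seed = 9)
  lens <- vapply(c(0.1, 0.2, 0.3, 0.4), function(f) {
    measure_ais(pr, f)$length_um
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
  # global intensity scaling leaves the relative-threshold result unchanged
  scaled <- intensity_profile(pr$positions, pr$intensities * 7.3,
                              pr$pixel_size)
  expect_equal(measure_ais(scaled, 0.3)$length_um,
               measure_ais(pr, 0.3)$length_um, tolerance = 1e-9)
})

test_that("disjoint suprathreshold runs pick the longest and are flagged", {
  x <- seq(0, 30, by = 0.2)
  y <- 0.05 + 1.0 * (x >= 4 & x <= 12) + 0.9 * (x >= 20 & x <= 22)
  pr <- intensity_profile(x, y, 0.2)
  m <- measure_ais(pr, 0.3)
  expect_equal(m$length_um, 8, tolerance = 0.5)
  expect_false(is.null(m$flags$multiple_runs))
  # threshold never surpassed
  flat <- intensity_profile(x, rep(1, length(x)), 0.2)
  expect_error(measure_ais(flat, 0.3), "detection error")
})

test_that("profile extraction along polylines respects geometry", {
  img <- matrix(rep(seq_len(40), each = 30), nrow = 30)  # constant columns
  # horizontal path along a row of a column-gradient image reads the gradient
  path <- data.frame(x_px = c(3, 30), y_px = c(10, 10))
  pr <- extract_profile(img, path, pixel_size_um = 0.2)
  expect_equal(pr$intensities, seq(3, 30), tolerance = 1e-9)
  # constant image: width averaging changes nothing
  u <- matrix(5, 30, 40)
  p1 <- extract_profile(u, path, 0.2, line_width_px = 1)
  p3 <- extract_profile(u, path, 0.2, line_width_px = 3)
  expect_equal(p1$intensities, p3$intensities)
  # diagonal arc length: 10*sqrt(2) px at 0.2 um/px
  diag_path <- data.frame(x_px = c(5, 15), y_px = c(5, 15))
  prd <- extract_profile(u, diag_path, 0.2)
  expect_equal(max(prd$positions), 10 * sqrt(2) * 0.2, tolerance = 0.2)
  # exiting the image is a geometry error
  bad <- data.frame(x_px = c(35, 45), y_px = c(10, 10))
  expect_error(extract_profile(img, bad, 0.2), "geometry error")
})

test_that("diameter is the FWHM of the perpendicular profile", {
  tr <- ais_geometry_truth(4, 12, diameter_um = 1.2, psf_sigma_um = 0.2,
                           pixel_size_um = 0.1, background_intensity = 0,
                           noise_sd = 0)
  img <- generate_ais_image(tr, nrow_px = 81, y0_px = 41)
  axis <- data.frame(x_px = c(1, ncol(img)), y_px = c(41, 41))
  d <- measure_diameter(img, axis, position_um = 8, pixel_size_um = 0.1)
  expect_equal(d, 1.2, tolerance = 0.05)
  # doubling the cross-section width doubles the FWHM
  tr2 <- ais_geometry_truth(4, 12, diameter_um = 2.4, psf_sigma_um = 0.2,
                            pixel_size_um = 0.1, background_intensity = 0,
                            noise_sd = 0)
  img2 <- generate_ais_image(tr2, nrow_px = 81, y0_px = 41)
  d2 <- measure_diameter(img2, axis, 8, 0.1, halfwidth_um = 4)
  expect_equal(d2, 2.4, tolerance = 0.1)
  # a Gaussian cross-section of sd sigma has FWHM 2.355 sigma: checked via
  # a synthetic image built directly from that definition
  sigma <- 0.5
  y <- exp(-((1:81 - 41) * 0.1)^2 / (2 * sigma^2))
  img3 <- matrix(rep(y, 40), ncol = 40)
  d3 <- measure_diameter(img3, data.frame(x_px = c(1, 40), y_px = c(41, 41)),
                         position_um = 2, pixel_size_um = 0.1,
                         halfwidth_um = 3)
  expect_equal(d3, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.02)
})

test_that("intensity profile CSV round trips", {
  tr <- ais_geometry_truth(4, 12, noise_sd = 0.02)
  pr <- generate_ais_profile(tr, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_intensity_profile(pr, path)
  back <- read_intensity_profile(path)
  expect_equal(back$intensities, pr$intensities, tolerance = 1e-9)
  expect_equal(back$pixel_size, pr$pixel_size)
})
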