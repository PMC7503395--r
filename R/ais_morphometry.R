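# AIS morphometry from fluorescence line profiles: relative-intensity
# threshold boundaries, length, and FWHM diameter.

#' Fluorescence intensity line profile
#'
#' @param positions Positions along the profile, um, strictly increasing and
#'   uniformly spaced; 0 at the soma-proximal origin.
#' @param intensities Non-negative intensities, arbitrary units.
#' @param pixel_size Pixel pitch, um.
#' @param meta Free-form metadata (ground truth for synthetic profiles).
#' @return An object of class `"intensity_profile"`.
#' @export
intensity_profile <- function(positions, intensities, pixel_size,
                              meta = list()) {
  if (length(positions) != length(intensities) || length(positions) < 3L) {
    stop("positions and intensities must be equal length (>= 3)",
         call. = FALSE)
  }
  d <- diff(positions)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-6 * d[1]) {
    stop("positions must be strictly increasing and uniformly spaced",
         call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 pixel_size = as.numeric(pixel_size), meta = meta),
            class = "intensity_profile")
}

#' Write / read an intensity profile CSV
#'
#' Columns `position_um, intensity` with a `#`-prefixed pixel-size header.
#'
#' @param profile An [intensity_profile()].
#' @param path CSV path.
#' @return Invisibly, `path` (writer); an [intensity_profile()] (reader).
#' @export
write_intensity_profile <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_um=%s", format_num(profile$pixel_size)),
             con)
  writeLines("position_um,intensity", con)
  writeLines(paste(format_num(profile$positions),
                   format_num(profile$intensities), sep = ","), con)
  invisible(path)
}

#' @rdname write_intensity_profile
#' @export
read_intensity_profile <- function(path) {
  first <- readLines(path, n = 1L)
  px <- if (grepl("^# pixel_size_um=", first)) {
    as.numeric(sub("^# pixel_size_um=", "", first))
  } else NA_real_
  df <- utils::read.csv(path, comment.char = "#")
  if (is.na(px)) px <- stats::median(diff(df$position_um))
  intensity_profile(df$position_um, df$intensity, px)
}

# Bilinear interpolation of img (rows = y, cols = x) at fractional pixel
# coordinates (x, y), 1-based.
bilinear <- function(img, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(pmax(x0, 1L), ncol(img) - 1L)
  y0 <- pmin(pmax(y0, 1L), nrow(img) - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    img[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1L, x0 + 1L)] * fx * fy
}

# Resample a polyline (data.frame x_px, y_px) at unit-pixel arc-length
# spacing; returns sample points, unit tangents, and cumulative arc length.
polyline_samples <- function(path_px, spacing = 1) {
  x <- path_px$x_px; y <- path_px$y_px
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  arc <- c(0, cumsum(seg))
  s <- seq(0, arc[length(arc)], by = spacing)
  xs <- stats::approx(arc, x, xout = s)$y
  ys <- stats::approx(arc, y, xout = s)$y
  # tangents by central differences along the resampled path
  n <- length(s)
  tx <- c(xs[2] - xs[1], (xs[-(1:2)] - xs[-((n - 1):n)]) / 2,
          xs[n] - xs[n - 1])
  ty <- c(ys[2] - ys[1], (ys[-(1:2)] - ys[-((n - 1):n)]) / 2,
          ys[n] - ys[n - 1])
  nrm <- sqrt(tx^2 + ty^2)
  list(x = xs, y = ys, s = s, tx = tx / nrm, ty = ty / nrm)
}

#' Extract an intensity profile along a polyline drawn over an AIS
#'
#' Intensities are sampled by bilinear interpolation at unit-pixel arc-length
#' spacing along the polyline and averaged across `line_width_px` samples
#' perpendicular to the local direction. Positions are cumulative arc length
#' times `pixel_size_um`.
#'
#' @param image Numeric matrix (rows y, columns x), e.g. a grayscale TIFF
#'   read with `tiff::readTIFF`.
#' @param path_px data.frame with columns `x_px`, `y_px` (1-based pixel
#'   coordinates, >= 2 vertices).
#' @param pixel_size_um Pixel size, um.
#' @param line_width_px Width of the perpendicular averaging band, px.
#' @return An [intensity_profile()].
#' @export
extract_profile <- function(image, path_px, pixel_size_um,
                            line_width_px = 1) {
  if (!is.matrix(image)) stop("`image` must be a numeric matrix",
                              call. = FALSE)
  if (nrow(path_px) < 2L) stop("polyline needs >= 2 vertices", call. = FALSE)
  ps <- polyline_samples(path_px)
  offs <- seq(-(line_width_px - 1) / 2, (line_width_px - 1) / 2,
              length.out = max(1L, line_width_px))
  acc <- 0
  for (o in offs) {
    px <- ps$x - o * ps$ty   # perpendicular = rotated tangent
    py <- ps$y + o * ps$tx
    if (any(px < 1 | px > ncol(image) | py < 1 | py > nrow(image))) {
      stop("geometry error: path (with averaging band) exits the image",
           call. = FALSE)
    }
    acc <- acc + bilinear(image, px, py)
  }
  intensity_profile(positions = ps$s * pixel_size_um,
                    intensities = acc / length(offs),
                    pixel_size = pixel_size_um)
}

#' Measure AIS boundaries and length with the relative-intensity threshold
#'
#' After optional background subtraction (minimum of the profile) and
#' optional 3-pixel moving-average smoothing, the proximal and distal AIS
#' boundaries are the first and last positions where the intensity surpasses
#' `threshold_fraction` of the maximum, linearly interpolated between the
#' bracketing pixels. With several disjoint suprathreshold runs (e.g. nodes
#' of Ranvier in the background) the longest contiguous run is measured and
#' the result flagged.
#'
#' @param profile An [intensity_profile()].
#' @param threshold_fraction Fraction of the (background-subtracted) maximum,
#'   in `[0.05, 0.5]`; the conventional operating range is 0.1-0.3.
#' @param smooth 3-pixel moving-average smoothing (default on).
#' @param background_subtract Subtract the profile minimum before applying
#'   the relative threshold (default on).
#' @return An object of class `"ais_measurement"`: `start_um`, `end_um`,
#'   `length_um`, `threshold_fraction`, `max_intensity_position_um`,
#'   `diameter_um` (`NA` here), `flags`.
#' @export
measure_ais <- function(profile, threshold_fraction = 0.3, smooth = TRUE,
                        background_subtract = TRUE) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (threshold_fraction < 0.05 || threshold_fraction > 0.5) {
    stop("threshold_fraction must lie in [0.05, 0.5]", call. = FALSE)
  }
  x <- profile$positions
  y <- profile$intensities
  if (smooth && length(y) >= 3L) {
    sm <- stats::filter(y, rep(1 / 3, 3), sides = 2)
    y <- ifelse(is.na(sm), y, as.numeric(sm))
  }
  bg <- if (background_subtract) min(y) else 0
  thr <- bg + threshold_fraction * (max(y) - bg)
  above <- y > thr
  if (!any(above)) {
    stop("detection error: threshold never surpassed", call. = FALSE)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  flags <- list()
  if (length(runs) > 1L) {
    flags$multiple_runs <- length(runs)
    runs <- runs[which.max(r$lengths[runs])]
  }
  i0 <- starts[runs]; i1 <- ends[runs]
  px <- profile$pixel_size
  rng <- max(y) - bg
  # Sub-pixel interpolation is only meaningful when the edge is resolved by
  # the sampling; across a near-discontinuous edge (most of the dynamic
  # range within one pixel) the boundary snaps to the first suprathreshold
  # pixel instead.
  steep <- function(dy) dy > 0.45 * rng
  start_um <- if (i0 > 1L) {
    if (steep(y[i0] - y[i0 - 1L])) x[i0]
    else x[i0 - 1L] + px * (thr - y[i0 - 1L]) / (y[i0] - y[i0 - 1L])
  } else {
    flags$clipped_start <- TRUE
    x[1]
  }
  end_um <- if (i1 < length(y)) {
    if (steep(y[i1] - y[i1 + 1L])) x[i1]
    else x[i1] + px * (y[i1] - thr) / (y[i1] - y[i1 + 1L])
  } else {
    flags$clipped_end <- TRUE
    x[length(x)]
  }
  structure(list(start_um = start_um, end_um = end_um,
                 length_um = end_um - start_um,
                 threshold_fraction = threshold_fraction,
                 max_intensity_position_um = x[which.max(y)],
                 diameter_um = NA_real_, flags = flags),
            class = "ais_measurement")
}

#' @export
print.ais_measurement <- function(x, ...) {
  cat(sprintf("<ais_measurement> [%.2f, %.2f] um, length %.2f um (threshold %g)\n",
              x$start_um, x$end_um, x$length_um, x$threshold_fraction))
  invisible(x)
}

#' AIS diameter from a perpendicular intensity profile
#'
#' Full width at half maximum of the background-subtracted intensity profile
#' taken perpendicular to the AIS axis at arc-length `position_um`; both
#' half-maximum crossings are linearly interpolated.
#'
#' @param image Numeric matrix (rows y, columns x).
#' @param axis_px data.frame `x_px`, `y_px`: the AIS axis polyline.
#' @param position_um Arc-length position of the cross-section, um.
#' @param pixel_size_um Pixel size, um.
#' @param halfwidth_um Half-length of the sampled cross-section, um.
#' @return Diameter (FWHM), um.
#' @export
measure_diameter <- function(image, axis_px, position_um, pixel_size_um,
                             halfwidth_um = 3) {
  ps <- polyline_samples(axis_px, spacing = 0.25)
  s_um <- ps$s * pixel_size_um
  if (position_um < 0 || position_um > max(s_um)) {
    stop("geometry error: position lies outside the axis polyline",
         call. = FALSE)
  }
  k <- which.min(abs(s_um - position_um))
  hw_px <- halfwidth_um / pixel_size_um
  off <- seq(-hw_px, hw_px, by = 0.25)
  px <- ps$x[k] - off * ps$ty[k]
  py <- ps$y[k] + off * ps$tx[k]
  if (any(px < 1 | px > ncol(image) | py < 1 | py > nrow(image))) {
    stop("geometry error: cross-section exits the image", call. = FALSE)
  }
  y <- bilinear(image, px, py)
  pos <- off * pixel_size_um
  bg <- min(y)
  half <- bg + (max(y) - bg) / 2
  pk <- which.max(y)
  left <- which(y[seq_len(pk)] < half)
  right <- which(y[pk:length(y)] < half) + pk - 1L
  if (!length(left) || !length(right)) {
    stop("detection error: half maximum not reached on both sides",
         call. = FALSE)
  }
  l <- max(left)
  xl <- pos[l] + (pos[l + 1L] - pos[l]) * (half - y[l]) / (y[l + 1L] - y[l])
  r <- min(right)
  xr <- pos[r - 1L] + (pos[r] - pos[r - 1L]) * (y[r - 1L] - half) /
    (y[r - 1L] - y[r])
  xr - xl
}
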