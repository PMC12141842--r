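# Time-lapse morphogenesis quantification: grey-level line profiles,
# kymographs, expansion-front tracking, wrinkle-wavelength detection, and
# colony expansion rates from diameter tables.

#' Construct an image stack
#'
#' @param frames list of grey-level matrices of identical size.
#' @param times_h frame times in hours, strictly increasing.
#' @param pixel_size mm per pixel.
#' @return An `image_stack`.
#' @export
image_stack <- function(frames, times_h, pixel_size) {
  if (length(frames) != length(times_h)) {
    stop_input("one time per frame required")
  }
  if (any(diff(times_h) <= 0)) stop_input("times must be strictly increasing")
  d1 <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d1), logical(1L)))) {
    stop_input("frames must share one shape")
  }
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  structure(list(frames = frames, times_h = as.numeric(times_h),
                 pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image stack: %d frames of %d x %d px, %.2f-%.2f h, %.3g mm/px\n",
              length(x$frames), nrow(x$frames[[1L]]), ncol(x$frames[[1L]]),
              min(x$times_h), max(x$times_h), x$pixel_size))
  invisible(x)
}

#' Grey-level profile along a probe line
#'
#' Samples grey values with bilinear (sub-pixel) interpolation at
#' `pixel_size` steps along a straight probe given in mm coordinates
#' (origin at the top-left pixel centre).
#'
#' @param image grey-level matrix.
#' @param probe numeric length-4: `(x0, y0, x1, y1)` in mm.
#' @param pixel_size mm per pixel.
#' @return Numeric vector of grey values with attribute `positions_mm`
#'   (distance along the probe).
#' @export
gray_profile <- function(image, probe, pixel_size) {
  stopifnot(is.matrix(image), length(probe) == 4L)
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  x0 <- probe[1L]; y0 <- probe[2L]; x1 <- probe[3L]; y1 <- probe[4L]
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len <= 0) stop_input("zero-length probe")
  ext_x <- (ncol(image) - 1) * pixel_size
  ext_y <- (nrow(image) - 1) * pixel_size
  if (min(x0, x1) < -1e-9 || max(x0, x1) > ext_x + 1e-9 ||
      min(y0, y1) < -1e-9 || max(y0, y1) > ext_y + 1e-9) {
    stop_input("probe outside the image")
  }
  s <- seq(0, len, by = pixel_size)
  px <- (x0 + (x1 - x0) * s / len) / pixel_size + 1
  py <- (y0 + (y1 - y0) * s / len) / pixel_size + 1
  structure(sample_bilinear(image, px, py), positions_mm = s)
}

#' Build a kymograph from a stack and a probe
#'
#' Row t of the kymograph is the grey profile of frame t along the probe,
#' so a moving boundary appears as a sloped edge in the space-time image.
#'
#' @param stack an [image_stack].
#' @param probe numeric length-4 `(x0, y0, x1, y1)` in mm.
#' @return A `kymograph`: list with `values` (time x space matrix),
#'   `positions` (mm), `times` (h).
#' @export
build_kymograph <- function(stack, probe) {
  stopifnot(inherits(stack, "image_stack"))
  rows <- lapply(stack$frames, gray_profile, probe = probe,
                 pixel_size = stack$pixel_size)
  structure(list(values = do.call(rbind, rows),
                 positions = attr(rows[[1L]], "positions_mm"),
                 times = stack$times_h),
            class = "kymograph")
}

#' Track an expansion front on a kymograph
#'
#' Per time row, the front is the outermost position where the profile
#' crosses a grey threshold (bright pellicle inside, darker medium outside;
#' linear interpolation between samples gives sub-pixel positions). The
#' front speed is the slope of a least-squares line of position on time.
#'
#' @param kym a `kymograph`.
#' @param level grey threshold within the grey range.
#' @param side `"outward"`: last position above `level` (default);
#'   `"inward"`: first position above `level`.
#' @param max_skipped maximum tolerated fraction of rows without a crossing
#'   (default 0.5).
#' @return A `front_track`: list with `times`, `front_position` (mm),
#'   `speed` (mm/h), `fit_r2`, `n_skipped`.
#' @export
track_front <- function(kym, level, side = c("outward", "inward"),
                        max_skipped = 0.5) {
  stopifnot(inherits(kym, "kymograph"))
  side <- match.arg(side)
  pos <- kym$positions
  front <- rep(NA_real_, nrow(kym$values))
  for (t in seq_len(nrow(kym$values))) {
    v <- kym$values[t, ]
    above <- v >= level
    if (!any(above) || all(above)) next
    if (side == "outward") {
      i <- max(which(above))
      front[t] <- if (i == length(v)) pos[i] else {
        pos[i] + (pos[i + 1L] - pos[i]) * (v[i] - level) / (v[i] - v[i + 1L])
      }
    } else {
      i <- min(which(above))
      front[t] <- if (i == 1L) pos[1L] else {
        pos[i] - (pos[i] - pos[i - 1L]) * (v[i] - level) / (v[i] - v[i - 1L])
      }
    }
  }
  skipped <- sum(is.na(front))
  if (skipped > max_skipped * length(front)) {
    stop_input("front not detectable in more than half of the rows")
  }
  ok <- !is.na(front)
  fit <- stats::lm(front[ok] ~ kym$times[ok])
  r2 <- if (stats::sd(front[ok]) > 0) summary(fit)$r.squared else NA_real_
  structure(list(times = kym$times[ok], front_position = front[ok],
                 speed = unname(stats::coef(fit)[2L]), fit_r2 = r2,
                 n_skipped = skipped),
            class = "front_track")
}

#' Dominant wrinkle wavelength of a grey-level profile
#'
#' The profile is detrended by subtracting a moving-average baseline
#' (window = twice the upper band limit), then the dominant wavelength is
#' the first peak of the spatial autocorrelation inside the wavelength band
#' that exceeds `ac_threshold`, refined to sub-lag precision by a parabolic
#' fit. The maximum of the periodogram inside the band is reported alongside
#' as a consistency check. A profile with no qualifying autocorrelation peak
#' is classified aperiodic.
#'
#' @param profile numeric grey-level profile (e.g. from [gray_profile]).
#' @param pixel_size mm per sample.
#' @param band numeric length-2 wavelength band `(min_mm, max_mm)`.
#' @param ac_threshold minimum autocorrelation for a significant peak
#'   (default 0.2).
#' @return A `wrinkle_spectrum`: list with `wavelengths`, `power`
#'   (periodogram inside the band), `dominant_wavelength` (mm, NA if
#'   aperiodic), `spectral_wavelength` (mm), `status` (`"periodic"` or
#'   `"aperiodic"`).
#' @export
wrinkle_wavelength <- function(profile, pixel_size, band,
                               ac_threshold = 0.2) {
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L]) {
    stop_input("band must be (min_mm, max_mm) with 0 < min < max")
  }
  n <- length(profile)
  if (n < 4 * band[2L] / pixel_size) {
    stop_input("profile too short: need at least 4 x max wavelength")
  }
  detr <- profile - moving_average(profile, round(2 * band[2L] / pixel_size))
  lag_max <- min(n - 2L, ceiling(1.5 * band[2L] / pixel_size))
  ac <- stats::acf(detr, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1L, 1L]
  lags <- seq_along(ac) - 1L
  lo <- band[1L] / pixel_size; hi <- band[2L] / pixel_size
  dominant <- NA_real_
  for (k in 3:(length(ac) - 1L)) {
    lag <- lags[k]
    if (lag < lo || lag > hi) next
    if (ac[k] > ac[k - 1L] && ac[k] >= ac[k + 1L] && ac[k] > ac_threshold) {
      den <- ac[k - 1L] - 2 * ac[k] + ac[k + 1L]
      delta <- if (abs(den) > 1e-12) (ac[k - 1L] - ac[k + 1L]) / (2 * den) else 0
      dominant <- (lag + max(-0.5, min(0.5, delta))) * pixel_size
      break
    }
  }
  # periodogram consistency check inside the band
  spec <- stats::spec.pgram(detr, detrend = TRUE, taper = 0.1, plot = FALSE)
  wl <- pixel_size / spec$freq
  in_band <- wl >= band[1L] & wl <= band[2L]
  spectral <- if (any(in_band)) wl[in_band][which.max(spec$spec[in_band])]
  else NA_real_
  structure(list(wavelengths = wl[in_band], power = spec$spec[in_band],
                 dominant_wavelength = dominant,
                 spectral_wavelength = spectral,
                 status = if (is.na(dominant)) "aperiodic" else "periodic"),
            class = "wrinkle_spectrum")
}

#' Colony expansion rate from diameter measurements
#'
#' Colonization rates are conventionally radius-like: the default is
#' `(diameter - baseline) / (2 * time)`. The diameter convention
#' `(diameter - baseline) / time` is available where a diameter-growth rate
#' is wanted; the convention used is recorded on the result.
#'
#' @param diameter colony diameter(s), mm.
#' @param time incubation time(s), h (> 0).
#' @param convention `"radius"` (default) or `"diameter"`.
#' @param baseline_diameter inoculum diameter subtracted before dividing,
#'   mm (default 0).
#' @return Expansion rate(s), mm/h, with attribute `convention`.
#' @export
expansion_rate <- function(diameter, time, convention = c("radius", "diameter"),
                           baseline_diameter = 0) {
  convention <- match.arg(convention)
  if (any(time <= 0)) stop_input("time must be positive")
  if (any(diameter < 0) || baseline_diameter < 0) {
    stop_input("diameters must be non-negative")
  }
  growth <- diameter - baseline_diameter
  rate <- if (convention == "radius") growth / (2 * time) else growth / time
  structure(rate, convention = convention)
}
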