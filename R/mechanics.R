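# Force-sensor mechanics: conversion of cantilever deflection to force,
# zero-force calibration against the post-failure record, correction of the
# pellicle elongation for the deflection of the "immobile" plate, failure
# detection, elastic-regime fitting (stiffness and intercept), true-strain
# correction for composite pellicles, and length rescaling of stiffness.

#' Double-cantilever force sensor model
#'
#' @param cantilever_stiffness sensor stiffness, mN/mm (default 19.5, i.e. a
#'   1 mN force deflects the sensor plate by 0.051 mm).
#' @param deflection_resolution capacitive gauge resolution, micrometres
#'   (default 0.40).
#' @export
sensor_model <- function(cantilever_stiffness = 19.5,
                         deflection_resolution = 0.40) {
  check_scalar(cantilever_stiffness, "cantilever_stiffness", lower = 0,
               strict_lower = TRUE)
  check_scalar(deflection_resolution, "deflection_resolution", lower = 0)
  structure(list(cantilever_stiffness = cantilever_stiffness,
                 deflection_resolution = deflection_resolution),
            class = "sensor_model")
}

#' Pulling protocol of the stretching device
#'
#' @param speed translation-stage speed, micrometres per second (default 160).
#' @param sampling_interval sensor sampling interval, ms (default 100).
#' @param max_travel total plate travel, mm (default 12).
#' @param plate_gap initial distance between the plates, mm (default 13.5).
#' @param plate_width plate width, mm (default 41).
#' @export
pull_protocol <- function(speed = 160, sampling_interval = 100,
                          max_travel = 12, plate_gap = 13.5,
                          plate_width = 41) {
  for (nm in c("speed", "sampling_interval", "max_travel", "plate_gap",
               "plate_width")) {
    check_scalar(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  structure(list(speed = speed, sampling_interval = sampling_interval,
                 max_travel = max_travel, plate_gap = plate_gap,
                 plate_width = plate_width),
            class = "pull_protocol")
}

#' Construct a force trace
#'
#' @param time_s sample times, s (strictly increasing).
#' @param plate_displacement_mm mobile-plate displacement, mm.
#' @param signal raw sensor signal: cantilever deflection in micrometres
#'   (`channel = "deflection_um"`) or pre-converted force in mN
#'   (`channel = "force_mN"`).
#' @param channel declared signal channel.
#' @return A `force_trace` data frame with columns `time_s`,
#'   `plate_displacement_mm`, `raw_signal` and (for a force channel)
#'   `force_mN`.
#' @export
force_trace <- function(time_s, plate_displacement_mm, signal,
                        channel = c("force_mN", "deflection_um")) {
  channel <- match.arg(channel)
  if (any(diff(time_s) <= 0)) stop_input("time must be strictly increasing")
  n <- length(time_s)
  if (length(plate_displacement_mm) != n || length(signal) != n) {
    stop_input("trace columns must have equal length")
  }
  df <- data.frame(time_s = time_s,
                   plate_displacement_mm = plate_displacement_mm,
                   raw_signal = signal)
  if (channel == "force_mN") df$force_mN <- signal
  structure(df, channel = channel, calibrated = FALSE,
            class = c("force_trace", "data.frame"))
}

#' Convert cantilever deflection to force
#'
#' `force = cantilever_stiffness x deflection` with units reconciled
#' (mN/mm applied to micrometres). The sign is preserved: pulling gives
#' positive, pushing negative deflections, so the two are discriminated
#' directly.
#'
#' @param deflection_um deflection(s), micrometres.
#' @param sensor a [sensor_model].
#' @return Force(s), mN.
#' @export
deflection_to_force <- function(deflection_um, sensor = sensor_model()) {
  stopifnot(inherits(sensor, "sensor_model"))
  sensor$cantilever_stiffness * deflection_um / 1000
}

#' Convert a deflection-channel trace to force
#'
#' @param trace a `force_trace` with channel `"deflection_um"`.
#' @param sensor a [sensor_model].
#' @return The trace with a `force_mN` column and channel `"force_mN"`.
#' @export
convert_channel <- function(trace, sensor = sensor_model()) {
  stopifnot(inherits(trace, "force_trace"))
  if (attr(trace, "channel") == "force_mN") return(trace)
  trace$force_mN <- deflection_to_force(trace$raw_signal, sensor)
  attr(trace, "channel") <- "force_mN"
  trace
}

#' Detect pellicle failure in a force trace
#'
#' Failure is an abrupt, permanent loss of transmitted force: the failure
#' index is the first sample whose force falls below `drop_fraction` times
#' the running maximum of the preceding `window_samples` samples and stays
#' below that level for `persistence` consecutive samples. Only drops from
#' a force level of at least `min_force` qualify, so noise around zero
#' before the pellicle is under tension cannot trigger a spurious
#' detection, and the persistence requirement rejects isolated noise dips
#' at low force (a broken pellicle never recovers its load). The failure
#' force is the running maximum; the failure elongation is read at the last
#' pre-drop sample.
#'
#' @param trace a `force_trace` with a `force_mN` column.
#' @param drop_fraction fraction of the recent maximum below which a sample
#'   signals failure (default 0.5).
#' @param window_samples length of the running-maximum window (default 5).
#' @param min_force minimum pre-drop force for a detection, mN (default 0.5).
#' @param persistence number of consecutive sub-threshold samples required
#'   (default 3; truncated at the end of the record).
#' @return A list: `status` (`"failed"` or `"none"`), `index`,
#'   `failure_force` (mN), `failure_elongation` (mm, from the `elongation_mm`
#'   column when present, else plate displacement).
#' @export
detect_failure <- function(trace, drop_fraction = 0.5, window_samples = 5L,
                           min_force = 0.5, persistence = 3L) {
  stopifnot(inherits(trace, "force_trace"))
  f <- trace$force_mN %||% stop_input("trace has no force_mN column; convert the channel first")
  n <- length(f)
  w <- max(1L, as.integer(window_samples))
  p <- max(1L, as.integer(persistence))
  elong <- trace$elongation_mm %||% trace$plate_displacement_mm
  for (i in 2:n) {
    lo <- max(1L, i - w)
    m <- max(f[lo:(i - 1L)])
    if (m >= min_force && f[i] < drop_fraction * m) {
      run <- i:min(n, i + p - 1L)
      if (all(f[run] < drop_fraction * m)) {
        return(list(status = "failed", index = i, failure_force = m,
                    failure_elongation = elong[i - 1L]))
      }
    }
  }
  list(status = "none", index = NA_integer_, failure_force = NA_real_,
       failure_elongation = NA_real_)
}

#' Zero-force calibration from the post-failure record
#'
#' After failure the pellicle no longer transmits force, so the mean signal
#' over a window at the end of the record measures the sensor's zero-force
#' value; it is subtracted from the whole trace. The calibration is exactly
#' idempotent (a second pass subtracts zero).
#'
#' @param trace a `force_trace` with a `force_mN` column.
#' @param post_failure_window length of the averaging window at the end of
#'   the record, s (default 2).
#' @param ... arguments passed to [detect_failure].
#' @return The calibrated trace; attribute `zero_offset` records the
#'   subtracted value.
#' @export
zero_calibrate <- function(trace, post_failure_window = 2, ...) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(trace$force_mN)) {
    stop_input("trace has no force_mN column; convert the channel first")
  }
  det <- detect_failure(trace, ...)
  if (det$status != "failed") {
    stop_input("no failure detected: cannot measure the zero-force value")
  }
  tmax <- max(trace$time_s)
  win <- trace$time_s > tmax - post_failure_window
  if (!any(win)) stop_input("empty post-failure window")
  if (min(which(win)) <= det$index) {
    stop_input("post-failure window overlaps pre-failure samples")
  }
  offset <- mean(trace$force_mN[win])
  trace$force_mN <- trace$force_mN - offset
  attr(trace, "calibrated") <- TRUE
  attr(trace, "zero_offset") <- offset
  attr(trace, "failure") <- detect_failure(trace, ...)
  trace
}

#' Pellicle elongation corrected for sensor-plate deflection
#'
#' A tensile force deflects the cantilever and drags the "immobile" plate
#' toward the mobile one, so the pellicle elongates less than the plate
#' travel: `elongation = plate_displacement - force / cantilever_stiffness`.
#'
#' @param trace a calibrated `force_trace`.
#' @param sensor a [sensor_model].
#' @return The trace with an `elongation_mm` column.
#' @export
pellicle_elongation <- function(trace, sensor = sensor_model()) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(trace$force_mN)) {
    stop_input("trace has no force_mN column; convert the channel first")
  }
  trace$elongation_mm <- trace$plate_displacement_mm -
    trace$force_mN / sensor$cantilever_stiffness
  trace
}

#' True-strain correction for composite pellicles
#'
#' When only a central fraction of the pellicle deforms, the elongation of
#' that region is `central_fraction` times the applied value; the corrected
#' axis expresses a true elongation of the reported region (e.g. a 3.7 mm
#' plate travel corresponds to 1 mm of central-region elongation at
#' fraction 0.27).
#'
#' @param elongation elongation values, mm (applied plate travel or
#'   sensor-corrected elongation).
#' @param central_fraction fraction of the applied elongation absorbed by
#'   the region of interest, in (0, 1].
#' @return Corrected elongation values, mm.
#' @export
correct_true_strain <- function(elongation, central_fraction) {
  check_scalar(central_fraction, "central_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  central_fraction * elongation
}

#' Fit the elastic regime of a force-elongation curve
#'
#' Least-squares line of force on elongation over a window expressed as
#' fractions of the failure elongation (default 5 % to 90 %), excluding
#' seating transients at the start and crack initiation just before failure.
#' The slope in mN/mm is reported as stiffness in N/m (numerically
#' identical); the intercept is the force extrapolated to zero elongation.
#'
#' @param trace a calibrated `force_trace`; the fit axis is `elongation_mm`
#'   when present, else plate displacement.
#' @param fit_range numeric length-2, fractions of the failure elongation.
#' @param failure optional result of [detect_failure]; detected when NULL.
#' @param ... arguments passed to [detect_failure].
#' @return A list: `stiffness` (N/m), `intercept` (mN), `r_squared`, `n`,
#'   `fit_window_mm`, `failure`.
#' @export
fit_elastic <- function(trace, fit_range = c(0.05, 0.90), failure = NULL,
                        ...) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(trace$force_mN)) {
    stop_input("trace has no force_mN column; convert the channel first")
  }
  e <- trace$elongation_mm %||% trace$plate_displacement_mm
  if (is.null(failure)) failure <- detect_failure(trace, ...)
  if (failure$status != "failed") {
    stop_input("no failure detected; pass an explicit 'failure' or fit range")
  }
  win <- c(fit_range[1L], fit_range[2L]) * failure$failure_elongation
  idx <- which(e >= win[1L] & e <= win[2L] &
                 seq_along(e) < failure$index)
  if (length(idx) < 10L) stop_input("fewer than 10 samples in the fit range")
  fit <- stats::lm(trace$force_mN[idx] ~ e[idx])
  sst <- sum((trace$force_mN[idx] - mean(trace$force_mN[idx]))^2)
  list(stiffness = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else NA_real_,
       n = length(idx), fit_window_mm = win, failure = failure)
}

#' Rescale a segment stiffness to another length
#'
#' The stiffness of a uniform strip scales inversely with its length, so the
#' product k x L is conserved: a segment occupying `segment_length_fraction`
#' of the full specimen with stiffness `k_segment` corresponds to a
#' full-length stiffness `k_segment * segment_length_fraction`.
#'
#' @param k_segment segment stiffness, N/m.
#' @param segment_length_fraction segment length as a fraction of the full
#'   length, in (0, 1].
#' @return Full-length stiffness, N/m.
#' @export
rescale_stiffness <- function(k_segment, segment_length_fraction) {
  if (!is.numeric(segment_length_fraction) ||
      any(!is.finite(segment_length_fraction)) ||
      any(segment_length_fraction <= 0) || any(segment_length_fraction > 1)) {
    stop_input("'segment_length_fraction' must lie in (0, 1]")
  }
  k_segment * segment_length_fraction
}

#' Failure strain as a percentage of the initial gap
#'
#' @param failure_elongation elongation at failure, mm.
#' @param initial_gap initial plate separation, mm.
#' @return Strain at failure, percent.
#' @export
failure_strain <- function(failure_elongation, initial_gap) {
  check_scalar(initial_gap, "initial_gap", lower = 0, strict_lower = TRUE)
  100 * failure_elongation / initial_gap
}

#' Summarise replicate mechanical fits
#'
#' Unweighted mean and standard deviation over pellicle replicates of the
#' fitted stiffness, intercept, and failure quantities.
#'
#' @param fits a list of results from [fit_elastic].
#' @param initial_gap initial plate separation for failure strain, mm.
#' @return A `mechanical_summary` list of per-quantity mean, sd, and `n`.
#' @export
summarize_mechanics <- function(fits, initial_gap = 13.5) {
  stopifnot(length(fits) >= 1L)
  g <- function(f) vapply(fits, f, numeric(1L))
  k <- g(function(f) f$stiffness)
  b <- g(function(f) f$intercept)
  ff <- g(function(f) f$failure$failure_force)
  fe <- g(function(f) f$failure$failure_elongation)
  structure(list(
    stiffness = mean(k), stiffness_sd = stats::sd(k),
    intercept = mean(b), intercept_sd = stats::sd(b),
    failure_force = mean(ff), failure_force_sd = stats::sd(ff),
    failure_elongation = mean(fe), failure_elongation_sd = stats::sd(fe),
    failure_strain_pct = mean(failure_strain(fe, initial_gap)),
    n_replicates = length(fits)), class = "mechanical_summary")
}

#' @export
print.mechanical_summary <- function(x, ...) {
  cat(sprintf("stiffness: %.3f +/- %.3f N/m (n = %d)\n",
              x$stiffness, x$stiffness_sd, x$n_replicates))
  cat(sprintf("intercept: %.3f +/- %.3f mN\n", x$intercept, x$intercept_sd))
  cat(sprintf("failure: %.2f mN at %.2f mm (%.1f%% strain)\n",
              x$failure_force, x$failure_elongation, x$failure_strain_pct))
  invisible(x)
}
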