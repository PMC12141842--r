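# Synthetic-data generators. Real pellicle images and force recordings are
# not redistributable, so every downstream stage is exercised on seeded
# synthetic inputs whose ground truth is known by construction: speckle
# images warped by a prescribed displacement profile, linear-elastic force
# traces with abrupt failure, and time-lapse stacks with moving fronts and
# periodic wrinkles.

#' Specification of a synthetic speckle image
#'
#' Speckle images emulate the optically visible non-uniformities of a
#' pellicle that serve as tracer "particles" for PIV. The texture is a field
#' of Gaussian-profile grains on a flat background plus additive Gaussian
#' noise; grain density and radius set the spatial correlation length.
#'
#' @param width_px,height_px image size in pixels.
#' @param grain_density expected number of grains per 1000 px^2.
#' @param grain_radius_px Gaussian radius (s.d.) of one grain, px.
#' @param contrast grain amplitude as a fraction of the headroom above the
#'   background, in (0, 1].
#' @param background_level background grey value (0-255 scale).
#' @param noise_sd additive Gaussian noise s.d., grey values.
#' @param seed integer RNG seed; identical spec + seed gives a bit-identical
#'   image.
#' @return A `speckle_spec` list.
#' @export
speckle_spec <- function(width_px = 512, height_px = 512, grain_density = 5,
                         grain_radius_px = 2, contrast = 0.6,
                         background_level = 60, noise_sd = 2, seed = 1L) {
  check_scalar(width_px, "width_px", lower = 1)
  check_scalar(height_px, "height_px", lower = 1)
  check_scalar(grain_density, "grain_density", lower = 0)
  check_scalar(grain_radius_px, "grain_radius_px", lower = 0, strict_lower = TRUE)
  check_scalar(contrast, "contrast", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(background_level, "background_level", lower = 0, upper = 255)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 grain_density = grain_density,
                 grain_radius_px = grain_radius_px, contrast = contrast,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "speckle_spec")
}

#' Generate a speckle image
#'
#' Grain count is Poisson with mean `grain_density * area / 1000`; centres
#' are uniform over the frame. Each grain adds a Gaussian bump of amplitude
#' `contrast * (255 - background_level)`. Values are clipped to \[0, 255\].
#'
#' @param spec a [speckle_spec].
#' @return A numeric matrix (rows = y, columns = x) of grey values.
#' @export
generate_speckle <- function(spec) {
  stopifnot(inherits(spec, "speckle_spec"))
  w <- spec$width_px; h <- spec$height_px
  with_seed(spec$seed, {
    img <- matrix(spec$background_level, nrow = h, ncol = w)
    n_grains <- stats::rpois(1L, spec$grain_density * w * h / 1000)
    amp <- spec$contrast * (255 - spec$background_level)
    r <- spec$grain_radius_px
    if (n_grains > 0L) {
      cx <- stats::runif(n_grains, 0.5, w + 0.5)
      cy <- stats::runif(n_grains, 0.5, h + 0.5)
      ext <- ceiling(3 * r)
      for (g in seq_len(n_grains)) {
        xs <- max(1L, floor(cx[g] - ext)):min(w, ceiling(cx[g] + ext))
        ys <- max(1L, floor(cy[g] - ext)):min(h, ceiling(cy[g] + ext))
        dx2 <- (xs - cx[g])^2
        dy2 <- (ys - cy[g])^2
        img[ys, xs] <- img[ys, xs] +
          amp * outer(exp(-dy2 / (2 * r^2)), exp(-dx2 / (2 * r^2)))
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(w * h, 0, spec$noise_sd), h, w)
    }
    clip_grey(img)
  })
}

#' Warp an image by a prescribed displacement profile
#'
#' Produces the "after stretching" frame of a synthetic image pair. The warp
#' is backward (output to source) with bilinear interpolation: the output
#' pixel at position x samples the source at `x - u(x)`, where
#' `u(x) = total_elongation_px * evaluate_profile(nodes, x / extent)`.
#' Backward mapping avoids the holes of forward splatting; edge samples take
#' clamped coordinates.
#'
#' @param image numeric grey-level matrix.
#' @param nodes a [profile_nodes] displacement profile.
#' @param total_elongation_px plate translation in pixels (>= 0).
#' @param axis `"horizontal"` (columns move) or `"vertical"` (rows move).
#' @return The warped matrix, same size as the input.
#' @export
apply_displacement <- function(image, nodes, total_elongation_px,
                               axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  check_scalar(total_elongation_px, "total_elongation_px", lower = 0)
  stopifnot(is.matrix(image), inherits(nodes, "profile_nodes"))
  if (total_elongation_px == 0) return(image)
  if (axis == "vertical") {
    return(t(apply_displacement(t(image), nodes, total_elongation_px,
                                "horizontal")))
  }
  w <- ncol(image)
  x_rel <- (seq_len(w) - 1) / (w - 1)
  u <- total_elongation_px * evaluate_profile(nodes, x_rel)
  src <- seq_len(w) - u
  src <- pmin(pmax(src, 1), w)
  x0 <- pmin(floor(src), w - 1L)
  fx <- src - x0
  out <- image[, x0, drop = FALSE] * rep(1 - fx, each = nrow(image)) +
    image[, x0 + 1L, drop = FALSE] * rep(fx, each = nrow(image))
  out
}

#' Specification of a synthetic force-elongation trace
#'
#' Emulates a tensile test on a pellicle clamped between an immobile plate
#' (force sensor) and a mobile plate: force rises linearly with pellicle
#' elongation from a (possibly negative) intercept, then drops abruptly at
#' failure. A negative intercept encodes a residual compressive force from
#' growth under confinement. For composite pellicles only a central fraction
#' of the plate travel is absorbed by the region whose stiffness is
#' prescribed; `central_fraction = 1` describes a uniformly deforming
#' (smooth-like) pellicle.
#'
#' @param stiffness_true slope of force vs. pellicle elongation, N/m
#'   (numerically identical to mN/mm).
#' @param intercept_true force at zero elongation, mN.
#' @param failure_elongation pellicle elongation at which the trace fails, mm
#'   (on the same axis as `central_fraction * plate displacement`).
#' @param post_failure_level force level transmitted after failure, mN.
#' @param noise_sd Gaussian force noise s.d., mN.
#' @param central_fraction fraction of plate travel absorbed by the reported
#'   region, in (0, 1].
#' @param baseline_offset constant sensor zero offset added to the whole
#'   record, mN; removed later by zero calibration.
#' @param seed integer RNG seed.
#' @export
force_trace_spec <- function(stiffness_true = 0.51, intercept_true = -1.2,
                             failure_elongation = 5, post_failure_level = 0,
                             noise_sd = 0.05, central_fraction = 1,
                             baseline_offset = 0, seed = 1L) {
  check_scalar(stiffness_true, "stiffness_true")
  check_scalar(intercept_true, "intercept_true")
  check_scalar(failure_elongation, "failure_elongation", lower = 0,
               strict_lower = TRUE)
  check_scalar(post_failure_level, "post_failure_level")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(central_fraction, "central_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(baseline_offset, "baseline_offset")
  structure(list(stiffness_true = stiffness_true,
                 intercept_true = intercept_true,
                 failure_elongation = failure_elongation,
                 post_failure_level = post_failure_level,
                 noise_sd = noise_sd, central_fraction = central_fraction,
                 baseline_offset = baseline_offset, seed = as.integer(seed)),
            class = "force_trace_spec")
}

#' Generate a synthetic force trace
#'
#' Samples at the protocol rate: plate displacement `d(t) = speed * t`,
#' pellicle elongation `e = central_fraction * d`. Before failure the force
#' is `intercept_true + stiffness_true * e` (1 N/m applied to mm gives mN);
#' at the first sample where `e >= failure_elongation` the force drops in a
#' single sample to `post_failure_level`. Seeded Gaussian noise and the
#' constant `baseline_offset` are added to the whole record. If the failure
#' elongation is beyond the protocol travel the trace never fails and is
#' flagged accordingly.
#'
#' @param spec a [force_trace_spec].
#' @param protocol a [pull_protocol].
#' @return A [force_trace] with channel `"force_mN"`; attribute
#'   `failure_expected` records whether failure occurs within travel.
#' @export
generate_force_trace <- function(spec, protocol = pull_protocol()) {
  stopifnot(inherits(spec, "force_trace_spec"), inherits(protocol, "pull_protocol"))
  speed_mm_s <- protocol$speed / 1000
  t_end <- protocol$max_travel / speed_mm_s
  time_s <- seq(0, t_end, by = protocol$sampling_interval / 1000)
  d <- speed_mm_s * time_s
  e <- spec$central_fraction * d
  force <- spec$intercept_true + spec$stiffness_true * e
  fail_idx <- which(e >= spec$failure_elongation)[1L]
  failed <- !is.na(fail_idx)
  if (failed) force[seq_along(force) >= fail_idx] <- spec$post_failure_level
  force <- force + spec$baseline_offset
  if (spec$noise_sd > 0) {
    force <- force + with_seed(spec$seed,
                               stats::rnorm(length(force), 0, spec$noise_sd))
  }
  tr <- force_trace(time_s = time_s, plate_displacement_mm = d,
                    signal = force, channel = "force_mN")
  attr(tr, "failure_expected") <- failed
  attr(tr, "protocol") <- protocol
  tr
}

#' Specification of a synthetic morphogenesis time-lapse
#'
#' Emulates top-view recordings of a pellicle forming in a rectangular dish:
#' a bright pellicle region whose boundary advances at a constant front
#' speed after an onset time, and, after a second onset, a sinusoidal
#' grey-level modulation of fixed wavelength inside the pellicle standing in
#' for periodic wrinkles.
#'
#' @param frame_interval minutes between frames.
#' @param duration recording length, hours.
#' @param pixel_size mm per pixel.
#' @param front_speed boundary speed, mm/h.
#' @param front_onset hours before the boundary starts to move.
#' @param front_start_mm initial boundary position along the probe axis, mm.
#' @param wrinkle_wavelength wrinkle spacing, mm.
#' @param wrinkle_onset hours at which wrinkles appear.
#' @param wrinkle_amplitude modulation amplitude, grey values.
#' @param dish_width,dish_height dish dimensions, mm (62 x 46 default).
#' @param pellicle_level,background grey levels of the pellicle region and
#'   of uncovered medium.
#' @param noise_sd additive Gaussian noise s.d., grey values.
#' @param seed integer RNG seed.
#' @export
timelapse_spec <- function(frame_interval = 15, duration = 9,
                           pixel_size = 0.05, front_speed = 0.25,
                           front_onset = 0, front_start_mm = NULL,
                           wrinkle_wavelength = 2.0, wrinkle_onset = Inf,
                           wrinkle_amplitude = 30, dish_width = 62,
                           dish_height = 46, pellicle_level = 170,
                           background = 50, noise_sd = 5, seed = 1L) {
  check_scalar(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_scalar(front_speed, "front_speed", lower = 0)
  check_scalar(wrinkle_wavelength, "wrinkle_wavelength", lower = 0,
               strict_lower = TRUE)
  if (wrinkle_wavelength < 2 * pixel_size) {
    stop_input("wrinkle_wavelength below 2 px is unresolvable")
  }
  front_start_mm <- front_start_mm %||% (0.3 * dish_width)
  structure(list(frame_interval = frame_interval, duration = duration,
                 pixel_size = pixel_size, front_speed = front_speed,
                 front_onset = front_onset, front_start_mm = front_start_mm,
                 wrinkle_wavelength = wrinkle_wavelength,
                 wrinkle_onset = wrinkle_onset,
                 wrinkle_amplitude = wrinkle_amplitude,
                 dish_width = dish_width, dish_height = dish_height,
                 pellicle_level = pellicle_level, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "timelapse_spec")
}

#' Generate a synthetic time-lapse stack
#'
#' The pellicle occupies columns left of the front; the front advances along
#' the horizontal axis at `front_speed` after `front_onset`. Frames after
#' `wrinkle_onset` carry a sinusoidal modulation of the pellicle grey level
#' with the configured wavelength. Noise is seeded per stack.
#'
#' @param spec a [timelapse_spec].
#' @return An [image_stack].
#' @export
generate_timelapse <- function(spec) {
  stopifnot(inherits(spec, "timelapse_spec"))
  w <- max(8L, round(spec$dish_width / spec$pixel_size))
  h <- max(8L, round(spec$dish_height / spec$pixel_size))
  times_h <- seq(0, spec$duration, by = spec$frame_interval / 60)
  x_mm <- (seq_len(w) - 0.5) * spec$pixel_size
  with_seed(spec$seed, {
    frames <- lapply(times_h, function(t) {
      front <- spec$front_start_mm +
        spec$front_speed * max(0, t - spec$front_onset)
      row_vals <- ifelse(x_mm <= front, spec$pellicle_level, spec$background)
      if (t >= spec$wrinkle_onset) {
        wr <- spec$wrinkle_amplitude *
          sin(2 * pi * x_mm / spec$wrinkle_wavelength)
        row_vals <- row_vals + ifelse(x_mm <= front, wr, 0)
      }
      fr <- matrix(rep(row_vals, each = h), nrow = h, ncol = w)
      if (spec$noise_sd > 0) {
        fr <- fr + matrix(stats::rnorm(w * h, 0, spec$noise_sd), h, w)
      }
      clip_grey(fr)
    })
    image_stack(frames, times_h, spec$pixel_size)
  })
}
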