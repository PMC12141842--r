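# Reduction of a 2-D displacement field to the 1-D deformation profile of a
# stretched pellicle (relative displacement vs. relative position along the
# elongation axis), with affine and continuous piecewise-linear fits, region
# elongation fractions and a mechanical classification of the regions.

#' Construct a deformation profile
#'
#' @param x_rel relative positions along the elongation axis, 0 = immobile
#'   plate (force sensor side), 1 = mobile plate.
#' @param u_rel relative displacement magnitudes (fractions of the applied
#'   elongation).
#' @param applied_elongation_mm total plate translation for the image pair.
#' @param error_rel per-point uncertainty in relative units (one pixel of
#'   PIV resolution divided by the applied elongation in px).
#' @return A `deformation_profile` data frame with columns `x_rel`, `u_rel`.
#' @export
deformation_profile <- function(x_rel, u_rel, applied_elongation_mm = NA_real_,
                                error_rel = NA_real_) {
  if (length(x_rel) != length(u_rel)) stop_input("x_rel and u_rel lengths differ")
  if (any(x_rel < -1e-9) || any(x_rel > 1 + 1e-9)) {
    stop_input("x_rel must lie in [0, 1]")
  }
  o <- order(x_rel)
  structure(data.frame(x_rel = x_rel[o], u_rel = u_rel[o]),
            applied_elongation_mm = applied_elongation_mm,
            error_rel = error_rel,
            class = c("deformation_profile", "data.frame"))
}

#' Deformation profile from a PIV displacement field
#'
#' Collapses the field along the transverse direction: at each longitudinal
#' station (grid column) the valid axial displacements are summarised by
#' their median (robust to edge menisci and stray vectors). Positions are
#' mapped to relative coordinates between the two plate positions;
#' because a tensile force deflects the cantilever, the "immobile" plate is
#' shifted toward the mobile one by `sensor_correction_mm` before the
#' mapping. Displacements are divided by the applied elongation.
#'
#' @param field a `displacement_field` (ideally after [validate_field]).
#' @param immobile_x_px,mobile_x_px plate positions in image-A pixel
#'   coordinates (columns); mobile must exceed immobile.
#' @param applied_elongation_mm total plate translation for the pair, > 0.
#' @param pixel_size mm per pixel (default 1, i.e. work in pixels).
#' @param sensor_correction_mm deflection of the immobile plate
#'   (force / sensor stiffness), mm.
#' @return A [deformation_profile]; stations without any valid vector are
#'   omitted and recorded in attribute `dropped_stations`.
#' @export
profile_from_field <- function(field, immobile_x_px, mobile_x_px,
                               applied_elongation_mm, pixel_size = 1,
                               sensor_correction_mm = 0) {
  stopifnot(inherits(field, "displacement_field"))
  if (mobile_x_px <= immobile_x_px) {
    stop_input("mobile_x_px must exceed immobile_x_px")
  }
  check_scalar(applied_elongation_mm, "applied_elongation_mm", lower = 0,
               strict_lower = TRUE)
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  imm_px <- immobile_x_px + sensor_correction_mm / pixel_size
  span_px <- mobile_x_px - imm_px
  elong_px <- applied_elongation_mm / pixel_size
  nx <- length(field$x)
  u_med <- rep(NA_real_, nx)
  for (j in seq_len(nx)) {
    ok <- field$valid[, j] & is.finite(field$u[, j])
    if (any(ok)) u_med[j] <- stats::median(field$u[ok, j])
  }
  keep <- is.finite(u_med)
  x_rel <- (field$x[keep] - imm_px) / span_px
  inside <- x_rel >= 0 & x_rel <= 1
  prof <- deformation_profile(x_rel[inside], u_med[keep][inside] / elong_px,
                              applied_elongation_mm = applied_elongation_mm,
                              error_rel = 1 / elong_px)
  attr(prof, "dropped_stations") <- which(!keep)
  prof
}

#' Affine fit of a deformation profile
#'
#' Least-squares line of relative displacement on relative position: the
#' expected profile of a homogeneous elastic sheet is the first bisector
#' (slope 1, intercept 0). A low coefficient of determination signals
#' departure from homogeneous elasticity.
#'
#' @param profile a [deformation_profile] (>= 3 points).
#' @return An `affine_fit` list: `slope`, `intercept`, `r_squared`.
#' @export
fit_affine <- function(profile) {
  stopifnot(inherits(profile, "deformation_profile"))
  if (nrow(profile) < 3L) stop_input("need at least 3 profile points")
  if (stats::sd(profile$x_rel) <= 0) stop_input("degenerate x_rel spread")
  fit <- stats::lm(u_rel ~ x_rel, data = profile)
  sst <- sum((profile$u_rel - mean(profile$u_rel))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = if (sst > 0) {
                   1 - sum(stats::resid(fit)^2) / sst
                 } else NA_real_),
            class = "affine_fit")
}

# Hinge-basis design matrix for a continuous piecewise-linear model with
# breakpoints b: u = c0 + c1 x + sum_i g_i (x - b_i)_+
pw_design <- function(x, breaks) {
  X <- cbind(1, x)
  for (b in breaks) X <- cbind(X, pmax(x - b, 0))
  X
}

pw_predict_coef <- function(coef, breaks, x) {
  drop(pw_design(x, breaks) %*% coef)
}

#' Continuous piecewise-linear fit of a deformation profile
#'
#' Fits a continuous piecewise-linear model with `n_segments - 1` interior
#' breakpoints by exhaustive search over a regular breakpoint grid (step
#' `grid_step` in relative units), minimising the sum of squared residuals.
#' Continuity is enforced through a hinge basis; each candidate breakpoint
#' configuration must leave at least `min_points` data points per segment.
#' Ties are broken deterministically in favour of the leftmost breakpoints.
#' The fitted model is summarised as profile nodes at x = 0, the
#' breakpoints, and x = 1 (end segments extrapolated to the plates).
#'
#' @param profile a [deformation_profile].
#' @param n_segments number of linear segments (>= 1).
#' @param grid_step breakpoint grid resolution in relative units
#'   (default 0.01).
#' @param min_points minimum data points per segment (default 2).
#' @return A `piecewise_fit`: list with `breakpoints`, `coefficients`,
#'   `nodes` ([profile_nodes] of the fitted model), `sse`, `n_segments`.
#' @export
fit_piecewise <- function(profile, n_segments = 4, grid_step = 0.01,
                          min_points = 2L) {
  stopifnot(inherits(profile, "deformation_profile"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop_input("n_segments must be >= 1")
  x <- profile$x_rel; yv <- profile$u_rel
  if (nrow(profile) < (n_segments + 1L) * min_points + 1L) {
    stop_input("too few points for the requested number of segments")
  }
  k <- n_segments - 1L
  if (k == 0L) {
    fit <- stats::lm.fit(pw_design(x, numeric(0)), yv)
    return(pw_result(fit$coefficients, numeric(0), sum(fit$residuals^2),
                     n_segments))
  }
  lo <- min(x) + grid_step
  hi <- max(x) - grid_step
  cand <- seq(ceiling(lo / grid_step) * grid_step,
              floor(hi / grid_step) * grid_step, by = grid_step)
  if (length(cand) < k) stop_input("breakpoint grid too coarse for n_segments")
  # hinge columns precomputed once per candidate
  hinges <- vapply(cand, function(b) pmax(x - b, 0), numeric(length(x)))
  n_le <- vapply(cand, function(b) sum(x <= b), integer(1L))  # points left of b
  base <- cbind(1, x)
  combos <- utils::combn(length(cand), k)
  best_sse <- Inf
  best <- NULL
  npts <- length(x)
  for (ci in seq_len(ncol(combos))) {
    idx <- combos[, ci]
    counts <- c(n_le[idx], npts) - c(0L, n_le[idx])
    if (any(counts < min_points)) next
    X <- cbind(base, hinges[, idx, drop = FALSE])
    fit <- stats::lm.fit(X, yv)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- list(coef = fit$coefficients, breaks = cand[idx])
    }
  }
  if (is.null(best)) stop_input("no admissible breakpoint configuration")
  pw_result(best$coef, best$breaks, best_sse, n_segments)
}

pw_result <- function(coef, breaks, sse, n_segments) {
  node_x <- c(0, breaks, 1)
  node_u <- pw_predict_coef(coef, breaks, node_x)
  structure(list(breakpoints = breaks, coefficients = unname(coef),
                 nodes = profile_nodes(node_x, node_u),
                 sse = sse, n_segments = n_segments),
            class = "piecewise_fit")
}

#' @export
predict.piecewise_fit <- function(object, x_rel, ...) {
  pw_predict_coef(object$coefficients, object$breakpoints, x_rel)
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("piecewise fit: %d segments, sse = %.4g\n", x$n_segments, x$sse))
  if (length(x$breakpoints)) {
    cat("breakpoints:", paste(sprintf("%.3f", x$breakpoints), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Elongation fraction absorbed by a region
#'
#' Share of the total applied elongation taken up by the pellicle between
#' two relative positions: `u_rel(x_hi) - u_rel(x_lo)` evaluated on the
#' fitted (or prescribed) profile. Fractions over a partition of \[0, 1\]
#' sum to 1.
#'
#' @param fit a `piecewise_fit`, or [profile_nodes] evaluated directly.
#' @param interval numeric length-2, relative positions `(x_lo, x_hi)`.
#' @return The elongation fraction (dimensionless).
#' @export
region_elongation_fraction <- function(fit, interval) {
  if (length(interval) != 2L || interval[1L] >= interval[2L] ||
      interval[1L] < -1e-9 || interval[2L] > 1 + 1e-9) {
    stop_input("interval must be (x_lo, x_hi) within [0, 1]")
  }
  u <- if (inherits(fit, "piecewise_fit")) {
    predict(fit, interval)
  } else if (inherits(fit, "profile_nodes")) {
    evaluate_profile(fit, interval)
  } else stop_input("fit must be a piecewise_fit or profile_nodes")
  u[2L] - u[1L]
}

#' Mechanical classification of fitted profile segments
#'
#' Labels each linear segment of a piecewise fit by its deformation regime:
#' * `rigid_translation` - local slope at most `rigid_slope_max`: matter
#'   translates without measurable deformation;
#' * `step` - a narrow segment (width at most `step_width_max`) with slope
#'   above 1: a quasi-discontinuous jump in displacement next to a clamp;
#' * `soft` - the first segment, adjoining the immobile plate, with slope
#'   above 1: an easily deformable edge region;
#' * `central` - everything else (ordinary elastic stretching).
#'
#' @param fit a `piecewise_fit` (or [profile_nodes]).
#' @param rigid_slope_max slope threshold for rigid translation (default 0.1).
#' @param step_width_max maximum relative width of a step segment
#'   (default 0.1).
#' @return A data frame with one row per segment: `x_lo`, `x_hi`, `slope`,
#'   `elongation_fraction`, `class`.
#' @export
classify_regions <- function(fit, rigid_slope_max = 0.1, step_width_max = 0.1) {
  nodes <- if (inherits(fit, "piecewise_fit")) fit$nodes
  else if (inherits(fit, "profile_nodes")) fit
  else stop_input("fit must be a piecewise_fit or profile_nodes")
  ns <- nrow(nodes) - 1L
  out <- data.frame(x_lo = nodes$x_rel[-(ns + 1L)], x_hi = nodes$x_rel[-1L])
  out$elongation_fraction <- diff(nodes$u_rel)
  out$slope <- out$elongation_fraction / (out$x_hi - out$x_lo)
  out$class <- vapply(seq_len(ns), function(i) {
    sl <- out$slope[i]; wd <- out$x_hi[i] - out$x_lo[i]
    if (sl <= rigid_slope_max) "rigid_translation"
    else if (wd <= step_width_max && sl > 1) "step"
    else if (i == 1L && out$x_lo[i] <= 1e-9 && sl > 1) "soft"
    else "central"
  }, character(1L))
  out[, c("x_lo", "x_hi", "slope", "elongation_fraction", "class")]
}
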