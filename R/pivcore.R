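# Particle image velocimetry by direct normalized cross-correlation of
# interrogation windows inside larger search windows, with subpixel peak
# refinement and neighbourhood-median outlier validation. Pellicle
# inhomogeneities act as the tracer pattern; the displacement field between
# an image pair taken at two elongation values maps the local deformation.

#' Convert a colour image to grayscale
#'
#' Luminance-weighted combination of the three channels (Rec. 709 weights by
#' default). Single-channel input passes through unchanged.
#'
#' @param image a numeric matrix (already grayscale) or an
#'   height x width x 3 array.
#' @param weights channel weights, summing to 1.
#' @return A numeric matrix.
#' @export
to_grayscale <- function(image, weights = c(0.2126, 0.7152, 0.0722)) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3L] == 3L) {
    w <- weights / sum(weights)
    return(image[, , 1L] * w[1L] + image[, , 2L] * w[2L] + image[, , 3L] * w[3L])
  }
  stop_input("unsupported channel count: expected a matrix or an h x w x 3 array")
}

#' PIV configuration
#'
#' @param interrogation_px side of the square interrogation (template)
#'   window, px.
#' @param search_px side of the square search window, px; must exceed
#'   `interrogation_px`.
#' @param overlap_fraction window overlap in \[0, 1); 0.5 gives a grid stride
#'   of half a window.
#' @param subpixel subpixel peak estimator: three-point Gaussian
#'   (`"gaussian3"`, default; falls back to parabolic when a neighbour score
#'   is non-positive), `"parabolic"`, or `"none"`.
#' @param min_contrast minimum grey-level s.d. of a template for the window
#'   to be correlated; flatter windows yield invalid vectors instead of
#'   spurious peaks.
#' @export
piv_config <- function(interrogation_px = 32, search_px = 50,
                       overlap_fraction = 0.5,
                       subpixel = c("gaussian3", "parabolic", "none"),
                       min_contrast = 1) {
  subpixel <- match.arg(subpixel)
  check_scalar(interrogation_px, "interrogation_px", lower = 8)
  check_scalar(search_px, "search_px", lower = 8)
  if (search_px <= interrogation_px) {
    stop_input("search_px must be strictly larger than interrogation_px")
  }
  check_scalar(overlap_fraction, "overlap_fraction", lower = 0, upper = 1 - 1e-9)
  check_scalar(min_contrast, "min_contrast", lower = 0)
  structure(list(interrogation_px = as.integer(interrogation_px),
                 search_px = as.integer(search_px),
                 overlap_fraction = overlap_fraction, subpixel = subpixel,
                 min_contrast = min_contrast),
            class = "piv_config")
}

#' Normalized cross-correlation surface between a template and a search window
#'
#' Scores are computed at every integer lag placing the template fully inside
#' the search window. Both windows are centred and scaled (zero mean, unit
#' variance), so scores lie in \[-1, 1\] and are comparable across
#' illumination levels. Lags follow the motion of matter from the template's
#' image to the search window's image: if the pattern moved by +3 px, the
#' peak sits at lag +3.
#'
#' @param template square numeric matrix (interrogation window from image A).
#' @param search larger square numeric matrix (search window from image B,
#'   centred on the same location).
#' @return A matrix of correlation scores with attributes `lag_x`, `lag_y`
#'   (integer lags per column/row) and `valid` (FALSE for a zero-variance
#'   template, in which case all scores are NA).
#' @export
correlate <- function(template, search) {
  stopifnot(is.matrix(template), is.matrix(search))
  n <- nrow(template)
  if (ncol(template) != n || nrow(search) != ncol(search)) {
    stop_input("template and search windows must be square")
  }
  m <- nrow(search)
  if (m <= n) stop_input("search window must be strictly larger than template")
  nl <- m - n + 1L
  off <- floor((m - n) / 2)
  lags <- (0:(m - n)) - off
  tm <- template - mean(template)
  tss <- sqrt(sum(tm^2))
  surf <- matrix(NA_real_, nl, nl)
  valid <- tss > 0
  if (valid) {
    for (iy in seq_len(nl)) {
      ys <- iy:(iy + n - 1L)
      for (ix in seq_len(nl)) {
        patch <- search[ys, ix:(ix + n - 1L)]
        pm <- patch - mean(patch)
        pss <- sqrt(sum(pm^2))
        surf[iy, ix] <- if (pss > 0) sum(tm * pm) / (tss * pss) else 0
      }
    }
  }
  structure(surf, lag_x = lags, lag_y = lags, valid = valid)
}

#' Subpixel refinement of a correlation peak
#'
#' Locates the integer maximum of a correlation surface and refines it
#' independently per axis with a three-point fit through the peak and its two
#' axis neighbours. The Gaussian estimator uses log-scores and requires all
#' three to be positive; otherwise (or when configured) a parabolic fit is
#' used. The refinement is bounded to +/- 0.5 px. A peak on the surface
#' border cannot be refined and is returned at integer precision, flagged.
#'
#' @param surface a correlation surface from [correlate] (lag attributes
#'   optional; row/column indices are used when absent).
#' @param method `"gaussian3"`, `"parabolic"` or `"none"`.
#' @return A list with `dx`, `dy` (real lags), `peak_value`, and `border`
#'   (TRUE when the integer peak touched the surface border).
#' @export
subpixel_peak <- function(surface, method = c("gaussian3", "parabolic", "none")) {
  method <- match.arg(method)
  stopifnot(is.matrix(surface))
  lag_x <- attr(surface, "lag_x") %||% seq_len(ncol(surface))
  lag_y <- attr(surface, "lag_y") %||% seq_len(nrow(surface))
  pk <- which(surface == max(surface, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  iy <- pk[[1L]]; ix <- pk[[2L]]
  border <- iy == 1L || iy == nrow(surface) || ix == 1L || ix == ncol(surface)
  refine1 <- function(rm, r0, rp) {
    if (method == "none") return(0)
    # an exact match already attains the correlation bound: any fractional
    # shift could only reduce it, so the peak is at the integer lag
    if (r0 >= 1 - 1e-9) return(0)
    use_gauss <- method == "gaussian3" && rm > 0 && r0 > 0 && rp > 0
    d <- if (use_gauss) {
      den <- 2 * (log(rm) + log(rp) - 2 * log(r0))
      if (abs(den) < 1e-300) 0 else (log(rm) - log(rp)) / den
    } else {
      den <- 2 * (rm - 2 * r0 + rp)
      if (abs(den) < 1e-300) 0 else (rm - rp) / den
    }
    max(-0.5, min(0.5, d))
  }
  if (border || method == "none") {
    return(list(dx = lag_x[ix], dy = lag_y[iy],
                peak_value = surface[iy, ix], border = border))
  }
  ddx <- refine1(surface[iy, ix - 1L], surface[iy, ix], surface[iy, ix + 1L])
  ddy <- refine1(surface[iy - 1L, ix], surface[iy, ix], surface[iy + 1L, ix])
  list(dx = lag_x[ix] + ddx, dy = lag_y[iy] + ddy,
       peak_value = surface[iy, ix], border = FALSE)
}

# Ratio of the highest correlation peak to the highest score outside its
# 3x3 neighbourhood; large ratios indicate unambiguous matches.
peak_ratio <- function(surface) {
  pk <- which(surface == max(surface, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  masked <- surface
  ys <- max(1L, pk[[1L]] - 1L):min(nrow(surface), pk[[1L]] + 1L)
  xs <- max(1L, pk[[2L]] - 1L):min(ncol(surface), pk[[2L]] + 1L)
  masked[ys, xs] <- NA
  second <- suppressWarnings(max(masked, na.rm = TRUE))
  p1 <- surface[pk[[1L]], pk[[2L]]]
  if (!is.finite(second) || second <= 0 || p1 <= 0) return(Inf)
  max(1, p1 / second)
}

#' Compute a gridded displacement field between two images
#'
#' Slices the pair into interrogation windows on a regular grid (stride set
#' by the overlap fraction, grid anchored so every search window fits inside
#' the frame), correlates each window of image A against the search window of
#' image B centred on the same location, and refines each peak to subpixel
#' precision. The sign convention is the motion of matter from A to B.
#'
#' @param imgA,imgB numeric grey-level matrices of identical size.
#' @param config a [piv_config].
#' @return A `displacement_field`: list with window-centre coordinates `x`,
#'   `y` (px), matrices `u`, `v` (px), `valid`, `peak_quality` and `status`
#'   (`"ok"`, `"flat"` for low-contrast templates, `"border"` for
#'   unrefinable border peaks).
#' @export
compute_field <- function(imgA, imgB, config = piv_config()) {
  stopifnot(is.matrix(imgA), is.matrix(imgB))
  if (!all(dim(imgA) == dim(imgB))) stop_input("images must have equal shapes")
  n <- config$interrogation_px; s <- config$search_px
  off <- floor((s - n) / 2)
  h <- nrow(imgA); w <- ncol(imgA)
  t_min <- off + 1L
  tx_max <- w - s + 1L + off
  ty_max <- h - s + 1L + off
  if (tx_max < t_min || ty_max < t_min) {
    stop_input("images too small for the configured windows")
  }
  stride <- max(1L, round(n * (1 - config$overlap_fraction)))
  tx0 <- seq(t_min, tx_max, by = stride)
  ty0 <- seq(t_min, ty_max, by = stride)
  nx <- length(tx0); ny <- length(ty0)
  u <- v <- pq <- matrix(NA_real_, ny, nx)
  status <- matrix("ok", ny, nx)
  for (j in seq_len(nx)) {
    xs_t <- tx0[j]:(tx0[j] + n - 1L)
    xs_s <- (tx0[j] - off):(tx0[j] - off + s - 1L)
    for (i in seq_len(ny)) {
      ys_t <- ty0[i]:(ty0[i] + n - 1L)
      tmpl <- imgA[ys_t, xs_t]
      if (stats::sd(tmpl) < config$min_contrast) {
        status[i, j] <- "flat"
        next
      }
      srch <- imgB[(ty0[i] - off):(ty0[i] - off + s - 1L), xs_s]
      surf <- correlate(tmpl, srch)
      if (!attr(surf, "valid")) {
        status[i, j] <- "flat"
        next
      }
      pk <- subpixel_peak(surf, config$subpixel)
      u[i, j] <- pk$dx
      v[i, j] <- pk$dy
      pq[i, j] <- peak_ratio(surf)
      if (pk$border) status[i, j] <- "border"
    }
  }
  structure(list(x = tx0 + (n - 1) / 2, y = ty0 + (n - 1) / 2,
                 u = u, v = v, valid = status == "ok", peak_quality = pq,
                 status = status, config = config),
            class = "displacement_field")
}

#' @export
as.data.frame.displacement_field <- function(x, ...) {
  grid <- expand.grid(y_px = x$y, x_px = x$x)
  data.frame(x_px = grid$x_px, y_px = grid$y_px,
             u_px = as.vector(x$u), v_px = as.vector(x$v),
             valid = as.vector(x$valid),
             peak_quality = as.vector(x$peak_quality))
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement field: %d x %d vectors, %d valid (%.1f%%)\n",
              nrow(x$u), ncol(x$u), sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Validate a displacement field with a neighbourhood median test
#'
#' Each vector is compared with the median of its valid 3x3 neighbourhood
#' (centre included, so the test stays unbiased at the grid border, where a
#' centre-excluded median systematically leads or lags on a displacement
#' gradient). Vectors deviating from that median by more than
#' `median_k * max(MAD, eps)` in either component are flagged as outliers
#' and replaced by the median of their valid neighbours (centre excluded);
#' vectors already invalid (flat or border windows) are likewise filled
#' from their neighbourhood. `eps` is a noise floor preventing zero-MAD
#' neighbourhoods on perfectly uniform fields from flagging everything.
#'
#' @param field a `displacement_field`.
#' @param median_k threshold in local-MAD units (default 3).
#' @param eps MAD noise floor, px (default 0.1).
#' @return The field with `u`, `v` repaired, `valid` updated, and a
#'   `replaced` logical matrix marking substituted vectors.
#' @export
validate_field <- function(field, median_k = 3, eps = 0.1) {
  stopifnot(inherits(field, "displacement_field"))
  ny <- nrow(field$u); nx <- ncol(field$u)
  u <- field$u; v <- field$v
  ok <- field$valid & is.finite(u) & is.finite(v)
  new_u <- u; new_v <- v
  replaced <- matrix(FALSE, ny, nx)
  for (j in seq_len(nx)) {
    for (i in seq_len(ny)) {
      ys <- max(1L, i - 1L):min(ny, i + 1L)
      xs <- max(1L, j - 1L):min(nx, j + 1L)
      hood <- ok[ys, xs]
      nb <- hood
      nb[ys == i, xs == j] <- FALSE
      if (!any(nb)) next
      nu <- u[ys, xs][nb]; nv <- v[ys, xs][nb]
      if (!ok[i, j]) {
        new_u[i, j] <- stats::median(nu)
        new_v[i, j] <- stats::median(nv)
        replaced[i, j] <- TRUE
        next
      }
      hu <- u[ys, xs][hood]; hv <- v[ys, xs][hood]
      med_u <- stats::median(hu); med_v <- stats::median(hv)
      mad_u <- stats::median(abs(hu - med_u))
      mad_v <- stats::median(abs(hv - med_v))
      if (abs(u[i, j] - med_u) > median_k * max(mad_u, eps) ||
          abs(v[i, j] - med_v) > median_k * max(mad_v, eps)) {
        new_u[i, j] <- stats::median(nu)
        new_v[i, j] <- stats::median(nv)
        replaced[i, j] <- TRUE
      }
    }
  }
  field$u <- new_u; field$v <- new_v
  field$valid <- (field$valid | replaced) & is.finite(new_u)
  field$replaced <- replaced
  field
}
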