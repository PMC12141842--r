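# File formats: 8/16-bit TIFF and PNG images (via the tiff and png
# packages, grey values scaled to 0-255 in memory), multi-page TIFF stacks
# with a CSV time manifest, force traces as CSV with a channel header, and
# displacement fields / profiles as CSV.

#' Read a grayscale image
#'
#' Reads a TIFF or PNG file, converts colour to grayscale with
#' [to_grayscale], and scales intensities to the 0-255 grey range.
#'
#' @param path image file (`.tif`, `.tiff` or `.png`).
#' @return Numeric grey-level matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop_input("unsupported image format: ", ext))
  if (length(dim(raw)) == 3L && dim(raw)[3L] == 4L) raw <- raw[, , 1:3]
  to_grayscale(raw) * 255
}

#' Write a grayscale image
#'
#' TIFF output is 16-bit; PNG output is 8-bit.
#'
#' @param image grey-level matrix (0-255).
#' @param path output file; format chosen by extension (`.tif`/`.png`).
#' @export
write_image <- function(image, path) {
  scaled <- clip_grey(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 16L),
         png = png::writePNG(scaled, path),
         stop_input("unsupported image format: ", ext))
  invisible(path)
}

#' Write an image stack as multi-page TIFF plus a CSV manifest
#'
#' @param stack an [image_stack].
#' @param tiff_path output multi-page TIFF.
#' @param manifest_path output CSV with columns `frame`, `time_h`,
#'   `pixel_size_mm` (default: TIFF path with `.csv` appended).
#' @export
write_stack <- function(stack, tiff_path,
                        manifest_path = paste0(tiff_path, ".csv")) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(lapply(stack$frames, function(f) clip_grey(f) / 255),
                  tiff_path, bits.per.sample = 16L)
  utils::write.csv(data.frame(frame = seq_along(stack$times_h),
                              time_h = stack$times_h,
                              pixel_size_mm = stack$pixel_size),
                   manifest_path, row.names = FALSE)
  invisible(tiff_path)
}

#' Read an image stack written by [write_stack]
#'
#' @param tiff_path multi-page TIFF.
#' @param manifest_path CSV manifest with `time_h` and `pixel_size_mm`.
#' @return An [image_stack].
#' @export
read_stack <- function(tiff_path, manifest_path = paste0(tiff_path, ".csv")) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  man <- utils::read.csv(manifest_path)
  frames <- lapply(pages, function(p) to_grayscale(p) * 255)
  image_stack(frames, man$time_h, man$pixel_size_mm[1L])
}

#' Write a force trace as CSV
#'
#' The first line is a comment header declaring the signal channel
#' (`# channel=force_mN` or `# channel=deflection_um`), followed by columns
#' `time_s`, `plate_displacement_mm`, `signal`.
#'
#' @param trace a `force_trace`.
#' @param path output CSV.
#' @export
write_force_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# channel=", attr(trace, "channel")), con)
  utils::write.csv(data.frame(time_s = trace$time_s,
                              plate_displacement_mm = trace$plate_displacement_mm,
                              signal = trace$raw_signal),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a force trace written by [write_force_trace_csv]
#'
#' @param path CSV file with a `# channel=` header line.
#' @return A `force_trace`.
#' @export
read_force_trace_csv <- function(path) {
  first <- readLines(path, n = 1L)
  channel <- if (grepl("^#\\s*channel=", first)) {
    sub("^#\\s*channel=", "", first)
  } else "force_mN"
  if (!channel %in% c("force_mN", "deflection_um")) {
    stop_input("unknown channel declaration: ", channel)
  }
  df <- utils::read.csv(path, comment.char = "#")
  force_trace(df$time_s, df$plate_displacement_mm, df$signal,
              channel = channel)
}

#' Write a displacement field as CSV
#'
#' Columns: `x_px`, `y_px`, `u_px`, `v_px`, `valid`, `peak_quality`.
#' @param field a `displacement_field`.
#' @param path output CSV.
#' @export
write_field_csv <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}

#' Read a displacement field written by [write_field_csv]
#'
#' @param path CSV file.
#' @return A `displacement_field` (status reconstructed from the valid flag).
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  xs <- sort(unique(df$x_px)); ys <- sort(unique(df$y_px))
  df <- df[order(df$x_px, df$y_px), ]
  shape <- c(length(ys), length(xs))
  structure(list(x = xs, y = ys,
                 u = matrix(df$u_px, shape[1L], shape[2L]),
                 v = matrix(df$v_px, shape[1L], shape[2L]),
                 valid = matrix(df$valid, shape[1L], shape[2L]),
                 peak_quality = matrix(df$peak_quality, shape[1L], shape[2L]),
                 status = matrix(ifelse(df$valid, "ok", "flat"),
                                 shape[1L], shape[2L]),
                 config = NULL),
            class = "displacement_field")
}

#' Export a deformation profile and its fits as CSV
#'
#' Columns: `x_rel`, `u_rel`, `u_fit`, `residual`.
#' @param profile a [deformation_profile].
#' @param fit optional `piecewise_fit` or `affine_fit` supplying `u_fit`.
#' @param path output CSV.
#' @export
write_profile_csv <- function(profile, path, fit = NULL) {
  u_fit <- if (inherits(fit, "piecewise_fit")) {
    predict(fit, profile$x_rel)
  } else if (inherits(fit, "affine_fit")) {
    fit$intercept + fit$slope * profile$x_rel
  } else rep(NA_real_, nrow(profile))
  utils::write.csv(data.frame(x_rel = profile$x_rel, u_rel = profile$u_rel,
                              u_fit = u_fit,
                              residual = profile$u_rel - u_fit),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a piecewise fit (nodes, sse, classes) as JSON
#'
#' @param fit a `piecewise_fit`.
#' @param path output JSON file.
#' @param ... arguments passed to [classify_regions].
#' @export
write_fit_json <- function(fit, path, ...) {
  stopifnot(inherits(fit, "piecewise_fit"))
  jsonlite::write_json(list(nodes = as.data.frame(fit$nodes),
                            breakpoints = fit$breakpoints,
                            sse = fit$sse, n_segments = fit$n_segments,
                            regions = classify_regions(fit, ...)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
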