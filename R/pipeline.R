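# Reproducible runs: a validated configuration tree drives synthetic-data
# generation and the analysis stages (PIV -> deformation profile, mechanics,
# kinetics), with seeded determinism and a JSON report carrying provenance.
# The thin command-line wrapper in inst/cli/pellimetry dispatches to these
# functions.

config_schema <- list(
  top = c("seed", "outdir", "log_level", "synth", "piv", "profile", "mech",
          "kinetics"),
  synth = c("speckle", "profile", "elongation_px", "pair_noise_sd", "force",
            "timelapse"),
  piv = c("interrogation_px", "search_px", "overlap_fraction", "subpixel",
          "min_contrast", "median_k"),
  profile = c("n_segments", "grid_step", "rigid_slope_max", "step_width_max"),
  mech = c("drop_fraction", "window_samples", "min_force",
           "post_failure_window", "fit_range", "central_fraction",
           "initial_gap"),
  kinetics = c("probe", "level", "band")
)

#' Default run configuration
#'
#' A nested list mirroring the pipeline stages. The synthetic block defaults
#' to the rough-pellicle scenario: a speckle pair warped by the canonical
#' rough profile, three smooth-like and three rough-like force traces, and a
#' time-lapse with a moving front and periodic wrinkles.
#'
#' @param seed global seed; every stochastic stage derives its seed from it.
#' @param outdir output directory for generated data and reports.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, outdir = "pellimetry-run") {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    log_level = "info",
    synth = list(
      speckle = list(width_px = 800L, height_px = 400L, grain_density = 5,
                     grain_radius_px = 2, contrast = 0.6,
                     background_level = 60, noise_sd = 2),
      profile = "rough",
      elongation_px = 12,
      pair_noise_sd = 2,
      force = list(
        smooth = list(stiffness_true = 0.51, intercept_true = -1.2,
                      failure_elongation = 5, noise_sd = 0.05,
                      central_fraction = 1, n = 3L),
        rough = list(stiffness_true = 5.1, intercept_true = 0,
                     failure_elongation = 1.2, noise_sd = 0.1,
                     central_fraction = 0.27, n = 3L)),
      timelapse = list(frame_interval = 15, duration = 9, pixel_size = 0.05,
                       front_speed = 0.25, wrinkle_wavelength = 2.0,
                       wrinkle_onset = 5, wrinkle_amplitude = 30,
                       dish_width = 62, dish_height = 8, noise_sd = 5)),
    piv = list(interrogation_px = 32L, search_px = 50L,
               overlap_fraction = 0.5, subpixel = "gaussian3",
               min_contrast = 1, median_k = 3),
    profile = list(n_segments = 4L, grid_step = 0.01,
                   rigid_slope_max = 0.1, step_width_max = 0.1),
    mech = list(drop_fraction = 0.5, window_samples = 5L, min_force = 0.5,
                post_failure_window = 2, fit_range = c(0.05, 0.90),
                initial_gap = 13.5),
    kinetics = list(level = 110, band = c(1, 4))),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Checks the key schema (unknown keys are rejected, naming the offender)
#' and basic value sanity. A config read back from YAML validates to the
#' same result as the in-memory original.
#'
#' @param config a configuration list (e.g. from [default_config] or
#'   [read_config_yaml]).
#' @return The validated config, classed `run_config`.
#' @export
validate_config <- function(config) {
  check_keys <- function(block, allowed, where) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown)) {
      stop_input("unknown config key(s) in ", where, ": ",
                 paste(unknown, collapse = ", "))
    }
  }
  check_keys(config, config_schema$top, "top level")
  for (blk in c("synth", "piv", "profile", "mech", "kinetics")) {
    if (!is.null(config[[blk]])) {
      check_keys(config[[blk]], config_schema[[blk]], blk)
    }
  }
  if (is.null(config$seed)) stop_input("config must declare a seed")
  check_scalar(config$seed, "seed")
  if (!is.null(config$synth$speckle$noise_sd) &&
      config$synth$speckle$noise_sd < 0) {
    stop_input("invalid value for field 'noise_sd': must be >= 0")
  }
  structure(config, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; missing blocks fall back to [default_config]
#'   values.
#' @return A validated `run_config`.
#' @export
read_config_yaml <- function(path) {
  usr <- yaml::read_yaml(path)
  base <- default_config(seed = usr$seed %||% 1L)
  merged <- utils::modifyList(unclass(base), usr)
  validate_config(merged)
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output YAML file.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

synth_paths <- function(outdir) {
  list(imgA = file.path(outdir, "speckle_A.tif"),
       imgB = file.path(outdir, "speckle_B.tif"),
       truth = file.path(outdir, "displacement_truth.csv"),
       stack = file.path(outdir, "timelapse.tif"),
       manifest = file.path(outdir, "synth_manifest.json"))
}

#' Generate all synthetic inputs for a pipeline run
#'
#' Writes the speckle image pair (before/after warping by the configured
#' profile), a ground-truth displacement CSV, force-trace CSVs for each
#' configured scenario and replicate, the time-lapse stack with its time
#' manifest, and a JSON manifest recording the spec and seeds.
#'
#' @param config a validated `run_config`.
#' @return Invisibly, the list of written file paths.
#' @export
run_synth <- function(config) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- synth_paths(outdir)
  sy <- config$synth
  seed <- config$seed

  sp <- do.call(speckle_spec, c(sy$speckle, list(seed = seed)))
  imgA <- generate_speckle(sp)
  nodes <- if (identical(sy$profile, "rough")) canonical_rough_nodes()
  else affine_nodes()
  imgB <- apply_displacement(imgA, nodes, sy$elongation_px)
  if (sy$pair_noise_sd > 0) {
    imgB <- with_seed(seed + 1L, clip_grey(
      imgB + matrix(stats::rnorm(length(imgB), 0, sy$pair_noise_sd),
                    nrow(imgB), ncol(imgB))))
  }
  write_image(imgA, p$imgA)
  write_image(imgB, p$imgB)
  x_rel <- seq(0, 1, length.out = 201L)
  utils::write.csv(data.frame(
    x_rel = x_rel,
    u_px = sy$elongation_px * evaluate_profile(nodes, x_rel)),
    p$truth, row.names = FALSE)

  trace_files <- list()
  for (scen in names(sy$force)) {
    fs <- sy$force[[scen]]
    n_rep <- fs$n %||% 1L
    fs$n <- NULL
    for (i in seq_len(n_rep)) {
      spec <- do.call(force_trace_spec, c(fs, list(seed = seed + i)))
      tr <- generate_force_trace(spec)
      f <- file.path(outdir, sprintf("trace_%s_%d.csv", scen, i))
      write_force_trace_csv(tr, f)
      trace_files[[sprintf("%s_%d", scen, i)]] <- f
    }
  }

  tl <- do.call(timelapse_spec, c(sy$timelapse, list(seed = seed + 100L)))
  stack <- generate_timelapse(tl)
  write_stack(stack, p$stack)

  jsonlite::write_json(list(seed = seed, config = unclass(config),
                            files = c(p[c("imgA", "imgB", "truth", "stack")],
                                      trace_files)),
                       p$manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(p, trace_files))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the analysis pipeline on generated (or equivalent) inputs
#'
#' Executes PIV on the image pair, reduces the field to a deformation
#' profile with affine and piecewise fits and a region classification, fits
#' the mechanics of every force trace in the output directory, and runs the
#' kinetics analyses on the time-lapse stack. The JSON report aggregates the
#' stage results with provenance (input MD5 hashes, the config, package
#' version).
#'
#' @param config a validated `run_config` whose `outdir` contains the files
#'   written by [run_synth] (or files of the same layout).
#' @param report_path output JSON path (default `report.json` in `outdir`).
#' @return The report list, invisibly written as JSON.
#' @export
run_pipeline <- function(config,
                         report_path = file.path(config$outdir, "report.json")) {
  config <- validate_config(config)
  outdir <- config$outdir
  p <- synth_paths(outdir)
  for (f in c(p$imgA, p$imgB)) {
    if (!file.exists(f)) stop_input("missing input file: ", f)
  }

  piv_cfg <- piv_config(config$piv$interrogation_px, config$piv$search_px,
                        config$piv$overlap_fraction, config$piv$subpixel,
                        config$piv$min_contrast)
  field <- run_stage("piv", {
    imgA <- read_image(p$imgA)
    imgB <- read_image(p$imgB)
    validate_field(compute_field(imgA, imgB, piv_cfg),
                   median_k = config$piv$median_k)
  })
  write_field_csv(field, file.path(outdir, "field.csv"))

  prof_res <- run_stage("profile", {
    imgA <- read_image(p$imgA)
    prof <- profile_from_field(field, immobile_x_px = 1,
                               mobile_x_px = ncol(imgA),
                               applied_elongation_mm = config$synth$elongation_px)
    aff <- fit_affine(prof)
    n_seg <- config$profile$n_segments
    pw <- fit_piecewise(prof, n_segments = n_seg,
                        grid_step = config$profile$grid_step)
    regions <- classify_regions(pw, config$profile$rigid_slope_max,
                                config$profile$step_width_max)
    write_profile_csv(prof, file.path(outdir, "profile.csv"), fit = pw)
    write_fit_json(pw, file.path(outdir, "piecewise_fit.json"))
    list(affine = unclass(aff),
         piecewise = list(breakpoints = pw$breakpoints, sse = pw$sse,
                          nodes = as.data.frame(pw$nodes)),
         regions = regions)
  })

  trace_files <- sort(list.files(outdir, pattern = "^trace_.*\\.csv$",
                                 full.names = TRUE))
  mech_res <- run_stage("mech", {
    scen_of <- sub("^trace_([a-z]+)_\\d+\\.csv$", "\\1", basename(trace_files))
    out <- list()
    for (scen in unique(scen_of)) {
      files <- trace_files[scen_of == scen]
      cf <- config$synth$force[[scen]]$central_fraction %||% 1
      fits <- lapply(files, function(f) {
        tr <- read_force_trace_csv(f)
        tr <- convert_channel(tr)
        tr <- zero_calibrate(tr, config$mech$post_failure_window,
                             drop_fraction = config$mech$drop_fraction,
                             window_samples = config$mech$window_samples,
                             min_force = config$mech$min_force)
        if (cf < 1) {
          tr$elongation_mm <- correct_true_strain(tr$plate_displacement_mm, cf)
        } else {
          tr <- pellicle_elongation(tr)
        }
        fit_elastic(tr, fit_range = config$mech$fit_range,
                    drop_fraction = config$mech$drop_fraction,
                    window_samples = config$mech$window_samples,
                    min_force = config$mech$min_force)
      })
      sm <- summarize_mechanics(fits, initial_gap = config$mech$initial_gap)
      out[[scen]] <- unclass(sm)
    }
    out
  })

  kin_res <- run_stage("kinetics", {
    stack <- read_stack(p$stack)
    h_mm <- (nrow(stack$frames[[1L]]) - 1L) * stack$pixel_size
    w_mm <- (ncol(stack$frames[[1L]]) - 1L) * stack$pixel_size
    probe <- config$kinetics$probe %||% c(0, h_mm / 2, w_mm, h_mm / 2)
    kym <- build_kymograph(stack, probe)
    ft <- track_front(kym, level = config$kinetics$level)
    last_prof <- kym$values[nrow(kym$values), ]
    ws <- wrinkle_wavelength(last_prof, stack$pixel_size,
                             band = config$kinetics$band)
    list(front = list(speed_mm_h = ft$speed, fit_r2 = ft$fit_r2,
                      n_skipped = ft$n_skipped),
         wrinkles = list(dominant_wavelength_mm = ws$dominant_wavelength,
                         spectral_wavelength_mm = ws$spectral_wavelength,
                         status = ws$status))
  })

  inputs <- c(p$imgA, p$imgB, p$stack, trace_files)
  report <- list(
    provenance = list(package_version = as.character(
      utils::packageVersion("pellimetry")),
      seed = config$seed,
      input_md5 = as.list(stats::setNames(tools::md5sum(inputs),
                                          basename(inputs))),
      config = unclass(config)),
    profile = prof_res, mechanics = mech_res, kinetics = kin_res)
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(report)
}
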