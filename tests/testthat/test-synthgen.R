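# Synthetic-data generators: determinism, degenerate cases, and agreement
# with independent oracles (blob labelling, correlation, block matching).

test_that("speckle generation is deterministic and handles degenerate specs", {
  flat <- generate_speckle(speckle_spec(64, 48, grain_density = 0,
                                        noise_sd = 0, background_level = 80))
  expect_true(all(flat == 80))
  expect_equal(dim(flat), c(48, 64))

  sp <- speckle_spec(128, 96, seed = 11)
  expect_identical(generate_speckle(sp), generate_speckle(sp))
  sp2 <- speckle_spec(128, 96, seed = 12)
  expect_false(identical(generate_speckle(sp), generate_speckle(sp2)))

  expect_error(speckle_spec(width_px = 0), class = "pellimetry_input_error")
  expect_error(speckle_spec(noise_sd = -1), class = "pellimetry_input_error")
})

test_that("speckle grain counts are Poisson-consistent under independent blob labelling", {
  count_blobs <- function(img, spec, thr_frac = 0.85) {
    thr <- spec$background_level +
      thr_frac * spec$contrast * (255 - spec$background_level)
    max(EBImage::bwlabel(img > thr))
  }
  # sparse case: negligible grain overlap, tight bounds
  sp2 <- speckle_spec(256, 256, grain_density = 2, grain_radius_px = 2,
                      noise_sd = 0, seed = 7)
  mu2 <- 2 * 256 * 256 / 1000
  n2 <- count_blobs(generate_speckle(sp2), sp2)
  expect_gt(n2, mu2 - 3 * sqrt(mu2))
  expect_lt(n2, mu2 + 3 * sqrt(mu2))
  # denser case: some blobs merge, so only the statistical bounds apply
  sp5 <- speckle_spec(256, 256, grain_density = 5, grain_radius_px = 2,
                      noise_sd = 0, seed = 7)
  mu5 <- 5 * 256 * 256 / 1000
  n5 <- count_blobs(generate_speckle(sp5), sp5)
  expect_gt(n5, mu5 - 4 * sqrt(mu5))
  expect_lt(n5, mu5 + 4 * sqrt(mu5))
})

test_that("profile evaluation interpolates the canonical nodes exactly", {
  rough <- canonical_rough_nodes()
  expect_equal(evaluate_profile(rough, 0.80), 0.60)
  expect_equal(evaluate_profile(affine_nodes(), 0.37), 0.37)
  # hand interpolation between nodes (0.15, 0.33) and (0.70, 0.60)
  expect_equal(evaluate_profile(rough, 0.50), 0.33 + 0.27 * 0.35 / 0.55,
               tolerance = 1e-12)
  expect_equal(evaluate_profile(rough, rough$x_rel), rough$u_rel)
  expect_error(evaluate_profile(rough, 1.2), class = "pellimetry_input_error")
  expect_error(evaluate_profile(rough, -0.1), class = "pellimetry_input_error")
})

test_that("warping matches correlation and block-matching oracles", {
  img <- generate_speckle(speckle_spec(200, 120, noise_sd = 0, seed = 3))
  expect_equal(apply_displacement(img, canonical_rough_nodes(), 0), img)

  # uniform translation of 3 px: full-frame correlation peak at lag 3
  shifted <- apply_displacement(img, shift_nodes(0.25), 12)
  expect_equal(best_int_lag(img, shifted), 3)

  # affine stretch of 6 px total: mid-column matter displaced ~3 px
  aff <- apply_displacement(img, affine_nodes(), 6)
  expect_equal(block_match(img, aff, cx = 100, cy = 60), 3)
})

test_that("force traces follow the linear-elastic model with abrupt failure", {
  prot <- pull_protocol(sampling_interval = 125)  # 0.02 mm per sample
  tr <- generate_force_trace(
    force_trace_spec(0.51, -1.2, failure_elongation = 6, noise_sd = 0), prot)
  i5 <- which(abs(tr$plate_displacement_mm - 5) < 1e-9)
  expect_equal(tr$force_mN[i5], -1.2 + 0.51 * 5, tolerance = 1e-12)

  # noise-free pre-failure record is exactly linear
  pre <- tr$plate_displacement_mm < 6
  fit <- lm(tr$force_mN[pre] ~ tr$plate_displacement_mm[pre])
  expect_lt(max(abs(resid(fit))), 1e-10)
  # unit identity: slope in mN/mm equals the spec stiffness in N/m
  expect_equal(unname(coef(fit)[2]), 0.51, tolerance = 1e-12)

  zero <- generate_force_trace(
    force_trace_spec(0, 0, failure_elongation = 6, noise_sd = 0), prot)
  expect_true(all(zero$force_mN[zero$plate_displacement_mm < 6] == 0))

  # composite pellicle: force follows the central-region elongation
  rough <- generate_force_trace(
    force_trace_spec(5.1, 0, failure_elongation = 1.2, noise_sd = 0,
                     central_fraction = 0.27), prot)
  i37 <- which(abs(rough$plate_displacement_mm - 3.7) < 1e-9)
  expect_equal(rough$force_mN[i37], 5.1 * 0.27 * 3.7, tolerance = 1e-12)

  # failure beyond the protocol travel: no failure, flagged
  nofail <- generate_force_trace(
    force_trace_spec(0.51, -1.2, failure_elongation = 20, noise_sd = 0), prot)
  expect_false(attr(nofail, "failure_expected"))

  spec <- force_trace_spec(0.51, -1.2, 5, noise_sd = 0.05, seed = 4)
  expect_identical(generate_force_trace(spec, prot),
                   generate_force_trace(spec, prot))
})

test_that("timelapse stacks have the configured front kinematics and wrinkles", {
  static <- generate_timelapse(timelapse_spec(
    duration = 2, front_speed = 0, dish_width = 20, dish_height = 3,
    noise_sd = 0, seed = 1))
  edges <- vapply(static$frames,
                  function(f) max(which(f[20, ] > 110)), integer(1))
  expect_true(all(edges == edges[1]))

  # 0.25 mm/h at 0.05 mm/px and 15-min frames: 1.25 px per frame
  mov <- generate_timelapse(timelapse_spec(
    duration = 6, front_speed = 0.25, front_onset = 0, dish_width = 25,
    dish_height = 3, noise_sd = 0, seed = 1))
  edges <- vapply(mov$frames, function(f) max(which(f[20, ] > 110)), integer(1))
  expect_equal(mean(diff(edges)), 1.25, tolerance = 0.05)

  # wrinkle modulation: grey-profile period of 40 px by autocorrelation
  wr <- generate_timelapse(timelapse_spec(
    duration = 1, front_speed = 0, front_start_mm = 24,
    wrinkle_onset = 0, wrinkle_wavelength = 2.0, dish_width = 25,
    dish_height = 3, noise_sd = 0, seed = 1))
  prof <- wr$frames[[3]][20, 1:440]
  ac <- acf(prof - mean(prof), lag.max = 60, plot = FALSE)$acf[, 1, 1]
  peaks <- which(diff(sign(diff(ac))) == -2)  # lag of interior local maxima
  expect_true(abs(peaks[which.max(ac[peaks + 1])] - 40) <= 1)

  expect_error(timelapse_spec(wrinkle_wavelength = 0.05, pixel_size = 0.05),
               class = "pellimetry_input_error")
})
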