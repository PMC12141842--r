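# Sensor mechanics: calibration, failure detection, elastic fitting,
# true-strain correction, and stiffness rescaling.

test_that("cantilever arithmetic converts deflection to force both ways", {
  s <- sensor_model()
  expect_equal(deflection_to_force(0, s), 0)
  # 1 mN corresponds to a 0.05 mm plate shift
  defl_um_for_1mN <- 1000 / s$cantilever_stiffness
  expect_equal(deflection_to_force(defl_um_for_1mN, s), 1, tolerance = 1e-12)
  expect_equal(round(defl_um_for_1mN / 1000, 2), 0.05)
  # resolution floor
  expect_equal(deflection_to_force(0.40, s), 19.5 * 0.0004, tolerance = 1e-12)
  # homogeneous of degree 1
  d <- c(-3, 0.5, 7)
  expect_equal(deflection_to_force(2.5 * d, s), 2.5 * deflection_to_force(d, s))

  tr <- force_trace(0:3, (0:3) * 0.1, c(10, 20, 30, 40),
                    channel = "deflection_um")
  expect_equal(convert_channel(tr, s)$force_mN, 19.5 * c(10, 20, 30, 40) / 1000)
})

test_that("zero calibration removes a known offset and is idempotent", {
  spec <- force_trace_spec(0.51, -1.2, 5, noise_sd = 0.05,
                           baseline_offset = 0.3, seed = 2)
  tr <- generate_force_trace(spec)
  cal <- zero_calibrate(tr)
  expect_equal(attr(cal, "zero_offset"), 0.3, tolerance = 0.1)
  post <- cal$force_mN[cal$time_s > max(cal$time_s) - 2]
  expect_equal(mean(post), 0, tolerance = 1e-9)

  # offset-free noiseless trace is unchanged
  clean <- generate_force_trace(force_trace_spec(0.51, -1.2, 5, noise_sd = 0))
  expect_equal(zero_calibrate(clean)$force_mN, clean$force_mN)

  # idempotence is exact
  cal2 <- zero_calibrate(cal)
  expect_equal(cal2$force_mN, cal$force_mN)

  # a window reaching into pre-failure samples is rejected
  expect_error(zero_calibrate(tr, post_failure_window = 60),
               class = "pellimetry_input_error")
})

test_that("pellicle elongation subtracts the sensor-plate deflection", {
  tr <- force_trace(c(0, 1), c(0, 0.5), c(0, 1), channel = "force_mN")
  el <- pellicle_elongation(tr)
  expect_equal(el$elongation_mm, c(0, 0.5 - 1 / 19.5), tolerance = 1e-12)
  # tensile force strictly decreases the elongation
  expect_true(all(el$elongation_mm[-1] < el$plate_displacement_mm[-1]))
  # worst-case correction in a smooth test is tiny vs. the travel
  expect_lt(1.5 / 19.5, 0.1)
})

test_that("failure detection is robust to glitches and absent failures", {
  tr <- generate_force_trace(force_trace_spec(0.51, -1.2, 5, noise_sd = 0.02,
                                              seed = 6))
  det <- detect_failure(tr)
  expect_equal(det$status, "failed")
  expect_equal(det$failure_elongation, 5, tolerance = 0.02 / 5)
  expect_equal(det$failure_force, -1.2 + 0.51 * 5, tolerance = 0.05)

  rising <- generate_force_trace(force_trace_spec(0.51, 0, 50, noise_sd = 0))
  expect_equal(detect_failure(rising)$status, "none")

  # one-sample dip smaller than the drop fraction is not failure
  f <- seq(0.1, 4, length.out = 100)
  f[60] <- f[60] * 0.7
  glitch <- force_trace(seq_len(100) / 10, seq_len(100) * 0.05, f)
  expect_equal(detect_failure(glitch, drop_fraction = 0.5)$status, "none")
  # nor is a deep but isolated one-sample dip: failure is permanent
  f[60] <- 0.2
  deep1 <- force_trace(seq_len(100) / 10, seq_len(100) * 0.05, f)
  expect_equal(detect_failure(deep1, drop_fraction = 0.5)$status, "none")
  # a persistent deep drop is failure, located at its first sample
  f[60:100] <- 0.2
  deep <- force_trace(seq_len(100) / 10, seq_len(100) * 0.05, f)
  expect_equal(detect_failure(deep, drop_fraction = 0.5)$index, 60)
})

test_that("elastic fits recover stiffness and intercept", {
  # noise-free: exact recovery
  clean <- generate_force_trace(force_trace_spec(0.51, -1.2, 5, noise_sd = 0))
  fe <- fit_elastic(clean)
  expect_equal(fe$stiffness, 0.51, tolerance = 1e-10)
  expect_equal(fe$intercept, -1.2, tolerance = 1e-10)

  # three noisy smooth replicates
  fits <- lapply(1:3, function(s) {
    tr <- generate_force_trace(force_trace_spec(0.51, -1.2, 5,
                                                noise_sd = 0.05, seed = s))
    fit_elastic(zero_calibrate(pellicle_elongation(tr)))
  })
  sm <- summarize_mechanics(fits)
  expect_equal(sm$stiffness, 0.51, tolerance = 0.04 / 0.51)
  expect_equal(sm$intercept, -1.2, tolerance = 0.2 / 1.2)

  # three rough replicates on the true-strain corrected axis
  rfits <- lapply(1:3, function(s) {
    tr <- generate_force_trace(force_trace_spec(5.1, 0, 1.2, noise_sd = 0.1,
                                                central_fraction = 0.27,
                                                seed = s))
    tr <- zero_calibrate(tr)
    tr$elongation_mm <- correct_true_strain(tr$plate_displacement_mm, 0.27)
    fit_elastic(tr)
  })
  rm <- summarize_mechanics(rfits)
  expect_equal(rm$stiffness, 5.1, tolerance = 0.6 / 5.1)
})

test_that("noisy fits are unbiased over 50 seeded replicates", {
  res <- vapply(1:50, function(s) {
    tr <- generate_force_trace(force_trace_spec(0.51, -1.2, 5,
                                                noise_sd = 0.05, seed = s))
    fe <- fit_elastic(tr)   # plate axis: generator truth is exact here
    c(fe$stiffness, fe$intercept)
  }, numeric(2))
  se_k <- sd(res[1, ]) / sqrt(50)
  se_b <- sd(res[2, ]) / sqrt(50)
  expect_lt(abs(mean(res[1, ]) - 0.51), 2 * se_k + 1e-6)
  expect_lt(abs(mean(res[2, ]) + 1.2), 2 * se_b + 1e-6)
})

test_that("true-strain correction and stiffness rescaling follow the scaling laws", {
  expect_equal(correct_true_strain(3.7, 0.27), 0.999)
  expect_equal(round(correct_true_strain(3.7, 0.27)), 1)
  expect_equal(correct_true_strain(0.6, 0.27), 0.162)
  expect_equal(correct_true_strain(c(1, 2, 3), 1), c(1, 2, 3))

  expect_equal(rescale_stiffness(5.1, 1), 5.1)
  expect_equal(rescale_stiffness(5.1, 0.55), 2.805)
  # k x L conservation: halving the length doubles the stiffness
  k <- 4.2
  expect_equal(rescale_stiffness(k, 0.5) / 1, k * 0.5)
  expect_equal(rescale_stiffness(2 * k, 0.5), k)
  fr <- c(0.25, 0.5, 0.75, 1)
  expect_equal(rescale_stiffness(k / fr, fr), rep(k, 4))
})

test_that("failure strain is elongation over initial gap, in percent", {
  expect_equal(failure_strain(5, 13.5), 100 * 5 / 13.5)
  expect_equal(failure_strain(0, 13.5), 0)
  expect_equal(failure_strain(13.5, 13.5), 100)
  expect_error(failure_strain(5, 0), class = "pellimetry_input_error")
})
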