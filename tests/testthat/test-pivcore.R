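# PIV core: grayscale conversion, window correlation, subpixel peaks,
# gridded fields, and outlier validation.

test_that("grayscale conversion is luminance-weighted and passes grey through", {
  m <- matrix(runif(12, 0, 255), 3, 4)
  expect_identical(to_grayscale(m), m)

  grey <- array(rep(m, 3), dim = c(3, 4, 3))
  expect_equal(to_grayscale(grey), m)

  red <- array(0, dim = c(2, 2, 3)); red[, , 1] <- 255
  expect_equal(to_grayscale(red), matrix(0.2126 * 255, 2, 2))

  expect_error(to_grayscale(array(0, dim = c(2, 2, 2))),
               class = "pellimetry_input_error")
})

test_that("correlation surfaces peak at the constructed offset and stay bounded", {
  set.seed(42)
  big <- matrix(runif(80 * 80, 0, 255), 80, 80)

  # template cut from the search-window centre: perfect match at zero lag
  srch <- big[11:60, 11:60]
  tmpl <- srch[10:41, 10:41]
  surf <- correlate(tmpl, srch)
  pk <- subpixel_peak(surf, "none")
  expect_equal(c(pk$dx, pk$dy), c(0, 0))
  expect_equal(pk$peak_value, 1, tolerance = 1e-12)
  expect_true(all(surf >= -1 - 1e-12 & surf <= 1 + 1e-12))

  # matter moved by (+3, -2): template from A, search from shifted B
  A <- big
  B <- matrix(0, 80, 80)
  B[1:78, 4:80] <- A[3:80, 1:77]   # content moves +3 in x, -2 in y
  tmplA <- A[25:56, 25:56]
  srchB <- B[16:65, 16:65]
  pk2 <- subpixel_peak(correlate(tmplA, srchB), "none")
  expect_equal(c(pk2$dx, pk2$dy), c(3, -2))

  # template against uncorrelated noise: low peak with high probability
  noise <- matrix(runif(50 * 50, 0, 255), 50, 50)
  expect_lt(max(correlate(tmpl, noise)), 0.5)

  flat <- correlate(matrix(5, 32, 32), srch)
  expect_false(attr(flat, "valid"))
})

test_that("subpixel refinement recovers analytic and generated peak positions", {
  # symmetric peak: zero fractional part
  sym <- outer(exp(-(-2:2)^2 / 2), exp(-(-2:2)^2 / 2))
  attr(sym, "lag_x") <- attr(sym, "lag_y") <- -2:2
  pk <- subpixel_peak(sym)
  expect_equal(c(pk$dx, pk$dy), c(0, 0))

  # sampled analytic Gaussian centred at (+0.3, -0.2): gaussian3 is exact
  gx <- exp(-((-2:2) - 0.3)^2 / 1.3)
  gy <- exp(-((-2:2) + 0.2)^2 / 1.3)
  surf <- outer(gy, gx)
  attr(surf, "lag_x") <- attr(surf, "lag_y") <- -2:2
  pk <- subpixel_peak(surf, "gaussian3")
  expect_equal(pk$dx, 0.3, tolerance = 1e-9)
  expect_equal(pk$dy, -0.2, tolerance = 1e-9)

  # border peak: integer result, flagged
  ramp <- matrix(seq_len(25), 5, 5)
  attr(ramp, "lag_x") <- attr(ramp, "lag_y") <- -2:2
  pkb <- subpixel_peak(ramp)
  expect_true(pkb$border)
  expect_equal(pkb$dx %% 1, 0)

  # speckle pair shifted by 2.5 px: estimate within 0.2 px
  img <- generate_speckle(speckle_spec(120, 120, noise_sd = 0, seed = 5))
  sh <- apply_displacement(img, shift_nodes(0.5), 5)
  surf <- correlate(img[41:72, 41:72], sh[32:81, 32:81])
  pk <- subpixel_peak(surf)
  expect_equal(pk$dx, 2.5, tolerance = 0.1)
  expect_equal(pk$dy, 0, tolerance = 0.1)
})

test_that("displacement fields recover identity, translation, and the rough plateau", {
  img <- generate_speckle(speckle_spec(300, 140, noise_sd = 0, seed = 9))
  cfg <- piv_config()

  f0 <- compute_field(img, img, cfg)
  expect_true(all(abs(f0$u[f0$valid]) < 1e-6))
  expect_true(all(abs(f0$v[f0$valid]) < 1e-6))
  expect_true(all(f0$peak_quality[f0$valid] >= 1))

  # integer 4 px translation along x
  tr4 <- apply_displacement(img, shift_nodes(0.5), 8)
  f4 <- compute_field(img, tr4, cfg)
  expect_equal(mean(f4$u[f4$valid]), 4, tolerance = 0.025)
  expect_lt(max(abs(f4$v[f4$valid])), 0.2)

  # translation equivariance: shifting B by (a, 0) shifts every vector by a
  tr2 <- apply_displacement(img, shift_nodes(0.25), 8)
  f2 <- compute_field(img, tr2, cfg)
  expect_lt(max(abs((f4$u - f2$u)[f4$valid & f2$valid] - 2)), 0.2)

  # rough-profile pair: plateau stations share one displacement
  pair <- make_pair(canonical_rough_nodes(), 8)
  fr <- validate_field(compute_field(pair$A, pair$B, cfg))
  x_rel <- (fr$x - 1) / (ncol(pair$A) - 1)
  plat <- fr$u[, x_rel >= 0.70 & x_rel <= 0.95]
  expect_lt(max(plat) - min(plat), 0.5)
  expect_equal(mean(plat), 0.60 * 8, tolerance = 0.05)

  expect_error(compute_field(img[1:40, 1:40], img[1:40, 1:40], cfg),
               class = "pellimetry_input_error")
})

test_that("recovery error grows monotonically with image noise", {
  img <- generate_speckle(speckle_spec(260, 120, noise_sd = 0, seed = 21))
  sh <- apply_displacement(img, shift_nodes(0.5), 7)  # 3.5 px
  err <- vapply(c(0, 10, 40), function(sd) {
    noisy <- if (sd > 0) {
      set.seed(100 + sd)
      pmin(pmax(sh + matrix(rnorm(length(sh), 0, sd), nrow(sh)), 0), 255)
    } else sh
    f <- compute_field(img, noisy, piv_config())
    mean(abs(f$u[f$valid] - 3.5))
  }, numeric(1))
  expect_true(all(diff(err) > 0))
})

test_that("median validation flags seeded outliers but not smooth gradients", {
  # uniform field with one spike
  u <- matrix(2, 6, 8)
  u[3, 4] <- 9
  fld <- validate_field(make_field(u))
  expect_equal(fld$u[3, 4], 2)
  expect_true(fld$replaced[3, 4])
  expect_equal(sum(fld$replaced), 1)

  # smooth affine gradient: untouched
  grad <- matrix(rep(seq(0, 6, length.out = 12), each = 9), 9, 12)
  fgrad <- validate_field(make_field(grad))
  expect_equal(sum(fgrad$replaced), 0)
  expect_equal(fgrad$u, grad)

  # 5% seeded outliers on an affine gradient
  set.seed(33)
  big <- matrix(rep(seq(0, 8, length.out = 40), each = 25), 25, 40)
  idx <- sample(length(big), round(0.05 * length(big)))
  spiked <- big
  spiked[idx] <- big[idx] + sample(c(-6, 6), length(idx), replace = TRUE)
  fsp <- validate_field(make_field(spiked))
  flagged <- which(fsp$replaced)
  expect_gte(length(intersect(flagged, idx)), 0.9 * length(idx))
  false_flags <- setdiff(flagged, idx)
  expect_lte(length(false_flags), 0.01 * (length(big) - length(idx)))
})
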