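# Shared fixtures and independent oracles, built in code at test time.

# Uniform-translation profile: every point moves by c * total elongation.
shift_nodes <- function(c) profile_nodes(c(0, 1), c(c, c))

# Noiseless speckle pair warped by a displacement profile.
make_pair <- function(nodes, total_px, w = 400, h = 160, seed = 7,
                      noise_sd = 0) {
  A <- generate_speckle(speckle_spec(width_px = w, height_px = h,
                                     grain_density = 5, grain_radius_px = 2,
                                     noise_sd = noise_sd, seed = seed))
  list(A = A, B = apply_displacement(A, nodes, total_px))
}

# Canonical rough profile sampled at regular stations.
sample_canonical <- function(step = 0.02, noise_sd = 0, seed = 1) {
  x <- seq(0, 1, by = step)
  u <- evaluate_profile(canonical_rough_nodes(), x)
  if (noise_sd > 0) {
    set.seed(seed)
    u <- u + rnorm(length(x), 0, noise_sd)
  }
  deformation_profile(x, u)
}

# Independent full-frame correlation oracle: best integer x-lag between two
# images, by direct correlation of overlapping columns.
best_int_lag <- function(A, B, max_lag = 6) {
  w <- ncol(A)
  scores <- sapply(-max_lag:max_lag, function(l) {
    if (l >= 0) {
      cor(as.vector(A[, 1:(w - l)]), as.vector(B[, (1 + l):w]))
    } else {
      cor(as.vector(A[, (1 - l):w]), as.vector(B[, 1:(w + l)]))
    }
  })
  (-max_lag:max_lag)[which.max(scores)]
}

# Independent block-matching oracle: integer displacement of a block centred
# at (cx, cy) by exhaustive SSD search.
block_match <- function(A, B, cx, cy, half = 16, max_lag = 8) {
  blk <- A[(cy - half):(cy + half), (cx - half):(cx + half)]
  best <- c(NA_integer_, Inf)
  for (l in -max_lag:max_lag) {
    cand <- B[(cy - half):(cy + half), (cx - half + l):(cx + half + l)]
    ssd <- sum((blk - cand)^2)
    if (ssd < best[2]) best <- c(l, ssd)
  }
  best[1]
}

# Independent brute-force continuous piecewise-linear fit: breakpoints
# enumerated over midpoints of consecutive data points, each candidate
# fitted with lm() on an explicitly built hinge basis.
bf_piecewise <- function(x, y, n_breaks) {
  mids <- (x[-1] + x[-length(x)]) / 2
  mids <- mids[mids > min(x) & mids < max(x)]
  combos <- utils::combn(length(mids), n_breaks)
  best <- list(sse = Inf)
  for (ci in seq_len(ncol(combos))) {
    b <- mids[combos[, ci]]
    dat <- data.frame(y = y, x = x)
    for (i in seq_along(b)) dat[[paste0("h", i)]] <- pmax(x - b[i], 0)
    fit <- lm(y ~ ., data = dat)
    sse <- sum(resid(fit)^2)
    if (sse < best$sse - 1e-12) best <- list(sse = sse, breaks = b)
  }
  best
}

# Build a displacement_field object directly (for tests that need full
# control of the vectors).
make_field <- function(u, v = u * 0, x = NULL, y = NULL) {
  if (is.null(x)) x <- seq_len(ncol(u)) * 10
  if (is.null(y)) y <- seq_len(nrow(u)) * 10
  structure(list(x = x, y = y,
                 u = u, v = v,
                 valid = matrix(TRUE, nrow(u), ncol(u)),
                 peak_quality = matrix(2, nrow(u), ncol(u)),
                 status = matrix("ok", nrow(u), ncol(u)),
                 config = NULL),
            class = "displacement_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
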