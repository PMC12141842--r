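# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of (spec, seed) without
#' side effects on the session.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_input <- function(...) {
  stop(structure(class = c("pellimetry_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input(sprintf("'%s' must be a finite numeric scalar", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    stop_input(sprintf("'%s' = %g out of range", name, x))
  }
  invisible(x)
}

clip_grey <- function(x) pmin(pmax(x, 0), 255)

#' Bilinear sampling of a grey-level matrix at real-valued pixel coordinates
#'
#' Coordinates are 1-based (column = x, row = y) and clamped to the image
#' border, so samples just outside the frame take the edge value.
#' @noRd
sample_bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * h + y0
  v00 <- img[i00];       v10 <- img[i00 + h]
  v01 <- img[i00 + 1];   v11 <- img[i00 + h + 1]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Moving-average baseline with edge padding
#' @noRd
moving_average <- function(x, window) {
  window <- max(3L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2L))[
    (half + 1L):(half + length(x))]
}
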