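# Internal numerical helpers shared across modules: FFT frequency grids,
# mirror padding, Gaussian blur, seeded RNG scopes and bilinear gathers.

#' @keywords internal
fft_freq <- function(n) {
  # cycles per sample, numpy ordering: 0, 1/n, ..., -1/n
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / n
}

#' Nyquist-normalised squared-frequency grid |kappa|^2
#'
#' kappa is scaled so the Nyquist frequency equals 1 in each axis, making
#' the MBA regulariser alpha resolution-independent.
#' @keywords internal
kappa2_grid <- function(nr, nc) {
  kr <- 2 * fft_freq(nr)
  kc <- 2 * fft_freq(nc)
  outer(kr^2, kc^2, `+`)
}

#' @keywords internal
fft2 <- function(x) stats::fft(x)

#' @keywords internal
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Mirror (reflective) padding of a matrix
#'
#' Pads by `frac` of each dimension per side (rounded up) using reflection
#' without repeating the edge sample, the standard symmetric extension.
#' @keywords internal
mirror_pad <- function(x, frac = 0.25) {
  if (frac <= 0) return(structure(x, pad = c(0L, 0L)))
  pr <- ceiling(nrow(x) * frac)
  pc <- ceiling(ncol(x) * frac)
  ri <- mirror_index(nrow(x), pr)
  ci <- mirror_index(ncol(x), pc)
  structure(x[ri, ci, drop = FALSE], pad = c(pr, pc))
}

#' @keywords internal
mirror_index <- function(n, p) {
  if (p >= n) stop("mirror padding wider than the image")
  c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
}

#' @keywords internal
crop_pad <- function(x, pad) {
  if (all(pad == 0)) {
    attr(x, "pad") <- NULL
    return(x)
  }
  x[(pad[1] + 1):(nrow(x) - pad[1]), (pad[2] + 1):(ncol(x) - pad[2]), drop = FALSE]
}

#' FFT Gaussian blur with mirror padding
#'
#' `sigma` in pixels; the transfer function is exp(-2 pi^2 sigma^2 f^2)
#' with f in cycles/pixel, i.e. the exact Fourier transform of a Gaussian.
#' @keywords internal
gauss_blur <- function(x, sigma, pad = 0.25) {
  if (sigma <= 0) return(x)
  xp <- mirror_pad(x, pad)
  p <- attr(xp, "pad")
  fr <- fft_freq(nrow(xp))
  fc <- fft_freq(ncol(xp))
  H <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, `+`))
  out <- Re(ifft2(fft2(xp) * H))
  crop_pad(out, p)
}

#' Evaluate code with a private RNG state
#'
#' Restores the caller's .Random.seed so simulation seeds never leak into
#' or depend on the session RNG.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Bilinear interpolation gather from a matrix
#'
#' Points outside the matrix contribute `fill`. `r`, `c` are fractional
#' 1-based row/column coordinates.
#' @keywords internal
bilerp <- function(m, r, c, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  wr <- r - r0; wc <- c - c0
  out <- numeric(length(r))
  for (dr in 0:1) for (dc in 0:1) {
    ri <- r0 + dr; ci <- c0 + dc
    w <- (if (dr == 0) 1 - wr else wr) * (if (dc == 0) 1 - wc else wc)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc & w > 0
    if (any(ok)) out[ok] <- out[ok] + w[ok] * m[cbind(ri[ok], ci[ok])]
    if (any(!ok)) out[!ok] <- out[!ok] + w[!ok] * fill
  }
  out
}

#' Linear interpolation gather from columns of a matrix (vectorised in rows)
#'
#' For back-projection: interpolates every row of `vals` (one row per z
#' slice) at fractional column positions `x` shared across rows.
#' Out-of-range positions contribute 0.
#' @keywords internal
lerp_cols <- function(vals, x) {
  n <- ncol(vals)
  x0 <- floor(x)
  w <- x - x0
  ok0 <- x0 >= 1 & x0 <= n
  ok1 <- x0 + 1 >= 1 & x0 + 1 <= n
  i0 <- pmin(pmax(x0, 1L), n)
  i1 <- pmin(pmax(x0 + 1L, 1L), n)
  v0 <- vals[, i0, drop = FALSE]
  v1 <- vals[, i1, drop = FALSE]
  v0[, !ok0] <- 0
  v1[, !ok1] <- 0
  sweep(v0, 2, 1 - w, `*`) + sweep(v1, 2, w, `*`)
}

#' @keywords internal
running_mean <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(x)
  n <- length(x)
  h <- (window - 1) / 2
  xe <- c(rep(x[1], h), x, rep(x[n], h))
  stats::filter(xe, rep(1 / window, window), sides = 2)[(h + 1):(h + n)]
}

#' @keywords internal
next_pow2 <- function(n) 2^ceiling(log2(n))
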