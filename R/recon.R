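# Tomographic reconstruction: parallel-beam filtered back-projection with
# the Ram-Lak ramp filter, Feldkamp (FDK) cone-beam reconstruction,
# region-of-interest padding and factor-2 binning.

#' Ram-Lak (ramp) frequency filter
#'
#' The frequency response of the band-limited ramp, built from its exact
#' spatial kernel (1/4 at lag 0, -1/(pi n)^2 at odd lags) rather than by
#' sampling |f| directly, which would bias the DC term and leave a constant
#' offset outside reconstructed objects.
#'
#' @param n length of the (zero-padded) projection row.
#' @param apodize `"none"` (standard Ram-Lak) or `"cosine"`.
#' @param reach truncate the spatial kernel at this lag (default n/2).
#'   Fixing the reach at the unpadded row width makes filtering invariant
#'   under ROI edge-extension of complete data.
#' @return numeric vector of length n in FFT ordering (real, >= 0).
#' @export
ram_lak <- function(n, apodize = c("none", "cosine"), reach = NULL) {
  apodize <- match.arg(apodize)
  lag <- c(seq(0, n / 2), seq(-n / 2 + 1, -1))
  h <- numeric(n)
  h[1] <- 1 / 4
  odd <- lag %% 2 != 0
  h[odd] <- -1 / (pi * lag[odd])^2
  if (!is.null(reach)) h[abs(lag) > reach] <- 0
  filt <- 2 * Re(stats::fft(h))
  if (apodize == "cosine") filt <- filt * cos(pi * fft_freq(n))
  pmax(filt, 0)
}

#' @keywords internal
filter_rows <- function(P, apodize = "none", reach = NULL) {
  # ramp-filter each row of P (one projection per row), zero-padded to
  # >= 2x the row length
  nc <- ncol(P)
  npad <- next_pow2(2 * nc)
  Pp <- cbind(P, matrix(0, nrow(P), npad - nc))
  filt <- ram_lak(npad, apodize, reach)
  Q <- Re(stats::mvfft(stats::mvfft(t(Pp)) * filt, inverse = TRUE)) / npad
  t(Q[seq_len(nc), , drop = FALSE])
}

#' Parallel-beam filtered back-projection
#'
#' Ram-Lak filtering of each projection (zero-padded to at least twice the
#' channel count) followed by linear-interpolation back-projection with
#' pi/n_angles weighting. The sinogram values are treated as line integrals
#' in physical units (value x micrometres); the output slice is in value
#' units on a grid of `channel_pitch` spacing, centered on the rotation
#' axis. If the sinogram carries ROI padding (see [pad_roi()]), the output
#' is cropped back to the original field of view.
#'
#' @param sino a `phasect_sinogram` whose angles span about 180 (or 360)
#'   degrees.
#' @param apodize ramp-filter apodization, `"none"` or `"cosine"`.
#' @param circle zero the pixels outside the inscribed circle of the field
#'   of view (default TRUE); those pixels lie outside the measured region
#'   and carry only filter-truncation bias.
#' @return matrix (n x n, n = channel count) with attribute `pitch_um`.
#'   Row index is y, column index is x, both increasing, with the rotation
#'   axis at the fractional 0-based position `rotation_center`.
#' @export
fbp_parallel <- function(sino, apodize = "none", circle = TRUE) {
  v <- sino$values
  if (nrow(v) < 2) stop("need at least 2 angles")
  nc <- ncol(v)
  rp0 <- attr(sino, "roi_pad")
  q <- filter_rows(v / sino$channel_pitch, apodize,
                   reach = if (!is.null(rp0)) nc - 2 * rp0 else NULL)
  rc <- sino$rotation_center
  g <- (seq_len(nc) - 1) - rc
  X <- matrix(g, nc, nc, byrow = TRUE)
  Y <- matrix(g, nc, nc)
  acc <- matrix(0, nc, nc)
  th <- sino$angles * pi / 180
  for (a in seq_along(th)) {
    pos <- -as.vector(X) * sin(th[a]) + as.vector(Y) * cos(th[a]) + rc + 1
    acc <- acc + matrix(lerp_cols(q[a, , drop = FALSE], pos), nc, nc)
  }
  out <- acc * pi / (2 * length(th))
  if (circle) out[X^2 + Y^2 > (nc / 2)^2] <- 0
  rp <- attr(sino, "roi_pad")
  if (!is.null(rp)) {
    keep <- (rp + 1):(nc - rp)
    out <- out[keep, keep, drop = FALSE]
  }
  structure(out, pitch_um = sino$channel_pitch)
}

#' Brute-force discrete back-projection (reference oracle)
#'
#' Direct summation over angles with the same linear interpolation and
#' weighting as [fbp_parallel()] but written as an explicit per-pixel loop.
#' Intended as an independent cross-check on tiny problems, not for use.
#'
#' @param q pre-filtered sinogram (rows = angles).
#' @param angles degrees.
#' @param rc 0-based rotation center.
#' @return matrix (nc x nc).
#' @export
backproject_bruteforce <- function(q, angles, rc = (ncol(q) - 1) / 2) {
  nc <- ncol(q)
  out <- matrix(0, nc, nc)
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    y <- (i - 1) - rc; x <- (j - 1) - rc
    s <- 0
    for (a in seq_along(angles)) {
      th <- angles[a] * pi / 180
      t <- -x * sin(th) + y * cos(th) + rc
      t0 <- floor(t); w <- t - t0
      v0 <- if (t0 >= 0 && t0 <= nc - 1) q[a, t0 + 1] else 0
      v1 <- if (t0 + 1 >= 0 && t0 + 1 <= nc - 1) q[a, t0 + 2] else 0
      s <- s + (1 - w) * v0 + w * v1
    }
    out[i, j] <- s * pi / (2 * length(angles))
  }
  out
}

#' Region-of-interest (local tomography) padding
#'
#' Continuously extends each row on both sides with its own edge value.
#' Truncated projections of a specimen larger than the field of view
#' otherwise produce a cupping bias after filtering; constant extension
#' suppresses it. For sinograms the rotation center is shifted accordingly
#' and an attribute instructs [fbp_parallel()] to crop the reconstruction
#' back to the original field of view.
#'
#' @param x a `phasect_sinogram` or plain matrix.
#' @param pad_width channels to add per side (default half the width).
#' @return same type as `x`, padded.
#' @export
pad_roi <- function(x, pad_width = NULL) {
  m <- if (inherits(x, "phasect_sinogram")) x$values else x
  if (is.null(pad_width)) pad_width <- floor(ncol(m) / 2)
  stopifnot(pad_width >= 0)
  if (pad_width == 0) return(x)
  mp <- cbind(m[, rep(1, pad_width), drop = FALSE], m,
              m[, rep(ncol(m), pad_width), drop = FALSE])
  if (inherits(x, "phasect_sinogram")) {
    out <- sinogram(mp, x$angles, x$channel_pitch,
                    x$rotation_center + pad_width)
    attr(out, "roi_pad") <- pad_width
    out
  } else mp
}

#' Factor-2 binning (resampling) of images or stacks
#'
#' Non-overlapping 2x2 mean over the image dimensions; for a 3D stack the
#' third (angle/frame) axis is left untouched. Odd dimensions are trimmed
#' by one row/column (reported via a message). Doubles the pixel pitch.
#'
#' @param x matrix or 3D array.
#' @return binned matrix or array.
#' @export
bin2 <- function(x) {
  d <- dim(x)
  if (any(d[1:2] %% 2 == 1)) {
    message("bin2: trimming odd dimension(s) ", d[1], "x", d[2],
            " to even size")
  }
  n1 <- 2 * (d[1] %/% 2); n2 <- 2 * (d[2] %/% 2)
  if (length(d) == 2) {
    x <- x[seq_len(n1), seq_len(n2), drop = FALSE]
    0.25 * (x[seq(1, n1, 2), seq(1, n2, 2)] + x[seq(2, n1, 2), seq(1, n2, 2)] +
            x[seq(1, n1, 2), seq(2, n2, 2)] + x[seq(2, n1, 2), seq(2, n2, 2)])
  } else {
    x <- x[seq_len(n1), seq_len(n2), , drop = FALSE]
    0.25 * (x[seq(1, n1, 2), seq(1, n2, 2), , drop = FALSE] +
            x[seq(2, n1, 2), seq(1, n2, 2), , drop = FALSE] +
            x[seq(1, n1, 2), seq(2, n2, 2), , drop = FALSE] +
            x[seq(2, n1, 2), seq(2, n2, 2), , drop = FALSE])
  }
}

#' @keywords internal
fbp_stack <- function(stack, angles, pitch, rc = (dim(stack)[2] - 1) / 2,
                      apodize = "none", reach = NULL) {
  # stack: (nz, nt, na) of line integrals; shared-angle FBP of all slices,
  # vectorised across z
  d <- dim(stack)
  nz <- d[1]; nt <- d[2]; na <- d[3]
  npad <- next_pow2(2 * nt)
  filt <- ram_lak(npad, apodize, reach)
  Q <- array(0, c(nz, nt, na))
  for (a in seq_len(na)) {
    P <- cbind(stack[, , a] / pitch, matrix(0, nz, npad - nt))
    Fq <- Re(stats::mvfft(stats::mvfft(t(P)) * filt, inverse = TRUE)) / npad
    Q[, , a] <- t(Fq[seq_len(nt), , drop = FALSE])
  }
  g <- (seq_len(nt) - 1) - rc
  X <- rep(g, each = nt)    # x varies along columns of the output slice
  Y <- rep(g, times = nt)   # y along rows
  th <- angles * pi / 180
  acc <- matrix(0, nz, nt * nt)
  for (a in seq_len(na)) {
    pos <- -X * sin(th[a]) + Y * cos(th[a]) + rc + 1
    acc <- acc + lerp_cols(Q[, , a], pos)
  }
  acc[, X^2 + Y^2 > (nt / 2)^2] <- 0
  vol <- array(acc * pi / (2 * na), c(nz, nt, nt))
  structure(vol, pitch_um = pitch)
}

#' Feldkamp (FDK) cone-beam reconstruction
#'
#' Feldkamp-type filtered back-projection for a circular cone-beam scan:
#' per-projection cosine (source-distance) weighting on the virtual
#' detector at the rotation axis, row-wise Ram-Lak filtering, then
#' voxel-driven back-projection along the diverging source-detector rays
#' with the (R/(R+l))^2 distance weight. In the small-cone limit the
#' central slice agrees with [fbp_parallel()].
#'
#' @param stack 3D array (nz, nt, n_angles) of line-integral projections
#'   sampled at `pitch_um` on the virtual detector through the rotation
#'   axis.
#' @param geometry a `phasect_geometry` with finite z1 (mode `"cone"` or
#'   `"inverse"`); parallel mode is refused in favour of [fbp_parallel()].
#' @param angles projection angles in degrees (a full 360 arc is the
#'   intended use).
#' @param pitch_um sample spacing of the stack (defaults to the geometry's
#'   effective pixel).
#' @param apodize ramp apodization.
#' @return a 3D array (nz, nt, nt) with attribute `pitch_um`.
#' @export
fdk_cone <- function(stack, geometry, angles,
                     pitch_um = geometry$effective_pixel_um,
                     apodize = "none", reach = NULL) {
  if (geometry$mode == "parallel")
    stop("geometry is parallel-beam: use fbp_parallel()")
  d <- dim(stack)
  nz <- d[1]; nt <- d[2]; na <- d[3]
  R <- geometry$z1 * 1e3 / pitch_um          # source-axis distance in pixels
  rc <- (nt - 1) / 2
  zc <- (nz - 1) / 2
  u <- (seq_len(nt) - 1) - rc
  vz <- (seq_len(nz) - 1) - zc
  cosw <- R / sqrt(R^2 + outer(vz^2, u^2, `+`))
  npad <- next_pow2(2 * nt)
  filt <- ram_lak(npad, apodize, reach)
  Q <- array(0, c(nz, nt, na))
  for (a in seq_len(na)) {
    P <- cbind(stack[, , a] * cosw / pitch_um, matrix(0, nz, npad - nt))
    Fq <- Re(stats::mvfft(stats::mvfft(t(P)) * filt, inverse = TRUE)) / npad
    Q[, , a] <- t(Fq[seq_len(nt), , drop = FALSE])
  }
  g <- (seq_len(nt) - 1) - rc
  X <- rep(g, each = nt)
  Y <- rep(g, times = nt)
  th <- angles * pi / 180
  vol <- array(0, c(nz, nt, nt))
  accflat <- matrix(0, nz, nt * nt)
  for (a in seq_len(na)) {
    l <- X * cos(th[a]) + Y * sin(th[a])     # along-beam voxel coordinate
    t <- -X * sin(th[a]) + Y * cos(th[a])
    U <- R / (R + l)
    upos <- t * U + rc + 1
    u0 <- floor(upos); wu <- upos - u0
    ok0 <- u0 >= 1 & u0 <= nt
    ok1 <- u0 + 1 >= 1 & u0 + 1 <= nt
    i0 <- pmin(pmax(u0, 1L), nt); i1 <- pmin(pmax(u0 + 1L, 1L), nt)
    Qa <- Q[, , a]
    for (z in seq_len(nz)) {
      vpos <- vz[z] * U + zc + 1
      v0 <- floor(vpos); wv <- vpos - v0
      r0 <- pmin(pmax(v0, 1L), nz); r1 <- pmin(pmax(v0 + 1L, 1L), nz)
      okv0 <- v0 >= 1 & v0 <= nz
      okv1 <- v0 + 1 >= 1 & v0 + 1 <= nz
      val <- (1 - wv) * (1 - wu) * Qa[cbind(r0, i0)] * (okv0 & ok0) +
             (1 - wv) * wu       * Qa[cbind(r0, i1)] * (okv0 & ok1) +
             wv       * (1 - wu) * Qa[cbind(r1, i0)] * (okv1 & ok0) +
             wv       * wu       * Qa[cbind(r1, i1)] * (okv1 & ok1)
      accflat[z, ] <- accflat[z, ] + val * U^2
    }
  }
  accflat[, X^2 + Y^2 > (nt / 2)^2] <- 0
  vol[] <- accflat * pi / (2 * na)
  structure(vol, pitch_um = pitch_um)
}

#' Reconstruct a full scan from retrieved contrast images
#'
#' Orchestrates the reconstruction chain: optional factor-2 binning of the
#' contrast images, conversion to line integrals, per-slice sinogram
#' assembly, ring removal, optional ROI padding, and parallel FBP (for
#' parallel/inverse geometry, treated as quasi-parallel at magnified pitch)
#' or FDK (cone geometry). Deterministic; records full provenance.
#'
#' @param contrast a `phasect_contrast` from [retrieve_stack()] (or a list
#'   with `stack`, `angles`, `pixel_um`, `geometry`).
#' @param ring `"wavelet"`, `"simple"` or `"none"`.
#' @param bin 1 or 2 (factor-2 resampling of the projections before
#'   reconstruction).
#' @param roi_pad channels of constant edge extension per side (0 = none).
#' @param apodize ramp apodization.
#' @param ring_levels,ring_sigma,ring_window ring-filter parameters.
#' @return a `phasect_volume`: `values` (nz, ny, nx), `voxel_size_um`,
#'   `provenance` list.
#' @export
reconstruct_scan <- function(contrast, ring = c("wavelet", "simple", "none"),
                             bin = 1, roi_pad = 0, apodize = "none",
                             ring_levels = NULL, ring_sigma = 2,
                             ring_window = 51) {
  ring <- match.arg(ring)
  stopifnot(bin %in% c(1, 2))
  stack <- contrast$stack
  pitch <- contrast$pixel_um
  if (bin == 2) {
    stack <- bin2(stack)
    pitch <- 2 * pitch
  }
  li <- to_line_integrals(stack)
  d <- dim(li)
  nz <- d[1]; nt <- d[2]
  angles <- contrast$angles
  geom <- contrast$geometry
  rc <- (nt - 1) / 2
  # ring removal acts on per-slice sinograms; cap the smoothing window on
  # narrow sinograms (odd, below the channel count)
  rw <- min(ring_window, nt - 1)
  if (rw %% 2 == 0) rw <- rw - 1
  if (ring != "none") {
    for (z in seq_len(nz)) {
      s <- sinogram(t(li[z, , ]), angles, pitch, rc)
      s <- if (ring == "wavelet")
        ring_remove_wavelet(s, levels = ring_levels, sigma = ring_sigma)
      else ring_remove_simple(s, window = rw)
      li[z, , ] <- t(s$values)
    }
  }
  if (geom$mode == "cone") {
    if (roi_pad > 0) {
      li2 <- array(0, c(nz, nt + 2 * roi_pad, dim(li)[3]))
      for (a in seq_len(dim(li)[3])) li2[, , a] <- pad_roi(li[, , a], roi_pad)
      vol <- fdk_cone(li2, geom, angles, pitch_um = pitch, apodize = apodize,
                      reach = nt)
      keep <- (roi_pad + 1):(roi_pad + nt)
      vol <- structure(vol[, keep, keep, drop = FALSE], pitch_um = pitch)
    } else {
      vol <- fdk_cone(li, geom, angles, pitch_um = pitch, apodize = apodize)
    }
  } else {
    if (roi_pad > 0) {
      li2 <- array(0, c(nz, nt + 2 * roi_pad, dim(li)[3]))
      for (a in seq_len(dim(li)[3])) li2[, , a] <- pad_roi(li[, , a], roi_pad)
      volp <- fbp_stack(li2, angles, pitch, rc = rc + roi_pad,
                        apodize = apodize, reach = nt)
      keep <- (roi_pad + 1):(roi_pad + nt)
      vol <- structure(volp[, keep, keep, drop = FALSE], pitch_um = pitch)
    } else {
      vol <- fbp_stack(li, angles, pitch, rc = rc, apodize = apodize)
    }
  }
  recon_volume(unclass(vol), voxel_size_um = pitch,
               provenance = list(mode = geom$mode, ring = ring, bin = bin,
                                 roi_pad = roi_pad, apodize = apodize,
                                 n_angles = length(angles),
                                 alpha = contrast$alpha,
                                 gamma = contrast$gamma,
                                 geometry = unclass(geom)))
}

#' Reconstructed-volume container
#'
#' @param values 3D array (z, y, x) of effective contrast (an
#'   absorption/phase mixture in arbitrary units).
#' @param voxel_size_um voxel edge in micrometres.
#' @param provenance list of processing parameters.
#' @return object of class `phasect_volume`.
#' @export
recon_volume <- function(values, voxel_size_um, provenance = list()) {
  stopifnot(length(dim(values)) == 3, all(is.finite(values)))
  structure(list(values = values, voxel_size_um = voxel_size_um,
                 provenance = provenance),
            class = "phasect_volume")
}

#' @export
print.phasect_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<phasect_volume> %dx%dx%d voxels @ %.3g um, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}
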