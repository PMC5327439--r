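# Image formation: projection approximation, Fresnel free-space propagation,
# detector corruption (penumbra blur, gain, Poisson counts) and full scans.
#
# Cone/inverse-beam formation is modelled as parallel projection at the
# magnified (effective) pixel pitch plus Fresnel propagation over
# z_eff = z1*z2/(z1+z2) -- the Fresnel scaling equivalence that
# single-distance retrieval itself relies on.

#' Project a phantom at one rotation angle (projection approximation)
#'
#' Computes the exit wave behind the object under the projection
#' approximation: phase phi = -k * integral(delta ds) and log-amplitude
#' ln A = -k * integral(beta ds) along parallel rays through the rotated
#' phantom. The rotation axis is z (the central image column); angles are
#' counter-clockwise with the beam along +x at 0 degrees. Line integrals
#' use bilinear in-plane resampling with unit-voxel steps along the beam.
#'
#' @param phantom a `phasect_phantom` (square in y/x).
#' @param geometry a `phasect_geometry` (supplies the wavenumber).
#' @param angle_deg rotation angle in degrees (any value; projection is
#'   periodic in 360).
#' @return list of class `phasect_exitwave`: `phase` and `log_amplitude`
#'   matrices (nz rows, nx columns), both <= 0, plus `pixel_um` and
#'   `angle_deg`. The object-plane intensity is exp(2 log_amplitude).
#' @export
forward_project <- function(phantom, geometry, angle_deg) {
  V <- phantom$delta; B <- phantom$beta
  if (anyNA(V) || anyNA(B)) stop("phantom contains NaN/NA")
  d <- dim(V)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (ny != nx) stop("phantom must be square in y/x")
  nt <- nx; ns <- nx
  ctr <- (nx + 1) / 2
  th <- angle_deg * pi / 180
  s_rel <- seq_len(ns) - (ns + 1) / 2
  t_rel <- seq_len(nt) - ctr
  X <- outer(cos(th) * s_rel, -sin(th) * t_rel, `+`) + ctr
  Y <- outer(sin(th) * s_rel, cos(th) * t_rel, `+`) + ctr
  xv <- as.vector(X); yv <- as.vector(Y)
  N <- length(xv)
  # stack delta and beta so one gather serves both integrals
  V2 <- rbind(matrix(V, nz, ny * nx), matrix(B, nz, ny * nx))
  y0 <- floor(yv); x0 <- floor(xv)
  wy <- yv - y0; wx <- xv - x0
  acc <- matrix(0, 2 * nz, N)
  for (dy in 0:1) for (dx in 0:1) {
    yi <- y0 + dy; xi <- x0 + dx
    w <- (if (dy == 0) 1 - wy else wy) * (if (dx == 0) 1 - wx else wx)
    ok <- which(yi >= 1 & yi <= ny & xi >= 1 & xi <= nx & w > 0)
    if (length(ok))
      acc[, ok] <- acc[, ok] +
        sweep(V2[, yi[ok] + (xi[ok] - 1) * ny, drop = FALSE], 2, w[ok], `*`)
  }
  dim(acc) <- c(2 * nz, ns, nt)
  integ <- colSums(aperm(acc, c(2, 1, 3))) * phantom$voxel_size_um
  k <- geometry$k_um
  structure(list(phase = -k * integ[seq_len(nz), , drop = FALSE],
                 log_amplitude = -k * integ[nz + seq_len(nz), , drop = FALSE],
                 pixel_um = phantom$voxel_size_um,
                 angle_deg = angle_deg),
            class = "phasect_exitwave")
}

#' Fresnel free-space propagation of an exit wave
#'
#' Propagates the complex exit wave psi = exp(ln A + i phi) over the
#' effective distance z_eff with the angular-spectrum transfer function
#' H(k_perp) = exp(-i z_eff |k_perp|^2 / (2k)) (paraxial, global phase
#' dropped) and returns the detector-plane intensity |psi_z|^2. At
#' z_eff = 0 the object-plane intensity is returned exactly. The propagator
#' is unitary, so pure phase objects conserve total intensity; near-field
#' propagation turns phase gradients into the familiar edge over/undershoot.
#'
#' @param exit_wave a `phasect_exitwave` (or any list with `phase`,
#'   `log_amplitude`, `pixel_um`).
#' @param geometry a `phasect_geometry`; its `z_eff_mm` and wavenumber set
#'   the Fresnel scale.
#' @param pad mirror-padding fraction per side for the Fourier transform;
#'   default 0.25.
#' @return intensity matrix (same size as the input images).
#' @export
fresnel_propagate <- function(exit_wave, geometry, pad = 0.25) {
  phi <- exit_wave$phase; lnA <- exit_wave$log_amplitude
  if (anyNA(phi) || anyNA(lnA)) stop("exit wave contains NaN/NA")
  z_um <- geometry$z_eff_mm * 1e3
  psi <- exp(lnA + 1i * phi)
  if (z_um == 0) return(Mod(psi)^2)
  pr <- if (pad > 0) ceiling(nrow(phi) * pad) else 0L
  pc <- if (pad > 0) ceiling(ncol(phi) * pad) else 0L
  if (pr > 0) {
    ri <- mirror_index(nrow(phi), pr); ci <- mirror_index(ncol(phi), pc)
    psi <- psi[ri, ci, drop = FALSE]
  }
  p <- exit_wave$pixel_um
  kx <- 2 * pi * fft_freq(nrow(psi)) / p   # angular spatial frequency, rad/um
  ky <- 2 * pi * fft_freq(ncol(psi)) / p
  H <- exp(-1i * z_um / (2 * geometry$k_um) * outer(kx^2, ky^2, `+`))
  out <- Mod(ifft2(fft2(psi) * H))^2
  crop_pad(out, c(pr, pc))
}

#' @keywords internal
rpois_big <- function(lambda) {
  # rpois returns integer and fails above .Machine$integer.max; fall back
  # to the Gaussian limit for very high counts
  big <- lambda > 2^30
  out <- numeric(length(lambda))
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) out[big] <- pmax(0, round(stats::rnorm(sum(big), lambda[big],
                                                       sqrt(lambda[big]))))
  out
}

#' Corrupt an ideal detector-plane intensity into raw counts
#'
#' Applies, in order: penumbra Gaussian blur (FWHM = source_fwhm * z2/z1,
#' expressed in detector pixels), per-pixel multiplicative gain, an additive
#' expected dark offset, and a Poisson draw at the stated expected flat-field
#' counts. Deterministic for a fixed seed.
#'
#' @param intensity non-negative intensity matrix (1 = flat field level).
#' @param geometry a `phasect_geometry` (sets the penumbra blur).
#' @param photon_count expected counts per pixel in the flat field (> 0).
#' @param gain_map per-pixel multiplicative gain (default 1).
#' @param seed integer seed for the Poisson draw.
#' @param offset expected additive dark counts per pixel.
#' @param poisson draw Poisson counts (TRUE) or return the expectation.
#' @return matrix of counts.
#' @export
corrupt <- function(intensity, geometry, photon_count, gain_map = NULL,
                    seed = 1, offset = 0, poisson = TRUE) {
  if (any(intensity < 0)) stop("negative intensity input")
  stopifnot(photon_count > 0)
  sig <- geometry$penumbra_fwhm_um / geometry$detector_pixel_um / 2.354820045
  out <- gauss_blur(intensity, sig)
  if (!is.null(gain_map)) out <- out * gain_map
  lambda <- out * photon_count + offset
  if (!poisson) return(lambda)
  with_seed(seed, rpois_big(as.vector(lambda))) |>
    matrix(nrow(intensity), ncol(intensity))
}

#' Simulate a full tomographic scan
#'
#' Runs forward projection, Fresnel propagation and detector corruption for
#' equally spaced angles over the scan arc (endpoint excluded), and
#' generates flat (empty-beam) and dark frames under the same noise model.
#' Per-detector-column gain errors, drawn once per scan and constant across
#' angles, are the mechanism that later produces sinogram stripes and
#' reconstruction rings.
#'
#' Warns when the first Fresnel-zone width sqrt(lambda z_eff) exceeds 5
#' effective pixels, the point where the near-field (TIE) description the
#' retrieval assumes starts to erode.
#'
#' @param phantom a `phasect_phantom`.
#' @param geometry a `phasect_geometry`.
#' @param n_angles number of projections (>= 2).
#' @param arc 180 or 360 degrees.
#' @param photon_count expected flat-field counts per pixel.
#' @param ring_sigma sd of the per-column multiplicative gain law (0.02
#'   default; 0 disables rings).
#' @param n_flats,n_darks number of flat/dark frames (20/20 default).
#' @param dark_fraction dark mean as a fraction of the flat mean (0.01).
#' @param noise draw Poisson counts (TRUE) or keep expectations (FALSE,
#'   noise-free studies).
#' @param seed integer master seed; all randomness derives from it.
#' @param intensities optional precomputed ideal detector-plane intensity
#'   stack (nz, nt, n_angles) from a previous run with the same phantom,
#'   geometry and angles; skips the forward model so several noise
#'   conditions can reuse one wave-optical simulation.
#' @return a `phasect_scan`: frames (nz, nt, n_angles), flats, darks,
#'   gain_map, angles, geometry, seed, photon_count, pixel_um. The ideal
#'   intensity stack is attached as attribute `intensities`.
#' @export
simulate_scan <- function(phantom, geometry, n_angles, arc = 180,
                          photon_count = 1e4, ring_sigma = 0.02,
                          n_flats = 20, n_darks = 20, dark_fraction = 0.01,
                          noise = TRUE, seed = 1, intensities = NULL) {
  stopifnot(n_angles >= 2, arc %in% c(180, 360))
  if (fresnel_zone_um(geometry) > 5 * geometry$effective_pixel_um)
    warning("first Fresnel zone sqrt(lambda*z_eff) exceeds 5 effective ",
            "pixels; the near-field (TIE) regime assumed by MBA/BAC erodes")
  n <- dim(phantom$delta)[1]
  angles <- arc * (seq_len(n_angles) - 1) / n_angles
  gains <- with_seed(seed, 1 + stats::rnorm(n, 0, ring_sigma))
  gain_map <- matrix(gains, n, n, byrow = TRUE)   # per detector column
  dark_rate <- dark_fraction * photon_count
  frames <- array(0, c(n, n, n_angles))
  if (is.null(intensities)) {
    intensities <- array(0, c(n, n, n_angles))
    for (i in seq_len(n_angles)) {
      ew <- forward_project(phantom, geometry, angles[i])
      intensities[, , i] <- fresnel_propagate(ew, geometry)
    }
  } else stopifnot(all(dim(intensities) == c(n, n, n_angles)))
  for (i in seq_len(n_angles)) {
    frames[, , i] <- corrupt(intensities[, , i], geometry, photon_count,
                             gain_map,
                             seed = (seed + 1000 + i) %% .Machine$integer.max,
                             offset = dark_rate, poisson = noise)
  }
  ones <- matrix(1, n, n)
  flats <- array(0, c(n, n, n_flats))
  for (i in seq_len(n_flats))
    flats[, , i] <- corrupt(ones, geometry, photon_count, gain_map,
                            seed = (seed + 2e5 + i) %% .Machine$integer.max,
                            offset = dark_rate, poisson = noise)
  darks <- array(0, c(n, n, n_darks))
  for (i in seq_len(n_darks)) {
    lam <- matrix(dark_rate, n, n)
    darks[, , i] <- if (noise)
      with_seed((seed + 3e5 + i) %% .Machine$integer.max,
                matrix(rpois_big(as.vector(lam)), n, n))
    else lam
  }
  structure(list(frames = frames, flats = flats, darks = darks,
                 gain_map = gain_map, angles = angles, arc = arc,
                 geometry = geometry, photon_count = photon_count,
                 ring_sigma = ring_sigma, dark_fraction = dark_fraction,
                 noise = noise, seed = seed,
                 pixel_um = phantom$voxel_size_um),
            class = "phasect_scan", intensities = intensities)
}

#' @export
print.phasect_scan <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<phasect_scan> %d projections over %d deg, frames %dx%d\n",
              d[3], x$arc, d[1], d[2]))
  cat(sprintf("  %d flats, %d darks, photons=%g, ring sigma=%g, seed=%d\n",
              dim(x$flats)[3], dim(x$darks)[3], x$photon_count,
              x$ring_sigma, x$seed))
  invisible(x)
}

#' Sinogram container
#'
#' @param values matrix, rows = angles, columns = detector channels.
#' @param angles angles in degrees, strictly increasing.
#' @param channel_pitch channel spacing in micrometres.
#' @param rotation_center fractional channel coordinate of the rotation
#'   axis, 0-based; default (n_channels - 1)/2.
#' @return object of class `phasect_sinogram`.
#' @export
sinogram <- function(values, angles, channel_pitch = 1,
                     rotation_center = (ncol(values) - 1) / 2) {
  stopifnot(nrow(values) == length(angles), !is.unsorted(angles))
  structure(list(values = values, angles = angles,
                 channel_pitch = channel_pitch,
                 rotation_center = rotation_center),
            class = "phasect_sinogram")
}

#' Exact sinogram of an ellipse set (analytic oracle)
#'
#' Line integrals through 2D ellipses via the closed-form chord length --
#' no grid sampling anywhere, making this an independent oracle for
#' filtered back-projection. Convention: the detector coordinate of point
#' (x, y) at angle theta is t = -x sin(theta) + y cos(theta) (beam along +x
#' at 0 degrees), in channel-pitch units relative to the rotation center.
#'
#' @param ellipses data frame with columns x0, y0 (center, channel units
#'   relative to the rotation axis), a, b (semi-axes, channel units),
#'   phi_deg (ellipse tilt) and value.
#' @param angles projection angles in degrees.
#' @param n_channels number of detector channels.
#' @param channel_pitch channel spacing in micrometres (scales the line
#'   integrals).
#' @param rotation_center 0-based fractional channel of the rotation axis.
#' @return a `phasect_sinogram`.
#' @export
analytic_sinogram <- function(ellipses, angles, n_channels,
                              channel_pitch = 1,
                              rotation_center = (n_channels - 1) / 2) {
  if (is.null(ellipses$phi_deg)) ellipses$phi_deg <- 0
  t_ch <- (seq_len(n_channels) - 1) - rotation_center
  vals <- matrix(0, length(angles), n_channels)
  for (e in seq_len(nrow(ellipses))) {
    x0 <- ellipses$x0[e]; y0 <- ellipses$y0[e]
    a <- ellipses$a[e]; b <- ellipses$b[e]
    if (sqrt(x0^2 + y0^2) + max(a, b) > n_channels / 2)
      warning("ellipse ", e, " extends beyond the field of view")
    v <- ellipses$value[e]
    phi <- ellipses$phi_deg[e] * pi / 180
    for (ia in seq_along(angles)) {
      th <- angles[ia] * pi / 180
      g <- th + pi / 2 - phi               # line normal in the ellipse frame
      s2 <- a^2 * cos(g)^2 + b^2 * sin(g)^2
      tau <- t_ch - (-x0 * sin(th) + y0 * cos(th))
      inside <- tau^2 < s2
      chord <- numeric(n_channels)
      chord[inside] <- 2 * v * a * b * sqrt(s2 - tau[inside]^2) / s2
      vals[ia, ] <- vals[ia, ] + chord
    }
  }
  sinogram(vals * channel_pitch, angles, channel_pitch, rotation_center)
}
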