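# Per-projection contrast retrieval: empty-beam normalization, Modified
# Bronnikov Algorithm (MBA) phase retrieval and Bronnikov Aided Correction
# (BAC).
#
# In the near field the measured intensity of a weakly absorbing object is,
# by the transport-of-intensity approximation,
#   I_z ~ I_0 * (1 - (z/k) laplacian(phi)),
# so phase contrast appears as edge enhancement. MBA inverts the weak-object
# limit with the regularised Fourier filter 1/(|kappa|^2 + alpha); BAC then
# divides the measured image by (1 - gamma * laplacian(phi_mba)) to recover
# a sharp object-plane intensity. All physical prefactors (k, z_eff, 2*pi
# conventions) are absorbed into the retrieved-phase scale: only the product
# gamma * laplacian(phi) matters downstream, and gamma calibrates it.

#' Empty-beam (flat/dark) normalization of a raw frame
#'
#' Computes (raw - mean dark)/(mean flat - mean dark) with frame-averaged
#' flats and darks. Values below `floor` are clamped (counted in the QC
#' attributes, never silent).
#'
#' @param raw raw detector frame (matrix of counts).
#' @param flats flat frames: matrix or 3D array (nz, nt, n_flats).
#' @param darks dark frames, same layout.
#' @param floor clamp floor for the normalized values (default 1e-6).
#' @return matrix of normalized intensities (about 1 in background) with
#'   attributes `n_clamped` and `bg_mean` (image mean, a cheap background
#'   proxy for empty-beam checks).
#' @export
normalize_projection <- function(raw, flats, darks, floor = 1e-6) {
  fl <- frame_mean(flats)
  dk <- frame_mean(darks)
  if (!all(dim(fl) == dim(raw)) || !all(dim(dk) == dim(raw)))
    stop("flat/dark shape does not match the raw frame")
  denom <- fl - dk
  bad <- sum(denom <= 0)
  if (bad > 0)
    stop("flat mean <= dark mean at ", bad, " pixel(s); cannot normalize")
  v <- (raw - dk) / denom
  ncl <- sum(v < floor)
  if (ncl > 0) v[v < floor] <- floor
  structure(v, n_clamped = ncl, bg_mean = mean(v))
}

#' @keywords internal
frame_mean <- function(x) {
  if (length(dim(x)) == 3) apply(x, c(1, 2), mean) else x
}

#' Modified Bronnikov Algorithm: single-distance phase retrieval
#'
#' Applies the regularised Fourier filter to the contrast g = 1 - I:
#'   phi = IFFT[ FFT(g) / (|kappa|^2 + alpha) ],
#' with kappa the Nyquist-normalised frequency grid (Nyquist = 1), computed
#' on a mirror-padded copy of the image and cropped back. The DC mode is
#' zeroed rather than inverted, so the retrieved phase is zero-mean over the
#' padded field. The physical prefactor (k/z_eff etc.) is absorbed into the
#' phase scale; BAC's gamma calibrates the product.
#'
#' @param values normalized intensity image (matrix), about 1 in background.
#' @param alpha regularization parameter, > 0, in squared Nyquist-normalised
#'   frequency units (default 1e-3).
#' @param pad mirror padding fraction per side (default 0.25; use 0 on
#'   periodic test patterns).
#' @return matrix: the scaled approximate phase.
#' @export
mba <- function(values, alpha = 1e-3, pad = 0.25) {
  if (alpha <= 0) stop("alpha must be > 0")
  g <- 1 - values
  gp <- mirror_pad(g, pad)
  p <- attr(gp, "pad")
  G <- fft2(gp)
  G[1, 1] <- 0                       # kappa = 0: regularized, not inverted
  phi <- Re(ifft2(G / (kappa2_grid(nrow(gp), ncol(gp)) + alpha)))
  crop_pad(phi, p)
}

#' Matched MBA regularization for a homogeneous specimen
#'
#' For a specimen with a single delta/beta ratio the absorption and phase
#' contrasts are proportional, and there is a regularization strength at
#' which the MBA filter followed by BAC at gamma = 1 recovers the pure
#' absorption image exactly in the weak-contrast limit:
#'   alpha* = (2 k / (z_eff * (pi/p)^2)) * (beta/delta),
#' with k the wavenumber, z_eff the effective propagation distance and p
#' the pixel size (alpha* is in squared Nyquist-normalised frequency
#' units, like [mba()]'s `alpha`). This is the sense in which the
#' regularizer is "absorption-dependent": it encodes how much of the
#' measured contrast is absorption rather than propagated phase.
#'
#' @param geometry a `phasect_geometry`.
#' @param pixel_um sampling pitch of the projections in micrometres.
#' @param delta_beta_ratio assumed delta/beta of the material (default 50,
#'   the dried-tissue regime of the bundled phantoms).
#' @return scalar alpha.
#' @export
mba_alpha <- function(geometry, pixel_um, delta_beta_ratio = 50) {
  z_um <- geometry$z_eff_mm * 1e3
  2 * geometry$k_um / (z_um * (pi / pixel_um)^2) / delta_beta_ratio
}

#' Fourier-multiplier Laplacian
#'
#' Multiplies by -|kappa|^2 on the (mirror-padded) frequency grid, the same
#' Nyquist-normalised grid MBA uses, so that bac()'s composed transfer
#' function is exactly |kappa|^2/(|kappa|^2 + alpha).
#'
#' @param img matrix.
#' @param pad mirror padding fraction per side.
#' @return matrix, zero-mean.
#' @export
fourier_laplacian <- function(img, pad = 0.25) {
  xp <- mirror_pad(img, pad)
  p <- attr(xp, "pad")
  out <- Re(ifft2(fft2(xp) * (-kappa2_grid(nrow(xp), ncol(xp)))))
  crop_pad(out, p)
}

#' Bronnikov Aided Correction
#'
#' Divides the normalized intensity by (1 + gamma * laplacian(phi)) using
#' the MBA phase, removing the edge-enhancement term of the near-field
#' intensity while averaging noise (the Laplacian filter is smooth at high
#' frequencies after MBA regularisation). gamma = 0 returns the input
#' unchanged. The denominator is clamped away from zero at `floor`
#' (clamp count reported, never silent).
#'
#' Sign convention: [mba()] retrieves a positive "projected density" phase
#' (material deficit in intensity maps to positive phase), under which the
#' near-field intensity is I = I_0 (1 + laplacian(phi_scaled)); the
#' corrective denominator therefore carries a plus sign. Conventions that
#' define the optical phase as negative write the same correction with a
#' minus sign.
#'
#' @param values normalized intensity image.
#' @param phase MBA phase retrieved from the same frame.
#' @param gamma correction strength >= 0.
#' @param floor denominator clamp floor (default 0.05).
#' @param pad mirror padding fraction for the Laplacian.
#' @return matrix of corrected intensities with attribute `n_clamped`.
#' @export
bac <- function(values, phase, gamma, floor = 0.05, pad = 0.25) {
  if (!all(dim(values) == dim(phase)))
    stop("normalized frame and phase map differ in shape")
  stopifnot(gamma >= 0)
  if (gamma == 0) return(structure(unclass_plain(values), n_clamped = 0L))
  den <- 1 + gamma * fourier_laplacian(phase, pad)
  ncl <- sum(den < floor)
  if (ncl > 0) den[den < floor] <- floor
  structure(unclass_plain(values) / den, n_clamped = ncl)
}

#' @keywords internal
unclass_plain <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Edge-overshoot metric of a step image
#'
#' Fraction by which the image over/undershoots the two known plateau
#' levels of an edge, relative to the step height: max(overshoot above the
#' high plateau, undershoot below the low plateau)/|hi - lo|. Used to
#' quantify edge enhancement and its removal by BAC.
#'
#' @param img image (or profile) containing an edge between flat levels.
#' @param lo,hi the true plateau levels.
#' @return non-negative scalar.
#' @export
edge_overshoot <- function(img, lo, hi) {
  h <- abs(hi - lo)
  max(max(img) - max(lo, hi), min(lo, hi) - min(img), 0) / h
}

#' Grid-search the BAC strength gamma on an edge image
#'
#' Scores each candidate gamma by the edge-overshoot metric and keeps the
#' flat-region coefficient of variation as a noise guard: among gammas whose
#' flat-region CV does not exceed the uncorrected one, picks the smallest
#' overshoot.
#'
#' @param values normalized edge image.
#' @param phase MBA phase of the same image.
#' @param lo,hi true plateau levels of the edge.
#' @param flat_region logical mask (or index matrix) of a flat patch for
#'   the CV guard.
#' @param gammas candidate grid (default seq(0, 2, by = 0.05)).
#' @param ... passed to [bac()].
#' @return tibble with columns gamma, overshoot, flat_cv, plus attribute
#'   `best` (the selected row).
#' @export
tune_bac_gamma <- function(values, phase, lo, hi, flat_region,
                           gammas = seq(0, 2, by = 0.05), ...) {
  cv <- function(x) stats::sd(x) / mean(x)
  res <- lapply(gammas, function(g) {
    out <- bac(values, phase, g, ...)
    c(overshoot = edge_overshoot(out, lo, hi), flat_cv = cv(out[flat_region]))
  })
  tb <- tibble::tibble(gamma = gammas,
                       overshoot = vapply(res, `[[`, 0, "overshoot"),
                       flat_cv = vapply(res, `[[`, 0, "flat_cv"))
  ok <- tb$flat_cv <= tb$flat_cv[1] + 1e-12
  best <- tb[ok, ][which.min(tb$overshoot[ok]), ]
  attr(tb, "best") <- best
  tb
}

#' Retrieve contrast for every projection of a scan
#'
#' Runs normalize -> MBA -> BAC per angle and collects a QC table
#' (clamp counts, min/max, background mean per frame). Deterministic.
#'
#' @param scan a `phasect_scan` (or anything with frames/flats/darks/angles).
#' @param alpha MBA regularization; default NULL uses the matched value
#'   [mba_alpha()] for a delta/beta = 50 specimen at the scan's geometry.
#' @param gamma BAC strength (default 1, the matched value when `alpha` is
#'   matched; tune on a simulated edge with [tune_bac_gamma()] otherwise).
#' @param pad mirror padding fraction.
#' @param floor_norm,floor_bac clamp floors.
#' @return list of class `phasect_contrast`: `stack` (nz, nt, n_angles
#'   array of corrected intensities), `angles`, `pixel_um`, `geometry`,
#'   `qc` tibble, and the parameters used.
#' @export
retrieve_stack <- function(scan, alpha = NULL, gamma = 1, pad = 0.25,
                           floor_norm = 1e-6, floor_bac = 0.05) {
  if (is.null(alpha)) alpha <- mba_alpha(scan$geometry, scan$pixel_um)
  na <- dim(scan$frames)[3]
  stack <- array(0, dim(scan$frames))
  qc <- vector("list", na)
  for (i in seq_len(na)) {
    nrm <- normalize_projection(scan$frames[, , i], scan$flats, scan$darks,
                                floor = floor_norm)
    phi <- mba(nrm, alpha = alpha, pad = pad)
    out <- bac(nrm, phi, gamma = gamma, floor = floor_bac, pad = pad)
    stack[, , i] <- out
    qc[[i]] <- tibble::tibble(angle = scan$angles[i],
                              clamped_norm = attr(nrm, "n_clamped"),
                              clamped_bac = attr(out, "n_clamped"),
                              min = min(out), max = max(out),
                              bg_mean = attr(nrm, "bg_mean"))
  }
  structure(list(stack = stack, angles = scan$angles, arc = scan$arc,
                 pixel_um = scan$pixel_um, geometry = scan$geometry,
                 qc = do.call(rbind, qc),
                 alpha = alpha, gamma = gamma, pad = pad),
            class = "phasect_contrast")
}

#' Convert corrected intensities to line integrals
#'
#' -log of the contrast image: background maps to ~0 and denser material to
#' larger values, the quantity filtered back-projection expects.
#'
#' @param values positive intensity image (matrix or stack).
#' @return same shape, -log(values).
#' @export
to_line_integrals <- function(values) {
  if (any(values <= 0)) stop("nonpositive contrast values; check clamping")
  -log(values)
}
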