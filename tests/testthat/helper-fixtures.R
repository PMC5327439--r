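# Shared fixtures: small geometries and phantoms built in code.

geom_inverse <- function(z2 = 20, src = 2)
  acquisition_geometry("inverse", z1 = 200, z2 = z2,
                       detector_pixel_um = 0.95 * (200 + z2) / 200,
                       source_fwhm_um = src)

geom_parallel <- function(z2 = 20)
  acquisition_geometry("parallel", z2 = z2, detector_pixel_um = 0.95,
                       source_fwhm_um = 0)

# single centered sphere, explicit radius/optics
sphere_phantom <- function(size = 64, r = 10, delta = 1e-6, beta = NULL) {
  ctr <- (size + 1) / 2
  obj <- data.frame(cz = ctr, cy = ctr, cx = ctr, rz = r, ry = r, rx = r,
                    delta = delta)
  if (!is.null(beta)) obj$beta <- beta
  build_phantom("disk_stack", size = size, objects = obj, seed = 1)
}

# sinusoidal single-mode test image on an n x n periodic grid
mode_image <- function(n, m, eps) {
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  list(values = 1 - eps * cos(2 * pi * m * x / n),
       phase = eps * cos(2 * pi * m * x / n),
       kappa0 = 2 * m / n)
}

with_seed_test <- function(seed, code) {
  withr::with_seed(seed, code)
}

# flats/darks arrays for a given frame size
flat_dark_set <- function(geometry, n = 64, photons = 1e4, n_frames = 10,
                          dark = 100, seed = 900) {
  flats <- array(0, c(n, n, n_frames))
  for (i in seq_len(n_frames))
    flats[, , i] <- corrupt(matrix(1, n, n), geometry, photons,
                            seed = seed + i, offset = dark)
  darks <- array(dark, c(n, n, n_frames))
  list(flats = flats, darks = darks)
}
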