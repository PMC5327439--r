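#' Desk-scale cortex recovery study (simulate -> retrieve -> reconstruct ->
#' segment)
#'
#' Runs the full pipeline twice on one cortex-layers phantom under the
#' package's reference laboratory conditions (inverse geometry z1 = 200 mm,
#' z2 = 20 mm, 9.25 keV, 0.95 um sampling, 10 um source spot): once
#' noise-free (correlation of the reconstructed effective contrast with the
#' ground-truth attenuation map, after the standard factor-2 resampling)
#' and once with Poisson counting noise plus per-column gain errors
#' (wavelet ring removal, full-resolution reconstruction, threshold-based
#' cell segmentation scored against the generator's component truth).
#'
#' The expensive wave-optical forward simulation is shared between the two
#' noise conditions.
#'
#' @param size phantom grid (voxels per axis).
#' @param n_angles projections over a 180 degree arc.
#' @param n_cells ground-truth cell count.
#' @param photon_count flat-field counts for the noisy condition.
#' @param ring_sigma per-column gain sd for the noisy condition.
#' @param seed master seed.
#' @return list: `r_noisefree` (Pearson correlation, binned volume vs
#'   binned truth), `n_true`, `n_found`, `n_matched` (found cells whose
#'   centroid lies within one radius + 2 voxels of a true cell),
#'   `volume_noisy`, `volume_noisefree`, `labels`, `phantom`.
#' @export
cortex_recovery_study <- function(size = 128, n_angles = 200, n_cells = 40,
                                  photon_count = 1e4, ring_sigma = 0.02,
                                  seed = 1) {
  vox <- 0.95
  ph <- build_phantom("cortex_layers", size = size, seed = seed,
                      n_cells = n_cells, voxel_size_um = vox)
  g <- acquisition_geometry("inverse", z1 = 200, z2 = 20,
                            detector_pixel_um = vox * 220 / 200,
                            source_fwhm_um = 10)
  scan0 <- simulate_scan(ph, g, n_angles = n_angles, arc = 180,
                         noise = FALSE, ring_sigma = 0, seed = seed)
  ideal <- attr(scan0, "intensities")
  ctr0 <- retrieve_stack(scan0)
  vol0 <- reconstruct_scan(ctr0, ring = "none", bin = 2)
  mu <- 2 * g$k_um * ph$beta
  mu2 <- bin2_volume(mu)
  r <- stats::cor(as.vector(vol0$values), as.vector(mu2))

  scan1 <- simulate_scan(ph, g, n_angles = n_angles, arc = 180,
                         photon_count = photon_count,
                         ring_sigma = ring_sigma, noise = TRUE, seed = seed,
                         intensities = ideal)
  ctr1 <- retrieve_stack(scan1)
  vol1 <- reconstruct_scan(ctr1, ring = "wavelet", bin = 1)
  # threshold at the midpoint of the nominal cell/background attenuation
  cells <- ph$component_truth[ph$component_truth$kind == "cell", ]
  mu_cell <- 2 * g$k_um * cells$beta[1]
  mu_bg <- 2 * g$k_um * min(ph$beta[ph$beta > 0])
  lab <- threshold_label(vol1, gray_range = c((mu_cell + mu_bg) / 2, Inf),
                         min_voxels = 27)
  st <- cell_statistics(lab)
  matched <- 0L
  if (nrow(st) > 0 && nrow(cells) > 0) {
    for (i in seq_len(nrow(st))) {
      d <- sqrt((cells$cz * vox - st$cz_um[i])^2 +
                (cells$cy * vox - st$cy_um[i])^2 +
                (cells$cx * vox - st$cx_um[i])^2)
      if (any(d <= (cells$rz + 2) * vox)) matched <- matched + 1L
    }
  }
  list(r_noisefree = r, n_true = nrow(cells), n_found = nrow(st),
       n_matched = matched, volume_noisy = vol1, volume_noisefree = vol0,
       labels = lab, phantom = ph, geometry = g)
}

#' Factor-2 binning of a 3D volume (all three axes)
#' @param v 3D array with even dimensions (trimmed if odd).
#' @return array of half size.
#' @export
bin2_volume <- function(v) {
  d <- dim(v)
  n1 <- 2 * (d[1] %/% 2)
  out <- array(0, c(n1 / 2, d[2] %/% 2, d[3] %/% 2))
  for (z in seq_len(n1 / 2))
    out[z, , ] <- 0.5 * (bin2(v[2 * z - 1, , ]) + bin2(v[2 * z, , ]))
  out
}
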