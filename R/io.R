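# Dataset layout, readers/writers and the top-level pipeline driver.
#
# A scan directory is plain and inspectable: frames.tif / flats.tif /
# darks.tif (multi-page 32-bit float), gain.tif, angles.txt (one degree
# value per line) and config.yaml (geometry, seed, photon count, scale
# factors). 32-bit TIFF samples are integer-quantized over [0, 1]; integer
# count data are therefore stored divided by 2^32 - 1 (one count = one
# sample step), which round-trips bit-exactly, while other data are divided
# by a power-of-two ceiling of their maximum (quantization ~2e-10 relative).

#' @keywords internal
tiff_scale <- function(x) {
  # the 32-bit sample codec truncates values to 2^32 steps over [0, 1];
  # integer counts below 2^31 stored at scale 2^32 (with a half-step
  # offset against truncation) occupy exact sample steps
  if (all(x >= 0) && all(x < 2^31) && all(x == round(x))) return(2^32)
  2^ceiling(log2(max(x, 1)))
}

#' @keywords internal
write_stack_tiff <- function(arr, path) {
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  sc <- tiff_scale(arr)
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(i) arr[, , i] / sc + 0.5 / 2^32)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  sc
}

#' @keywords internal
read_stack_tiff <- function(path, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * scale
  if (scale == 2^32) arr <- round(arr)
  arr
}

#' Write a simulated or measured scan to a plain directory
#'
#' @param scan a `phasect_scan`.
#' @param path directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sc_f <- write_stack_tiff(scan$frames, file.path(path, "frames.tif"))
  sc_fl <- write_stack_tiff(scan$flats, file.path(path, "flats.tif"))
  sc_d <- write_stack_tiff(scan$darks, file.path(path, "darks.tif"))
  sc_g <- write_stack_tiff(scan$gain_map, file.path(path, "gain.tif"))
  writeLines(format(scan$angles, digits = 17), file.path(path, "angles.txt"))
  g <- scan$geometry
  cfg <- list(
    geometry = list(mode = g$mode, z1 = g$z1, z2 = g$z2,
                    energy_kev = g$energy_kev,
                    detector_pixel_um = g$detector_pixel_um,
                    source_fwhm_um = g$source_fwhm_um),
    arc = scan$arc, photon_count = scan$photon_count,
    ring_sigma = scan$ring_sigma, dark_fraction = scan$dark_fraction,
    noise = scan$noise, seed = scan$seed, pixel_um = scan$pixel_um,
    scales = list(frames = sc_f, flats = sc_fl, darks = sc_d, gain = sc_g))
  write_config(cfg, file.path(path, "config.yaml"))
  invisible(path)
}

#' Read a scan directory written by [write_scan()]
#'
#' @param path scan directory.
#' @return a `phasect_scan` (bit-exact round trip of [write_scan()]).
#' @export
read_scan <- function(path) {
  cfgf <- file.path(path, "config.yaml")
  if (!file.exists(cfgf)) stop("no config.yaml in ", path)
  for (f in c("frames.tif", "flats.tif", "darks.tif"))
    if (!file.exists(file.path(path, f)))
      stop("scan directory is missing ", f)
  cfg <- read_config(cfgf)
  gd <- cfg$geometry
  geom <- acquisition_geometry(gd$mode, z1 = if (gd$mode == "parallel") 200
                               else gd$z1, z2 = gd$z2,
                               energy_kev = gd$energy_kev,
                               detector_pixel_um = gd$detector_pixel_um,
                               source_fwhm_um = gd$source_fwhm_um)
  frames <- read_stack_tiff(file.path(path, "frames.tif"), cfg$scales$frames)
  flats <- read_stack_tiff(file.path(path, "flats.tif"), cfg$scales$flats)
  darks <- read_stack_tiff(file.path(path, "darks.tif"), cfg$scales$darks)
  gain <- read_stack_tiff(file.path(path, "gain.tif"), cfg$scales$gain)[, , 1]
  angles <- as.numeric(readLines(file.path(path, "angles.txt")))
  if (length(angles) != dim(frames)[3])
    stop("angles.txt (", length(angles), ") does not match frame count (",
         dim(frames)[3], ")")
  structure(list(frames = frames, flats = flats, darks = darks,
                 gain_map = gain, angles = angles, arc = cfg$arc,
                 geometry = geom, photon_count = cfg$photon_count,
                 ring_sigma = cfg$ring_sigma,
                 dark_fraction = cfg$dark_fraction,
                 noise = cfg$noise, seed = cfg$seed,
                 pixel_um = cfg$pixel_um),
            class = "phasect_scan")
}

#' Write a reconstructed volume (multi-page float TIFF + JSON provenance)
#'
#' @param volume a `phasect_volume`.
#' @param path output TIFF path; a `<path>.json` sidecar stores voxel size,
#'   scale and provenance.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  v <- volume$values
  off <- min(v, 0)
  sc <- tiff_scale(v - off)
  pages <- lapply(seq_len(dim(v)[1]), function(z) (v[z, , ] - off) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  side <- list(voxel_size_um = volume$voxel_size_um, scale = sc,
               offset = off, dim = dim(v), provenance = volume$provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#' @param path TIFF path with its `.json` sidecar.
#' @return a `phasect_volume`.
#' @export
read_volume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- unlist(side$dim)
  v <- array(0, d)
  for (z in seq_along(pages)) v[z, , ] <- pages[[z]] * side$scale + side$offset
  recon_volume(v, side$voxel_size_um,
               provenance = as.list(side$provenance))
}

#' Write / read a pipeline configuration (YAML)
#'
#' Configurations round-trip losslessly; every pipeline run writes its
#' resolved configuration next to its outputs.
#' @param config named list.
#' @param path YAML file path.
#' @return `path` (write) or the config list (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("unparseable config: ", path)
  cfg
}

#' Run the full pipeline from a configuration
#'
#' simulate (optional) -> retrieve -> reconstruct -> segment (optional),
#' writing every product plus the resolved configuration and a structured
#' log into `out_dir`. All randomness flows from the single config seed.
#'
#' Config keys: `seed`; `simulate` (preset, size, n_angles, arc,
#' photon_count, ring_sigma, noise, voxel_size_um, n_cells) or `scan_dir`;
#' `geometry` (mode, z1, z2, energy_kev, detector_pixel_um, source_fwhm_um);
#' `retrieve` (alpha, gamma, pad); `reconstruct` (ring, bin, roi_pad);
#' optional `segment` (gray_quantiles or gray_range, min_voxels).
#'
#' @param config named list or path to a YAML file.
#' @param out_dir output directory.
#' @return list with `volume` (a `phasect_volume`), optional `labels`,
#'   `qc`, and the resolved config, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  need <- function(key, where = config) {
    if (is.null(where[[key]])) stop("config is missing key '", key, "'")
    where[[key]]
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- need("seed")
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  gd <- need("geometry")
  geom <- acquisition_geometry(need("mode", gd),
                               z1 = gd$z1 %||% 200, z2 = gd$z2 %||% 20,
                               energy_kev = gd$energy_kev %||% 9.25,
                               detector_pixel_um = gd$detector_pixel_um %||% 0.54,
                               source_fwhm_um = gd$source_fwhm_um %||% 10)
  if (!is.null(config$simulate)) {
    sm <- config$simulate
    phant <- build_phantom(need("preset", sm), size = need("size", sm),
                           seed = seed,
                           voxel_size_um = sm$voxel_size_um %||%
                             geom$effective_pixel_um,
                           n_cells = sm$n_cells %||% 40)
    scan <- simulate_scan(phant, geom, n_angles = need("n_angles", sm),
                          arc = sm$arc %||% 180,
                          photon_count = sm$photon_count %||% 1e4,
                          ring_sigma = sm$ring_sigma %||% 0.02,
                          noise = sm$noise %||% TRUE, seed = seed)
    logline("simulated %s phantom size=%d n_angles=%d seed=%d",
            sm$preset, sm$size, sm$n_angles, seed)
  } else if (!is.null(config$scan_dir)) {
    scan <- read_scan(config$scan_dir)
    phant <- NULL
    logline("read scan from %s (%d frames)", config$scan_dir,
            dim(scan$frames)[3])
  } else stop("config is missing key 'simulate' or 'scan_dir'")
  rt <- need("retrieve")
  contrast <- retrieve_stack(scan, alpha = need("alpha", rt),
                             gamma = need("gamma", rt),
                             pad = rt$pad %||% 0.25)
  logline("retrieved %d projections (alpha=%g gamma=%g; %d BAC clamps)",
          length(contrast$angles), contrast$alpha, contrast$gamma,
          sum(contrast$qc$clamped_bac))
  rc <- need("reconstruct")
  vol <- reconstruct_scan(contrast, ring = rc$ring %||% "wavelet",
                          bin = rc$bin %||% 1, roi_pad = rc$roi_pad %||% 0)
  write_volume(vol, file.path(out_dir, "volume.tif"))
  utils::write.csv(contrast$qc, file.path(out_dir, "retrieval_qc.csv"),
                   row.names = FALSE)
  logline("reconstructed %s volume (%s ring removal, bin=%d)",
          paste(dim(vol$values), collapse = "x"),
          vol$provenance$ring, vol$provenance$bin)
  labels <- NULL
  if (!is.null(config$segment)) {
    sg <- config$segment
    gr <- if (!is.null(sg$gray_range)) unlist(sg$gray_range)
          else stats::quantile(vol$values,
                               unlist(sg$gray_quantiles %||% c(0.985, 1)),
                               names = FALSE)
    labels <- threshold_label(vol, gray_range = gr,
                              min_voxels = sg$min_voxels %||% 27)
    utils::write.csv(cell_statistics(labels),
                     file.path(out_dir, "cells.csv"), row.names = FALSE)
    logline("segmented %d cells in [%g, %g]", max(labels$labels),
            gr[1], gr[2])
  }
  config$resolved_geometry <- unclass(geom)
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(list(volume = vol, labels = labels, qc = contrast$qc,
                 config = config))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
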