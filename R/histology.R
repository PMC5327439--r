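# Virtual histology: thickness bookkeeping, arbitrary-axis slabs
# (single / MIP / MinIP / mean), H&E-like rendering and threshold-based
# single-cell segmentation with 3D statistics.

#' Number of reconstructed slices emulating a physical section thickness
#'
#' Largest integer n with n * voxel <= thickness. A 30 um histological
#' section at a 0.95 um voxel is emulated by a projection over 31 slices.
#'
#' @param thickness_um desired physical section thickness (um, > 0).
#' @param voxel_um voxel size (um, > 0).
#' @return integer number of slices (>= 1 whenever thickness >= voxel).
#' @export
n_slices_for_thickness <- function(thickness_um, voxel_um) {
  stopifnot(thickness_um > 0, voxel_um > 0)
  as.integer(floor(thickness_um / voxel_um + 1e-9))
}

#' Virtual section (slab) through a reconstructed volume
#'
#' Pointwise max / min / mean (or a single slice) over `n_slices`
#' consecutive planes. Axis-aligned planes are exact; oblique planes are
#' resampled trilinearly along a unit `normal` with in-plane basis vectors
#' chosen deterministically. Maximum intensity projections emulate thick
#' stained sections (cytoarchitecture); minimum intensity projections
#' highlight low-density structures such as vessel lumina.
#'
#' @param volume a `phasect_volume` (or plain 3D array).
#' @param plane `"axial"` (z), `"coronal"` (y), `"sagittal"` (x), or a
#'   numeric length-3 normal vector (z, y, x components) for oblique
#'   sections through the volume center.
#' @param start first plane index (1-based; for oblique planes, offset in
#'   voxels along the normal from the volume center minus half the slab).
#' @param n_slices slab depth in planes (>= 1).
#' @param mode `"single"`, `"max"`, `"min"` or `"mean"`.
#' @return a `phasect_section`: list with `image`, `mode`, `plane`,
#'   `n_slices`, `physical_thickness_um` (= n_slices * voxel size).
#' @export
slab <- function(volume, plane = "axial", start = 1, n_slices = 1,
                 mode = c("max", "min", "mean", "single")) {
  mode <- match.arg(mode)
  if (mode == "single" && n_slices != 1)
    stop("mode 'single' implies n_slices = 1")
  vol <- if (inherits(volume, "phasect_volume")) volume$values else volume
  vox <- if (inherits(volume, "phasect_volume")) volume$voxel_size_um else 1
  stopifnot(n_slices >= 1)
  d <- dim(vol)
  planes <- if (is.character(plane)) {
    plane <- match.arg(plane, c("axial", "coronal", "sagittal"))
    ax <- switch(plane, axial = 1L, coronal = 2L, sagittal = 3L)
    if (start < 1 || start + n_slices - 1 > d[ax])
      stop("slab [", start, ", ", start + n_slices - 1,
           "] out of bounds for axis of length ", d[ax])
    lapply(seq(start, start + n_slices - 1), function(i)
      switch(plane, axial = vol[i, , ], coronal = vol[, i, ],
             sagittal = vol[, , i]))
  } else {
    oblique_planes(vol, plane, start, n_slices)
  }
  img <- switch(mode,
                single = planes[[1]],
                max = Reduce(pmax, planes),
                min = Reduce(pmin, planes),
                mean = Reduce(`+`, planes) / length(planes))
  structure(list(image = img, mode = mode, plane = plane,
                 start = start, n_slices = as.integer(n_slices),
                 physical_thickness_um = n_slices * vox),
            class = "phasect_section")
}

#' @keywords internal
oblique_planes <- function(vol, normal, start, n_slices) {
  stopifnot(length(normal) == 3)
  nrm <- normal / sqrt(sum(normal^2))
  # deterministic in-plane basis: cross products with the least-aligned axis
  seed_ax <- diag(3)[which.min(abs(nrm)), ]
  e1 <- cross3(nrm, seed_ax); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(nrm, e1)
  d <- dim(vol)
  ctr <- (d + 1) / 2
  m <- min(d)
  uu <- seq(-(m - 1) / 2, (m - 1) / 2)
  offs <- start - 1 + seq_len(n_slices) - (n_slices + 1) / 2
  lapply(offs, function(o) {
    P1 <- outer(uu * e1[1], uu * e2[1], `+`) + ctr[1] + o * nrm[1]
    P2 <- outer(uu * e1[2], uu * e2[2], `+`) + ctr[2] + o * nrm[2]
    P3 <- outer(uu * e1[3], uu * e2[3], `+`) + ctr[3] + o * nrm[3]
    # clamp to the volume (nearest-edge extension at the boundary)
    P1 <- pmin(pmax(P1, 1), d[1]); P2 <- pmin(pmax(P2, 1), d[2])
    P3 <- pmin(pmax(P3, 1), d[3])
    matrix(trilerp(vol, as.vector(P1), as.vector(P2), as.vector(P3)), m, m)
  })
}

#' @keywords internal
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' @keywords internal
trilerp <- function(vol, z, y, x) {
  d <- dim(vol)
  out <- numeric(length(z))
  z0 <- floor(z); y0 <- floor(y); x0 <- floor(x)
  wz <- z - z0; wy <- y - y0; wx <- x - x0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    zi <- z0 + dz; yi <- y0 + dy; xi <- x0 + dx
    w <- (if (dz == 0) 1 - wz else wz) * (if (dy == 0) 1 - wy else wy) *
         (if (dx == 0) 1 - wx else wx)
    ok <- which(zi >= 1 & zi <= d[1] & yi >= 1 & yi <= d[2] &
                xi >= 1 & xi <= d[3] & w > 0)
    if (length(ok))
      out[ok] <- out[ok] + w[ok] * vol[cbind(zi[ok], yi[ok], xi[ok])]
  }
  out
}

#' Threshold-based cell segmentation (scriptable "brush")
#'
#' Segments voxels whose intensity lies inside `gray_range` within a seed
#' mask (the scriptable counterpart of an interactive threshold brush),
#' groups them into connected components (26-connectivity by default) and
#' discards components below `min_voxels` (count reported in the result).
#'
#' @param volume a `phasect_volume` or 3D array.
#' @param gray_range numeric (lo, hi), lo < hi.
#' @param seed_mask logical 3D array of the same shape (NULL = everywhere).
#' @param connectivity 26 (default) or 6.
#' @param min_voxels minimum component size kept (default 27, about a
#'   1.5 um radius sphere at 1 um voxels).
#' @return a `phasect_labels`: `labels` (3D integer array, 0 background),
#'   `table` (tibble: label, n_voxels, centroid z/y/x in um, mean
#'   intensity), `n_discarded`, and the parameters.
#' @export
threshold_label <- function(volume, gray_range, seed_mask = NULL,
                            connectivity = 26, min_voxels = 27) {
  stopifnot(length(gray_range) == 2, gray_range[1] < gray_range[2],
            connectivity %in% c(6, 26))
  vol <- if (inherits(volume, "phasect_volume")) volume$values else volume
  vox <- if (inherits(volume, "phasect_volume")) volume$voxel_size_um else 1
  d <- dim(vol)
  sel <- vol >= gray_range[1] & vol <= gray_range[2]
  if (!is.null(seed_mask)) {
    if (!all(dim(seed_mask) == d)) stop("seed mask shape mismatch")
    sel <- sel & (seed_mask > 0)
  }
  idx <- which(sel)
  labels <- array(0L, d)
  if (length(idx) == 0) {
    warning("threshold range selects no voxels")
    return(new_labelmap(labels, vol, vox, gray_range, min_voxels, 0L))
  }
  # connect foreground voxels via half-neighbourhood offsets
  zi <- ((idx - 1) %% d[1]) + 1
  yi <- (((idx - 1) %/% d[1]) %% d[2]) + 1
  xi <- ((idx - 1) %/% (d[1] * d[2])) + 1
  offs <- neighbour_offsets(connectivity)
  inv <- integer(prod(d)); inv[idx] <- seq_along(idx)
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    dz <- offs[k, 1]; dy <- offs[k, 2]; dx <- offs[k, 3]
    ok <- zi + dz >= 1 & zi + dz <= d[1] & yi + dy >= 1 & yi + dy <= d[2] &
          xi + dx >= 1 & xi + dx <= d[3]
    nb <- idx[ok] + dz + dy * d[1] + dx * d[1] * d[2]
    hit <- inv[nb] > 0
    if (any(hit))
      edges[[length(edges) + 1]] <- cbind(inv[idx[ok]][hit], inv[nb][hit])
  }
  em <- do.call(rbind, c(edges, list(matrix(integer(0), ncol = 2))))
  g <- igraph::make_graph(edges = as.vector(t(em)), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_voxels)
  n_discarded <- length(sizes) - length(keep)
  # deterministic labels: order components by their first voxel index
  first <- vapply(keep, function(cc) min(idx[comp == cc]), 0)
  keep <- keep[order(first)]
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  labels[idx] <- relab[comp]
  new_labelmap(labels, vol, vox, gray_range, min_voxels,
               as.integer(n_discarded))
}

#' @keywords internal
neighbour_offsets <- function(connectivity) {
  full <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  full <- full[rowSums(abs(full)) > 0, ]
  if (connectivity == 6) full <- full[rowSums(abs(full)) == 1, ]
  # half neighbourhood (each unordered pair once)
  full[full[, 3] > 0 | (full[, 3] == 0 & full[, 2] > 0) |
       (full[, 3] == 0 & full[, 2] == 0 & full[, 1] > 0), , drop = FALSE]
}

#' @keywords internal
new_labelmap <- function(labels, vol, vox, gray_range, min_voxels,
                         n_discarded) {
  K <- max(labels)
  tb <- if (K == 0) {
    tibble::tibble(label = integer(), n_voxels = integer(),
                   cz_um = numeric(), cy_um = numeric(), cx_um = numeric(),
                   mean_intensity = numeric())
  } else {
    d <- dim(labels)
    idx <- which(labels > 0)
    lab <- labels[idx]
    zi <- ((idx - 1) %% d[1]) + 1
    yi <- (((idx - 1) %/% d[1]) %% d[2]) + 1
    xi <- ((idx - 1) %/% (d[1] * d[2])) + 1
    nv <- tabulate(lab, K)
    tibble::tibble(
      label = seq_len(K),
      n_voxels = nv,
      cz_um = as.vector(tapply(zi, lab, mean)) * vox,
      cy_um = as.vector(tapply(yi, lab, mean)) * vox,
      cx_um = as.vector(tapply(xi, lab, mean)) * vox,
      mean_intensity = as.vector(tapply(vol[idx], lab, mean)))
  }
  structure(list(labels = labels, table = tb, gray_range = gray_range,
                 min_voxels = min_voxels, n_discarded = n_discarded,
                 voxel_size_um = vox),
            class = "phasect_labels")
}

#' @export
print.phasect_labels <- function(x, ...) {
  cat(sprintf("<phasect_labels> %d cells (%d small components discarded)\n",
              max(x$labels), x$n_discarded))
  invisible(x)
}

#' Per-cell statistics from a label map
#'
#' Centroids (um), voxel counts, equivalent-sphere diameters and, when a
#' layer mask is supplied, the layer each cell belongs to plus per-layer
#' counts (attribute `layer_counts`).
#'
#' @param labelmap a `phasect_labels`.
#' @param layer_mask optional integer 3D array assigning a layer id to
#'   every voxel.
#' @return tibble: label, n_voxels, cz_um, cy_um, cx_um, mean_intensity,
#'   equiv_diameter_um (and layer).
#' @export
cell_statistics <- function(labelmap, layer_mask = NULL) {
  tb <- labelmap$table
  vox <- labelmap$voxel_size_um
  tb$equiv_diameter_um <- 2 * (3 * tb$n_voxels * vox^3 / (4 * pi))^(1 / 3)
  if (!is.null(layer_mask)) {
    if (!all(dim(layer_mask) == dim(labelmap$labels)))
      stop("layer mask shape mismatch")
    idx <- which(labelmap$labels > 0)
    lab <- labelmap$labels[idx]
    lay <- layer_mask[idx]
    tb$layer <- as.vector(tapply(lay, lab, function(v)
      as.integer(names(sort(table(v), decreasing = TRUE))[1])))
    counts <- table(tb$layer)
    attr(tb, "layer_counts") <- tibble::tibble(
      layer = as.integer(names(counts)), n_cells = as.integer(counts))
  }
  tb
}

#' H&E-like rendering of a virtual section
#'
#' Monotone white-to-pink-to-magenta colour ramp (denser tissue = darker,
#' as in hematoxylin/eosin stains) with percentile-clipped contrast.
#' Purely cosmetic.
#'
#' @param image scalar matrix (or `phasect_section`).
#' @param probs clipping percentiles, default c(0.01, 0.99).
#' @return integer array (nrow, ncol, 3) of 8-bit RGB values in 0..255.
#' @export
render_hne <- function(image, probs = c(0.01, 0.99)) {
  img <- if (inherits(image, "phasect_section")) image$image else image
  qs <- stats::quantile(img, probs, names = FALSE)
  x <- if (qs[2] > qs[1]) pmin(pmax((img - qs[1]) / (qs[2] - qs[1]), 0), 1)
       else img * 0
  ramp <- grDevices::colorRamp(c("#FFFFFF", "#F6C9DD", "#D1699E", "#8C2155",
                                 "#4A0E2E"))
  rgb <- ramp(as.vector(x))
  out <- array(0L, c(nrow(img), ncol(img), 3))
  out[, , 1] <- as.integer(round(rgb[, 1]))
  out[, , 2] <- as.integer(round(rgb[, 2]))
  out[, , 3] <- as.integer(round(rgb[, 3]))
  out
}
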