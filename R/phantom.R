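#' Build a brain-like optical phantom
#'
#' Generates a voxelised phantom of the x-ray optical constants
#' delta (refractive decrement, drives phase shift) and beta (extinction,
#' drives attenuation) of a weakly absorbing dried-tissue specimen,
#' n = 1 - delta + i beta. The phantom is the ground truth against which
#' phase retrieval, reconstruction and segmentation are scored.
#'
#' Presets:
#' \describe{
#'   \item{`disk_stack`}{explicit ellipsoids (analytic-oracle friendly);
#'     pass them via `objects`, or get a small default stack.}
#'   \item{`cortex_layers`}{a tissue cylinder with horizontal bands of
#'     differing cell density; `n_cells` non-touching spherical "cells" of
#'     5--10 um diameter with elevated delta, emulating somata in a dried
#'     protein matrix.}
#'   \item{`vessel_tree`}{tissue cylinder pierced by low-delta tubes
#'     (air-filled vessels after solvent evaporation).}
#'   \item{`fiber_bundle`}{aligned high-delta cylinders along x (myelinated
#'     axon bundle after lipid removal).}
#'   \item{`slab`}{a half-width cuboid giving a single straight edge,
#'     for edge-enhancement studies.}
#' }
#'
#' Default optical constants are set for dried protein matrix at 9.25 keV
#' (delta about 2e-6 for dense somata, 5e-7 for neuropil background,
#' delta/beta = 50 -- the phase-dominant regime that motivates
#' phase-contrast imaging).
#'
#' @param preset one of `"disk_stack"`, `"cortex_layers"`, `"vessel_tree"`,
#'   `"fiber_bundle"`, `"slab"`.
#' @param size grid size per axis in voxels (>= 32); the grid is
#'   `size x size x size` (z, y, x).
#' @param seed integer seed; the phantom is deterministic in (arguments, seed).
#' @param voxel_size_um voxel edge length in micrometres.
#' @param n_cells number of cells for `cortex_layers`.
#' @param n_layers number of density bands for `cortex_layers`.
#' @param objects optional data frame of ellipsoids for `disk_stack`
#'   (columns cz, cy, cx, rz, ry, rx in voxels, 1-based centers, and
#'   delta, beta).
#' @param delta_cell,delta_bg,delta_beta_ratio optical-constant knobs.
#' @return an `phasect_phantom`: list with 3D arrays `delta`, `beta`
#'   (dim nz, ny, nx), `voxel_size_um`, and `component_truth`, a tibble of
#'   every placed object (kind, center, radii in voxels, delta, beta).
#' @export
build_phantom <- function(preset = c("cortex_layers", "disk_stack",
                                     "vessel_tree", "fiber_bundle", "slab"),
                          size = 64, seed = 1,
                          voxel_size_um = 0.95,
                          n_cells = 40, n_layers = 4,
                          objects = NULL,
                          delta_cell = 2e-6, delta_bg = 5e-7,
                          delta_beta_ratio = 50) {
  preset <- match.arg(preset)
  stopifnot(size >= 32, voxel_size_um > 0, delta_beta_ratio >= 10)
  n <- as.integer(size)
  delta <- array(0, c(n, n, n))
  beta <- array(0, c(n, n, n))
  truth <- list()
  b_of <- function(d) d / delta_beta_ratio
  ctr <- (n + 1) / 2

  add_ellipsoid <- function(cz, cy, cx, rz, ry, rx, dval, bval, kind) {
    if (cz - rz < 1 || cz + rz > n || cy - ry < 1 || cy + ry > n ||
        cx - rx < 1 || cx + rx > n)
      stop("phantom object exceeds the grid (center ", cz, ",", cy, ",", cx,
           " radii ", rz, ",", ry, ",", rx, " on ", n, "^3)")
    zi <- max(1, floor(cz - rz)):min(n, ceiling(cz + rz))
    yi <- max(1, floor(cy - ry)):min(n, ceiling(cy + ry))
    xi <- max(1, floor(cx - rx)):min(n, ceiling(cx + rx))
    dz2 <- ((zi - cz) / rz)^2
    dy2 <- ((yi - cy) / ry)^2
    dx2 <- ((xi - cx) / rx)^2
    msk <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
    dd <- delta[zi, yi, xi]; bb <- beta[zi, yi, xi]
    dd[msk] <- dval; bb[msk] <- bval
    delta[zi, yi, xi] <<- dd; beta[zi, yi, xi] <<- bb
    truth[[length(truth) + 1]] <<- list(kind = kind, cz = cz, cy = cy, cx = cx,
                                        rz = rz, ry = ry, rx = rx,
                                        delta = dval, beta = bval)
  }

  fill_cylinder <- function(radius, dval, bval, kind = "layer") {
    # tissue column along z
    d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
    msk <- d2 <= radius^2
    for (z in seq_len(n)) {
      dd <- delta[z, , ]; bb <- beta[z, , ]
      dd[msk] <- dval; bb[msk] <- bval
      delta[z, , ] <<- dd; beta[z, , ] <<- bb
    }
    truth[[length(truth) + 1]] <<- list(kind = kind, cz = ctr, cy = ctr,
                                        cx = ctr, rz = n / 2, ry = radius,
                                        rx = radius, delta = dval, beta = bval)
  }

  with_seed(seed, {
    if (preset == "disk_stack") {
      if (is.null(objects)) {
        objects <- data.frame(
          cz = ctr + c(-n / 4, 0, n / 4), cy = rep(ctr, 3), cx = rep(ctr, 3),
          rz = rep(n / 10, 3), ry = n * c(0.30, 0.22, 0.14),
          rx = n * c(0.30, 0.22, 0.14),
          delta = delta_cell * c(0.5, 1, 0.75))
      }
      if (is.null(objects$beta)) objects$beta <- b_of(objects$delta)
      for (i in seq_len(nrow(objects)))
        add_ellipsoid(objects$cz[i], objects$cy[i], objects$cx[i],
                      objects$rz[i], objects$ry[i], objects$rx[i],
                      objects$delta[i], objects$beta[i], kind = "cell")
    } else if (preset == "slab") {
      # half-width cuboid: straight edge at the central column
      xi <- seq_len(floor(ctr))
      delta[, , xi] <- delta_cell
      beta[, , xi] <- b_of(delta_cell)
      truth[[1]] <- list(kind = "layer", cz = ctr, cy = ctr, cx = ctr / 2,
                         rz = n / 2, ry = n / 2, rx = ctr / 2,
                         delta = delta_cell, beta = b_of(delta_cell))
    } else if (preset == "cortex_layers") {
      rcyl <- 0.42 * n
      fill_cylinder(rcyl, delta_bg, b_of(delta_bg))
      # band edges along y; cell density per band rises layerwards
      edges <- round(seq(1, n + 1, length.out = n_layers + 1))
      weights <- seq_len(n_layers)
      band_of_cell <- sample(seq_len(n_layers), n_cells * 2, replace = TRUE,
                             prob = weights)
      r_um <- stats::runif(n_cells * 2, 2.5, 5)     # 5-10 um diameter
      r_vox <- pmax(r_um / voxel_size_um, 1.5)
      placed <- matrix(numeric(0), ncol = 4)        # cz, cy, cx, r
      k <- 0; tries <- 0
      while (k < n_cells && tries < 20000) {
        tries <- tries + 1
        i <- k + 1
        r <- r_vox[(tries - 1) %% length(r_vox) + 1]
        band <- band_of_cell[(tries - 1) %% length(band_of_cell) + 1]
        lo <- max(edges[band], r + 2); hi <- min(edges[band + 1], n - r - 1)
        if (lo >= hi) next
        cy <- stats::runif(1, lo, hi)
        cz <- stats::runif(1, r + 2, n - r - 1)
        cx <- stats::runif(1, r + 2, n - r - 1)
        if ((cy - ctr)^2 + (cx - ctr)^2 > (rcyl - r - 1)^2) next
        if (nrow(placed) > 0) {
          dmin <- sqrt((placed[, 1] - cz)^2 + (placed[, 2] - cy)^2 +
                       (placed[, 3] - cx)^2) - placed[, 4] - r
          if (min(dmin) < 2) next   # keep cells non-touching
        }
        add_ellipsoid(cz, cy, cx, r, r, r, delta_cell, b_of(delta_cell),
                      kind = "cell")
        placed <- rbind(placed, c(cz, cy, cx, r))
        k <- i
      }
      if (k < n_cells)
        stop("could not place ", n_cells, " non-touching cells on a ",
             n, "^3 grid; reduce n_cells or enlarge the grid")
    } else if (preset == "vessel_tree") {
      fill_cylinder(0.42 * n, delta_bg * 2, b_of(delta_bg * 2))
      n_vessels <- 4
      for (v in seq_len(n_vessels)) {
        r <- stats::runif(1, 1.5, 3)
        y0 <- stats::runif(1, 0.35 * n, 0.65 * n)
        x0 <- stats::runif(1, 0.35 * n, 0.65 * n)
        drift <- stats::runif(2, -0.15, 0.15)
        for (z in seq(4, n - 3)) {
          cy <- y0 + drift[1] * (z - n / 2)
          cx <- x0 + drift[2] * (z - n / 2)
          yi <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
          xi <- max(1, floor(cx - r)):min(n, ceiling(cx + r))
          msk <- outer((yi - cy)^2, (xi - cx)^2, `+`) <= r^2
          dd <- delta[z, yi, xi]; bb <- beta[z, yi, xi]
          dd[msk] <- 0; bb[msk] <- 0   # air lumen
          delta[z, yi, xi] <- dd; beta[z, yi, xi] <- bb
        }
        truth[[length(truth) + 1]] <- list(kind = "vessel", cz = ctr, cy = y0,
                                           cx = x0, rz = n / 2 - 3, ry = r,
                                           rx = r, delta = 0, beta = 0)
      }
    } else if (preset == "fiber_bundle") {
      n_fibers <- 25
      r <- max(1.0 / voxel_size_um, 1.2)
      for (f in seq_len(n_fibers)) {
        cz <- stats::runif(1, 0.3 * n, 0.7 * n)
        cy <- stats::runif(1, 0.3 * n, 0.7 * n)
        zi <- max(1, floor(cz - r)):min(n, ceiling(cz + r))
        yi <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
        msk <- outer((zi - cz)^2, (yi - cy)^2, `+`) <= r^2
        for (x in seq_len(n)) {
          dd <- delta[zi, yi, x]; bb <- beta[zi, yi, x]
          dd[msk] <- delta_cell; bb[msk] <- b_of(delta_cell)
          delta[zi, yi, x] <- dd; beta[zi, yi, x] <- bb
        }
        truth[[length(truth) + 1]] <- list(kind = "fiber", cz = cz, cy = cy,
                                           cx = ctr, rz = r, ry = r,
                                           rx = n / 2, delta = delta_cell,
                                           beta = b_of(delta_cell))
      }
    }
  })

  ct <- if (length(truth) == 0) {
    tibble::tibble(kind = character(), cz = numeric(), cy = numeric(),
                   cx = numeric(), rz = numeric(), ry = numeric(),
                   rx = numeric(), delta = numeric(), beta = numeric())
  } else {
    tibble::as_tibble(do.call(rbind, lapply(truth, function(o)
      data.frame(kind = o$kind, cz = o$cz, cy = o$cy, cx = o$cx,
                 rz = o$rz, ry = o$ry, rx = o$rx,
                 delta = o$delta, beta = o$beta))))
  }
  structure(list(delta = delta, beta = beta,
                 voxel_size_um = voxel_size_um,
                 component_truth = ct,
                 preset = preset, seed = seed),
            class = "phasect_phantom")
}

#' Empty phantom of a given size
#' @param size voxels per axis.
#' @param voxel_size_um voxel size in micrometres.
#' @return a `phasect_phantom` with delta = beta = 0 everywhere.
#' @export
empty_phantom <- function(size = 64, voxel_size_um = 0.95) {
  n <- as.integer(size)
  structure(list(delta = array(0, c(n, n, n)), beta = array(0, c(n, n, n)),
                 voxel_size_um = voxel_size_um,
                 component_truth = tibble::tibble(
                   kind = character(), cz = numeric(), cy = numeric(),
                   cx = numeric(), rz = numeric(), ry = numeric(),
                   rx = numeric(), delta = numeric(), beta = numeric()),
                 preset = "empty", seed = NA_integer_),
            class = "phasect_phantom")
}

#' @export
print.phasect_phantom <- function(x, ...) {
  d <- dim(x$delta)
  cat(sprintf("<phasect_phantom> preset=%s  %dx%dx%d voxels @ %.3g um\n",
              x$preset, d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  %d ground-truth objects; max delta=%.3g, max beta=%.3g\n",
              nrow(x$component_truth), max(x$delta), max(x$beta)))
  invisible(x)
}
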