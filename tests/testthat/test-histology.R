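test_that("slice count for a physical thickness uses the floor rule", {
  expect_identical(n_slices_for_thickness(30, 0.95), 31L)
  expect_identical(n_slices_for_thickness(1, 1), 1L)
  expect_identical(n_slices_for_thickness(10, 3), 3L)
  expect_error(n_slices_for_thickness(-1, 1))
  expect_error(n_slices_for_thickness(5, 0))
})

test_that("slabs honor thickness bookkeeping and order statistics", {
  set.seed(2)
  vol <- recon_volume(array(rnorm(32^3), c(32, 32, 32)), 0.95)
  s1 <- slab(vol, "axial", start = 5, n_slices = 1, mode = "single")
  expect_equal(s1$image, vol$values[5, , ])
  expect_equal(s1$physical_thickness_um, 0.95)
  sm <- slab(vol, "coronal", 3, 7, "max")
  sn <- slab(vol, "coronal", 3, 7, "min")
  sa <- slab(vol, "coronal", 3, 7, "mean")
  expect_true(all(sm$image >= sa$image))
  expect_true(all(sa$image >= sn$image))
  expect_equal(sm$physical_thickness_um, 7 * 0.95)
  # constant volume: constant sections in every mode
  cv <- recon_volume(array(3, c(16, 16, 16)), 1)
  for (m in c("max", "min", "mean"))
    expect_equal(slab(cv, "sagittal", 2, 5, m)$image, matrix(3, 16, 16))
  expect_error(slab(vol, "axial", 30, 5), "out of bounds")
  expect_error(slab(vol, "axial", 1, 3, "single"), "single")
})

test_that("max slab folds associatively over sub-slabs", {
  set.seed(3)
  vol <- recon_volume(array(rnorm(20^3), c(20, 20, 20)), 1)
  whole <- slab(vol, "axial", 1, 10, "max")$image
  part <- pmax(slab(vol, "axial", 1, 5, "max")$image,
               slab(vol, "axial", 6, 5, "max")$image)
  expect_equal(whole, part)
})

test_that("oblique slabs through a constant volume stay constant", {
  cv <- recon_volume(array(2, c(24, 24, 24)), 1)
  s <- slab(cv, plane = c(1, 1, 0.5), start = 1, n_slices = 3, mode = "mean")
  expect_equal(s$image, matrix(2, 24, 24), tolerance = 1e-12)
})

test_that("threshold labeling counts non-touching cells exactly", {
  ph <- build_phantom("cortex_layers", size = 64, n_cells = 15, seed = 11)
  vol <- recon_volume(ph$delta, ph$voxel_size_um)
  lab <- threshold_label(vol, gray_range = c(1e-6, 1), min_voxels = 10)
  expect_identical(max(lab$labels), 15L)
  expect_identical(nrow(lab$table), 15L)
  # empty range warns, zero labels
  expect_warning(l0 <- threshold_label(vol, gray_range = c(10, 20)),
                 "no voxels")
  expect_identical(max(l0$labels), 0L)
})

test_that("connectivity and gray range split touching objects", {
  v <- array(0, c(24, 24, 24))
  # two spheres touching at a one-voxel neck of lower intensity
  for (c0 in list(c(12, 12, 8), c(12, 12, 16))) {
    for (z in 1:24) for (y in 1:24) for (x in 1:24)
      if ((z - c0[1])^2 + (y - c0[2])^2 + (x - c0[3])^2 <= 16)
        v[z, y, x] <- 1
  }
  v[12, 12, 12] <- 0.5  # neck voxel, dimmer
  lab1 <- threshold_label(v, gray_range = c(0.4, 1.5), min_voxels = 5)
  expect_identical(max(lab1$labels), 1L)
  lab2 <- threshold_label(v, gray_range = c(0.9, 1.5), min_voxels = 5)
  expect_identical(max(lab2$labels), 2L)
})

test_that("seed masks restrict the brush and small components are dropped", {
  v <- array(0, c(16, 16, 16))
  v[4:6, 4:6, 4:6] <- 1    # 27 voxels
  v[12, 12, 12] <- 1       # single-voxel speck
  mask <- array(TRUE, c(16, 16, 16))
  lab <- threshold_label(v, c(0.5, 2), seed_mask = mask, min_voxels = 27)
  expect_identical(max(lab$labels), 1L)
  expect_identical(lab$n_discarded, 1L)
  mask[, , 1:8] <- FALSE   # exclude the cube
  lab2 <- suppressWarnings(threshold_label(v, c(0.5, 2), seed_mask = mask,
                                           min_voxels = 1))
  expect_identical(lab2$table$n_voxels, 1L)
})

test_that("cell statistics recover centroids and diameters", {
  ph <- sphere_phantom(48, r = 10, delta = 1e-6)
  lab <- threshold_label(recon_volume(ph$delta, 2), c(1e-7, 1))
  st <- cell_statistics(lab)
  expect_equal(st$cz_um, 24.5 * 2, tolerance = 0.5 * 2 / 24.5)
  expect_equal(st$equiv_diameter_um, 2 * 10 * 2, tolerance = 0.02)
  empty <- suppressWarnings(threshold_label(recon_volume(array(0, c(8, 8, 8)),
                                                         1), c(1, 2)))
  expect_identical(nrow(cell_statistics(empty)), 0L)
})

test_that("per-layer counts follow a supplied layer mask", {
  v <- array(0, c(16, 16, 16))
  v[3:5, 3:5, 3:5] <- 1
  v[10:12, 10:12, 10:12] <- 1
  layers <- array(1L, c(16, 16, 16)); layers[, 9:16, ] <- 2L
  lab <- threshold_label(v, c(0.5, 2), min_voxels = 5)
  st <- cell_statistics(lab, layer_mask = layers)
  lc <- attr(st, "layer_counts")
  expect_identical(lc$n_cells, c(1L, 1L))
})

test_that("H&E rendering is monotone, bounded 8-bit and constant-safe", {
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  rgb <- render_hne(img)
  expect_true(all(rgb >= 0L & rgb <= 255L))
  lum <- 0.2126 * rgb[, , 1] + 0.7152 * rgb[, , 2] + 0.0722 * rgb[, , 3]
  ord <- order(img)
  expect_true(all(diff(lum[ord]) <= 1e-9))  # denser = darker
  cst <- render_hne(matrix(4, 5, 5))
  expect_equal(length(unique(as.vector(cst[, , 1]))), 1L)
})
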