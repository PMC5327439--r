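test_that("projection of an empty phantom is identically zero", {
  fp <- forward_project(empty_phantom(32), geom_inverse(), 13.7)
  expect_true(all(fp$phase == 0))
  expect_true(all(fp$log_amplitude == 0))
})

test_that("homogeneous slab projection matches the closed form -k*delta*t", {
  g <- geom_inverse()
  ph <- build_phantom("slab", size = 64, delta_cell = 2e-6)
  fp <- forward_project(ph, g, 0)
  # at 0 deg every ray crosses the full slab thickness (32 voxels)
  expected <- -g$k_um * 2e-6 * 32 * ph$voxel_size_um
  expect_equal(max(abs(fp$phase - expected)), 0, tolerance = abs(expected) * 0.01)
  expect_true(all(fp$phase <= 0))
  expect_true(all(exp(2 * fp$log_amplitude) <= 1 &
                  exp(2 * fp$log_amplitude) > 0))
})

test_that("projection is periodic in the rotation angle", {
  ph <- sphere_phantom(48, r = 8)
  a <- forward_project(ph, geom_inverse(), 0)
  b <- forward_project(ph, geom_inverse(), 360)
  expect_equal(a$phase, b$phase, tolerance = 1e-12)
})

test_that("NaN phantoms are refused", {
  ph <- empty_phantom(32)
  ph$delta[1] <- NaN
  expect_error(forward_project(ph, geom_inverse(), 0), "NaN")
})

test_that("uniform unit wave propagates to uniform unit intensity", {
  ew <- list(phase = matrix(0, 48, 48), log_amplitude = matrix(0, 48, 48),
             pixel_um = 0.95)
  I <- fresnel_propagate(ew, geom_inverse())
  expect_equal(max(abs(I - 1)), 0, tolerance = 1e-12)
})

test_that("Fresnel propagator is unitary on pure phase objects", {
  ph <- sphere_phantom(96, r = 15, delta = 1e-6, beta = 0)
  fp <- forward_project(ph, geom_inverse(), 0)
  for (z2 in c(5, 20, 60)) {
    I <- fresnel_propagate(fp, geom_inverse(z2))
    expect_equal(mean(I), 1, tolerance = 1e-6)
  }
})

test_that("edge overshoot grows with propagation distance and vanishes at z=0", {
  ph <- build_phantom("slab", size = 96, delta_cell = 5e-7)
  fp <- forward_project(ph, geom_inverse(), 90)
  att <- exp(2 * fp$log_amplitude)
  ov <- vapply(c(5, 20, 60), function(z2)
    edge_overshoot(fresnel_propagate(fp, geom_inverse(z2)), min(att), max(att)),
    0)
  expect_true(all(diff(ov) > 0))
  I0 <- fresnel_propagate(fp, acquisition_geometry("parallel", z2 = 1e-9,
                                                   source_fwhm_um = 0))
  expect_lt(edge_overshoot(I0, min(att), max(att)), 0.005)
})

test_that("corrupt reproduces the blurred intensity in the high-count limit", {
  g <- geom_inverse(z2 = 20, src = 10)  # penumbra 1 um
  ph <- sphere_phantom(48, r = 8)
  I <- fresnel_propagate(forward_project(ph, g, 0), g)
  raw <- corrupt(I, g, photon_count = 1e12, seed = 4)
  blurred <- corrupt(I, g, photon_count = 1, seed = 1, poisson = FALSE)
  expect_equal(mean(abs(raw / 1e12 - blurred)), 0, tolerance = 1e-3)
})

test_that("corrupt is deterministic for a fixed seed and honors column gain", {
  g <- geom_inverse()
  I <- matrix(1, 48, 48)
  a <- corrupt(I, g, 1e4, seed = 11)
  b <- corrupt(I, g, 1e4, seed = 11)
  expect_identical(a, b)
  gain <- matrix(1, 48, 48); gain[, 20] <- 1.05
  cnt <- corrupt(I, g, 1e4, gain_map = gain, seed = 12)
  expect_equal(mean(cnt[, 20]) / mean(cnt[, -20]), 1.05, tolerance = 0.02)
  expect_error(corrupt(I - 2, g, 1e4), "negative")
})

test_that("simulate_scan lays out angles, flats and darks as stated", {
  ph <- empty_phantom(32)
  g <- geom_inverse(z2 = 4)
  scan <- simulate_scan(ph, g, n_angles = 4, arc = 180, seed = 2,
                        photon_count = 1e4)
  expect_equal(scan$angles, c(0, 45, 90, 135))
  expect_identical(dim(scan$flats)[3], 20L)
  expect_identical(dim(scan$darks)[3], 20L)
  expect_gt(mean(scan$flats), mean(scan$darks))
  # empty phantom: normalized frames are 1 within Poisson noise
  nrm <- normalize_projection(scan$frames[, , 2], scan$flats, scan$darks)
  expect_equal(mean(nrm), 1, tolerance = 3 / sqrt(1e4 * 32 * 32))
})

test_that("identical seeds give bit-identical scans", {
  ph <- sphere_phantom(32, r = 5)
  g <- geom_inverse(z2 = 4)
  a <- simulate_scan(ph, g, 3, seed = 9)
  b <- simulate_scan(ph, g, 3, seed = 9)
  expect_identical(a$frames, b$frames)
  expect_identical(a$gain_map, b$gain_map)
})

test_that("noise-free small-z scan reduces to the attenuation image", {
  ph <- sphere_phantom(48, r = 8, delta = 1e-6)
  g <- acquisition_geometry("inverse", z1 = 200, z2 = 0.01,
                            detector_pixel_um = 0.95, source_fwhm_um = 0)
  scan <- simulate_scan(ph, g, 2, noise = FALSE, ring_sigma = 0, seed = 1)
  nrm <- normalize_projection(scan$frames[, , 1], scan$flats, scan$darks)
  att <- exp(2 * forward_project(ph, g, 0)$log_amplitude)
  # overshoot beyond the attenuation range under 0.5% of the step height
  expect_lt(edge_overshoot(nrm, min(att), max(att)), 0.005)
  expect_equal(max(abs(nrm - att)), 0, tolerance = 5e-4)
})

test_that("simulator warns when the Fresnel zone outgrows the pixel", {
  ph <- empty_phantom(32)
  g <- acquisition_geometry("inverse", z1 = 200, z2 = 190,
                            detector_pixel_um = 0.3, source_fwhm_um = 0)
  expect_warning(simulate_scan(ph, g, 2, noise = FALSE, seed = 1),
                 "Fresnel zone")
})
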