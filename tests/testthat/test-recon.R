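test_that("analytic sinogram obeys chord length, mass conservation, linearity", {
  th <- 180 * (0:39) / 40
  one <- analytic_sinogram(data.frame(x0 = 0, y0 = 0, a = 60, b = 60,
                                      value = 1), th, 256)
  expect_equal(one$values[1, 128], 2 * 60 * sqrt(1 - (0.5 / 60)^2),
               tolerance = 1e-9)
  mass <- rowSums(one$values)
  expect_lt(diff(range(mass)) / mean(mass), 1e-9)
  e1 <- data.frame(x0 = -40, y0 = 0, a = 10, b = 10, value = 1)
  e2 <- data.frame(x0 = 40, y0 = 20, a = 8, b = 5, value = 2)
  s12 <- analytic_sinogram(rbind(e1, e2), th, 256)
  s1 <- analytic_sinogram(e1, th, 256)
  s2 <- analytic_sinogram(e2, th, 256)
  expect_equal(s12$values, s1$values + s2$values, tolerance = 1e-12)
})

test_that("FBP reconstructs a centered disk to 5% inside, 2% outside", {
  sg <- analytic_sinogram(data.frame(x0 = 0, y0 = 0, a = 60, b = 60,
                                     value = 1), 180 * (0:399) / 400, 256)
  sl <- fbp_parallel(sg)
  expect_equal(max(abs(fbp_parallel(sinogram(sg$values * 0, sg$angles)))), 0)
  g <- (0:255) - 127.5
  R2 <- outer(g^2, g^2, `+`)
  expect_equal(mean(sl[R2 < 50^2]), 1, tolerance = 0.05)
  expect_lt(abs(mean(sl[R2 > 70^2 & R2 < 120^2])), 0.02)
})

test_that("FBP equals brute-force back-projection after identical filtering", {
  th <- 180 * (0:23) / 24
  sg <- analytic_sinogram(data.frame(x0 = 3, y0 = -2, a = 8, b = 6,
                                     value = 2), th, 32)
  q <- phasect:::filter_rows(sg$values / sg$channel_pitch)
  bf <- backproject_bruteforce(q, th)
  ff <- fbp_parallel(sg, circle = FALSE)
  expect_lt(max(abs(bf - ff)), 1e-6)
})

test_that("FBP is linear and consistent under rotation-center shifts", {
  th <- 180 * (0:99) / 100
  sa <- analytic_sinogram(data.frame(x0 = 5, y0 = 0, a = 15, b = 10,
                                     value = 1), th, 96)
  sb <- analytic_sinogram(data.frame(x0 = -10, y0 = 8, a = 12, b = 12,
                                     value = 0.5), th, 96)
  lin <- fbp_parallel(sinogram(2 * sa$values + 3 * sb$values, th))
  expect_equal(lin, 2 * fbp_parallel(sa) + 3 * fbp_parallel(sb),
               tolerance = 1e-10, ignore_attr = TRUE)
  ell <- data.frame(x0 = 3, y0 = -2, a = 20, b = 14, value = 1)
  r1 <- fbp_parallel(analytic_sinogram(ell, th, 128))
  r2 <- fbp_parallel(analytic_sinogram(ell, th, 128,
                                       rotation_center = 63.5 + 3))
  i <- 20:105
  expect_lt(sqrt(mean((r1[i, i] - r2[i + 3, i + 3])^2)) / diff(range(r1)),
            0.01)
})

test_that("slice mass matches sinogram mass for complete parallel data", {
  th <- 180 * (0:199) / 200
  sg <- analytic_sinogram(data.frame(x0 = 0, y0 = 0, a = 60, b = 60,
                                     value = 1), th, 256)
  sl <- fbp_parallel(sg)
  expect_equal(sum(sl), mean(rowSums(sg$values)), tolerance = 0.03)
})

test_that("ROI padding reduces truncation cupping by more than half", {
  th <- 180 * (0:299) / 300
  full <- analytic_sinogram(data.frame(x0 = 0, y0 = 0, a = 200, b = 200,
                                       value = 0.01), th, 512)
  roi <- sinogram(full$values[, 193:320], th, 1, (512 - 1) / 2 - 192)
  g <- (0:127) - 63.5
  R <- sqrt(outer(g^2, g^2, `+`))
  cup <- function(sl) abs(mean(sl[R > 50 & R < 60]) - mean(sl[R < 10]))
  c_un <- cup(fbp_parallel(roi))
  c_pad <- cup(fbp_parallel(pad_roi(roi, 64)))
  expect_lt(c_pad, 0.5 * c_un)
})

test_that("ROI padding is a no-op on complete data and at width zero", {
  th <- 180 * (0:149) / 150
  sg <- analytic_sinogram(data.frame(x0 = 5, y0 = -3, a = 30, b = 25,
                                     value = 1), th, 128)
  expect_identical(pad_roi(sg, 0), sg)
  r1 <- fbp_parallel(sg)
  r2 <- fbp_parallel(pad_roi(sg, 64))
  g <- (0:127) - 63.5
  R <- sqrt(outer(g^2, g^2, `+`))
  expect_lt(max(abs(r1 - r2)[R < 63]), 1e-6)
})

test_that("bin2 averages 2x2 blocks and shrinks white-noise variance 4x", {
  expect_equal(bin2(matrix(7, 8, 8)), matrix(7, 4, 4))
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(bin2(cb), matrix(0.5, 4, 4))
  set.seed(5)
  w <- matrix(rnorm(256^2), 256, 256)
  expect_equal(var(as.vector(bin2(w))), 0.25, tolerance = 0.1)
  expect_message(bin2(matrix(1, 5, 4)), "trimming")
})

test_that("FDK agrees with parallel FBP in the small-cone limit", {
  ph <- build_phantom("disk_stack", size = 48, seed = 2)
  # half-cone about 1.8 deg
  g <- acquisition_geometry("cone", z1 = 0.72, z2 = 50,
                            detector_pixel_um = 0.95 * (0.72 + 50) / 0.72,
                            source_fwhm_um = 0)
  na <- 90
  ang <- 360 * (0:(na - 1)) / na
  stack <- array(0, c(48, 48, na))
  for (i in seq_len(na))
    stack[, , i] <- -2 * forward_project(ph, g, ang[i])$log_amplitude
  vf <- fdk_cone(stack, g, ang, pitch_um = 0.95)
  vp <- phasect:::fbp_stack(stack, ang, 0.95)
  expect_lt(sqrt(mean((vf - vp)^2)) / diff(range(vp)), 0.02)
  expect_equal(max(abs(fdk_cone(stack * 0, g, ang, pitch_um = 0.95))), 0)
  expect_error(fdk_cone(stack, geom_parallel(), ang), "fbp_parallel")
})

test_that("FDK localizes a point-like bead to within one voxel", {
  obj <- data.frame(cz = 30, cy = 21, cx = 27, rz = 2.5, ry = 2.5, rx = 2.5,
                    delta = 2e-6)
  ph <- build_phantom("disk_stack", size = 48, objects = obj, seed = 1)
  g <- acquisition_geometry("cone", z1 = 0.72, z2 = 50,
                            detector_pixel_um = 0.95 * (0.72 + 50) / 0.72,
                            source_fwhm_um = 0)
  na <- 90
  ang <- 360 * (0:(na - 1)) / na
  stack <- array(0, c(48, 48, na))
  for (i in seq_len(na))
    stack[, , i] <- -2 * forward_project(ph, g, ang[i])$log_amplitude
  vb <- fdk_cone(stack, g, ang, pitch_um = 0.95)
  ctr <- colMeans(which(vb > 0.5 * max(vb), arr.ind = TRUE))
  expect_lt(max(abs(ctr - c(30, 21, 27))), 1)
})

test_that("reconstruct_scan recovers a disk-stack phantom end to end", {
  ph <- build_phantom("disk_stack", size = 48, seed = 3)
  g <- geom_inverse(z2 = 20)
  scan <- simulate_scan(ph, g, 90, noise = FALSE, ring_sigma = 0, seed = 3)
  ctr <- retrieve_stack(scan)
  vol <- reconstruct_scan(ctr, ring = "none")
  mu <- 2 * g$k_um * ph$beta
  expect_gt(cor(as.vector(vol$values), as.vector(mu)), 0.9)
  # determinism
  vol2 <- reconstruct_scan(retrieve_stack(scan), ring = "none")
  expect_identical(vol$values, vol2$values)
  expect_equal(vol$voxel_size_um, ph$voxel_size_um)
})

test_that("ring removal in the pipeline lowers the ring metric", {
  ph <- build_phantom("disk_stack", size = 48, seed = 3)
  g <- geom_inverse(z2 = 4)
  scan <- simulate_scan(ph, g, 90, noise = TRUE, photon_count = 1e4,
                        ring_sigma = 0.03, seed = 13)
  ctr <- retrieve_stack(scan)
  v_none <- reconstruct_scan(ctr, ring = "none")
  v_wav <- reconstruct_scan(ctr, ring = "wavelet")
  # ring metric: stripe metric of the middle-slice sinogram equivalent --
  # use the radial-artifact proxy: std of the angle-mean of the sinogram
  s_none <- stripe_metric(t(to_line_integrals(ctr$stack)[24, , ]))
  li <- to_line_integrals(ctr$stack)
  s_wav <- stripe_metric(
    ring_remove_wavelet(sinogram(t(li[24, , ]), ctr$angles))$values)
  expect_lt(s_wav, s_none)
  expect_false(identical(v_none$values, v_wav$values))
})
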