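test_that("normalization reproduces flats, clamps darks, errors on bad flats", {
  fl <- matrix(100, 8, 8); dk <- matrix(10, 8, 8)
  n1 <- normalize_projection(fl, fl, dk * 0)
  expect_equal(unclass(n1)[, ], matrix(1, 8, 8))
  n2 <- normalize_projection(dk, fl, dk)
  expect_true(all(n2 == 1e-6))
  expect_identical(attr(n2, "n_clamped"), 64L)
  expect_error(normalize_projection(fl, dk, fl), "flat mean <= dark mean")
})

test_that("normalization of a simulated empty scan is unbiased", {
  g <- geom_inverse(z2 = 4)
  scan <- simulate_scan(empty_phantom(32), g, 2, photon_count = 1e4,
                        ring_sigma = 0, seed = 21)
  nrm <- normalize_projection(scan$frames[, , 1], scan$flats, scan$darks)
  sigma <- 1 / sqrt(1e4) / 32  # image-mean sd at 1e4 counts, 32x32 pixels
  expect_lt(abs(mean(nrm) - 1), 3 * sigma * 2)
})

test_that("MBA is exact on a single Fourier mode (closed form)", {
  md <- mode_image(64, m = 5, eps = 0.01)
  alpha <- 1e-3
  phi <- mba(md$values, alpha = alpha, pad = 0)
  expect_lt(max(abs(phi - md$phase / (md$kappa0^2 + alpha))), 1e-10)
})

test_that("MBA is linear in the contrast and vanishes in the alpha limit", {
  md <- mode_image(32, m = 3, eps = 0.02)
  g1 <- mba(md$values, 1e-3, pad = 0)
  g2 <- mba(1 - 3 * (1 - md$values), 1e-3, pad = 0)
  expect_equal(g2, 3 * g1, tolerance = 1e-12)
  expect_identical(mba(matrix(1, 16, 16), 1e-3), matrix(0, 16, 16))
  expect_lt(max(abs(mba(md$values, 1e6, pad = 0))), 1e-7)
  expect_error(mba(md$values, alpha = 0), "alpha")
})

test_that("Fourier Laplacian has cosine eigenfunctions and kills constants", {
  md <- mode_image(48, m = 4, eps = 1)
  lp <- fourier_laplacian(1 - md$values, pad = 0)  # = cos mode itself
  expect_equal(lp, -md$kappa0^2 * (1 - md$values), tolerance = 1e-12)
  expect_equal(fourier_laplacian(matrix(5, 16, 16), pad = 0),
               matrix(0, 16, 16), tolerance = 1e-12)
})

test_that("laplacian(mba(v)) equals the composed Fourier multiplier", {
  set.seed(1)
  v <- 1 + matrix(rnorm(64^2, 0, 0.01), 64, 64)
  direct <- fourier_laplacian(mba(v, 1e-2, pad = 0), pad = 0)
  k2 <- phasect:::kappa2_grid(64, 64)
  G <- stats::fft(1 - v); G[1, 1] <- 0
  composed <- Re(stats::fft(G * (-k2) / (k2 + 1e-2), inverse = TRUE)) / 64^2
  expect_equal(direct, composed, tolerance = 1e-10)
})

test_that("BAC at gamma = 0 is the identity and shapes must agree", {
  v <- matrix(runif(64, 0.9, 1.1), 8, 8)
  expect_equal(unclass(bac(v, v * 0, gamma = 0))[, ], v)
  expect_error(bac(v, matrix(0, 4, 4), 1), "shape")
})

test_that("tuned BAC halves edge overshoot without raising flat noise", {
  g <- geom_inverse(z2 = 20)
  ph <- build_phantom("slab", size = 96, delta_cell = 5e-7)
  fp <- forward_project(ph, g, 90)
  I <- fresnel_propagate(fp, g)
  raw <- corrupt(I, g, photon_count = 1e4, seed = 3, offset = 100)
  fd <- flat_dark_set(g, 96, 1e4)
  nrm <- normalize_projection(raw, fd$flats, fd$darks)
  att <- exp(2 * fp$log_amplitude)
  alpha <- mba_alpha(g, ph$voxel_size_um)
  phi <- mba(nrm, alpha)
  flat <- matrix(FALSE, 96, 96); flat[20:76, 60:90] <- TRUE
  tb <- tune_bac_gamma(nrm, phi, min(att), max(att), flat)
  best <- attr(tb, "best")
  expect_lte(best$overshoot, 0.5 * tb$overshoot[1])
  expect_lte(best$flat_cv, tb$flat_cv[1])
})

test_that("retrieved stacks are deterministic and near 1 for empty scans", {
  g <- geom_inverse(z2 = 4)
  scan <- simulate_scan(empty_phantom(32), g, 4, photon_count = 1e5,
                        ring_sigma = 0, seed = 31)
  a <- retrieve_stack(scan)
  b <- retrieve_stack(scan)
  expect_identical(a$stack, b$stack)
  expect_identical(nrow(a$qc), 4L)
  expect_equal(mean(a$stack), 1, tolerance = 0.005)
})

test_that("BAC profile tracks true attenuation better than the raw frame", {
  g <- geom_inverse(z2 = 20)
  ph <- sphere_phantom(64, r = 12, delta = 1e-6)
  scan <- simulate_scan(ph, g, 2, noise = FALSE, ring_sigma = 0, seed = 1)
  ctr <- retrieve_stack(scan)
  nrm <- normalize_projection(scan$frames[, , 1], scan$flats, scan$darks)
  att <- exp(2 * forward_project(ph, g, 0)$log_amplitude)
  rmse <- function(x) sqrt(mean((-log(x) + log(att))^2))
  expect_lt(rmse(ctr$stack[, , 1]), rmse(matrix(nrm, nrow(nrm), ncol(nrm))))
})

test_that("line-integral conversion is -log with positivity checks", {
  expect_equal(to_line_integrals(matrix(1, 3, 3)), matrix(0, 3, 3))
  expect_equal(to_line_integrals(exp(-1)), 1)
  expect_error(to_line_integrals(c(1, 0)), "nonpositive")
  expect_lt(to_line_integrals(1.5), to_line_integrals(0.9))
})
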