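test_that("streaming accumulator matches the quadruple-loop oracle bit for bit", {
  set.seed(31)
  nk <- 3; nphi <- 8; npat <- 3
  vals <- array(runif(nk * nphi * npat, 0, 5), c(nk, nphi, npat))
  valid <- array(runif(nk * nphi * npat) > 0.25, c(nk, nphi, npat))
  ref <- brute_force_correlations(vals * valid, valid, nphi / 2 + 1)
  s <- accumulate_polar(NULL, vals, valid, k_grid = 1:nk, engine = "direct")
  expect_identical(s$C, ref$C)
  expect_identical(s$T, ref$T)
  expect_identical(s$D, ref$D)
  expect_identical(s$counts, ref$counts)
  # FFT engine computes the same sums up to round-off
  sf <- accumulate_polar(NULL, vals, valid, k_grid = 1:nk, engine = "fft")
  expect_equal(sf$C, ref$C, tolerance = 1e-12)
  expect_equal(sf$T, ref$T, tolerance = 1e-12)
  expect_equal(sf$D, ref$D, tolerance = 1e-12)
  expect_equal(sf$counts, ref$counts, tolerance = 1e-9)
})

test_that("constant patterns give the moment powers at every bin", {
  a <- 3
  vals <- array(a, c(2, 8, 1))
  s <- finalize(accumulate_polar(NULL, vals, k_grid = 1:2))
  expect_equal(max(abs(s$C - a^2)), 0, tolerance = 1e-12)
  expect_equal(max(abs(s$T - a^3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(s$D - a^4)), 0, tolerance = 1e-12)
  # pair counts for a full pattern: n_phi at psi = 0 and pi, 2 n_phi else
  expect_equal(s$counts[1, 1, 1], 8)
  expect_equal(s$counts[1, 1, 5], 8)
  expect_equal(s$counts[1, 2, 3], 16)
})

test_that("merging partial accumulators equals accumulating the union", {
  set.seed(32)
  nk <- 2; nphi <- 10
  v1 <- array(runif(nk * nphi * 2), c(nk, nphi, 2))
  v2 <- array(runif(nk * nphi * 3), c(nk, nphi, 3))
  a <- accumulate_polar(NULL, v1, k_grid = 1:nk)
  b <- accumulate_polar(NULL, v2, k_grid = 1:nk)
  merged <- finalize(merge_corr(a, b))
  vall <- array(c(v1, v2), c(nk, nphi, 5))
  direct <- finalize(accumulate_polar(NULL, vall, k_grid = 1:nk))
  expect_equal(merged$C, direct$C, tolerance = 1e-12)
  expect_equal(merged$counts, direct$counts)
  expect_equal(merged$ibar, direct$ibar, tolerance = 1e-12)
  expect_error(finalize(merged), "already finalized")
})

test_that("zero-count bins finalize to NA, not zero", {
  vals <- array(1, c(1, 6, 1))
  valid <- array(TRUE, c(1, 6, 1))
  valid[1, c(2, 4, 6), 1] <- FALSE       # only even shifts possible
  s <- finalize(accumulate_polar(NULL, vals, valid, k_grid = 1))
  expect_true(any(is.na(s$C)))
  expect_true(all(is.na(s$C[s$counts == 0])))
  expect_true(all(!is.na(s$C[s$counts > 0])))
})

test_that("polar resampling honors masks and preserves values", {
  g <- small_geometry(48)
  kg <- seq(0.02, 0.16, length.out = 5)
  # radially constant pattern: all bins equal the constant, both methods
  for (method in c("nearest", "bicubic")) {
    smp <- polar_sampler(g, kg, 24, method = method)
    pp <- polar_resample(matrix(7, 48, 48), smp)
    expect_equal(pp$values[pp$valid], rep(7, sum(pp$valid)), tolerance = 1e-9)
  }
  # nearest: every output value exists verbatim in the input
  set.seed(4)
  pat <- matrix(rnorm(48 * 48), 48, 48)
  smp <- polar_sampler(g, kg, 24, method = "nearest")
  pp <- polar_resample(pat, smp)
  expect_true(all(pp$values[pp$valid] %in% pat))
  # half-plane mask invalidates exactly the corresponding azimuth bins
  mask <- matrix(TRUE, 48, 48); mask[, 1:24] <- FALSE   # y < center masked
  ppm <- polar_resample(pat, smp, mask = mask)
  phi <- 2 * pi * (0:23) / 24
  masked_bins <- ppm$valid[3, ]          # a mid-radius shell
  expect_true(all(!masked_bins[sin(phi) < -0.3]))
  expect_true(all(masked_bins[sin(phi) > 0.3]))
})

test_that("included angle folds correctly in flat and curved modes", {
  expect_equal(included_angle(0.1, 0.1, pi / 3), pi / 3)
  expect_equal(included_angle(0.1, 0.2, 0), 0)
  expect_equal(included_angle(0.1, 0.2, 1.5 * pi), 0.5 * pi)
  # curved: theta1 = theta2 = 80 deg, dphi = pi -> psi = 160 deg < pi
  g <- small_geometry()
  th <- 80 * pi / 180
  k <- (2 / g$wavelength) * sin(pi / 2 - th)   # theta = pi/2 - theta_s
  psi <- included_angle(k, k, pi, geometry = g, flat = FALSE)
  expect_equal(psi * 180 / pi, 160, tolerance = 1e-6)
})

test_that("measured correlations converge to targets as 1/sqrt(n)", {
  model <- make_phantom("blobs", size = 32, voxel_size = 2.5, seed = 7)
  g <- small_geometry()
  kmap <- kamcorr:::detector_kmap(g, TRUE)
  kg <- seq(0.3, 0.8, length.out = 3) * max(kmap$k[, 32])
  l_max <- 8
  vol <- density_to_intensity(model, kg, kamcorr:::sq_grid(l_max))
  scale <- 1e13 * 2e-10 / cartesian_intensity(model)$i_zero
  cc <- sh_analyze(vol, l_max); cc$coeffs <- cc$coeffs * scale
  err <- numeric(3)
  ns <- c(100, 400, 1600)
  for (j in seq_along(ns)) {
    stack <- generate_dataset(model, ns[j], g, seed = 40 + j)
    s <- finalize(accumulate(stack, kg, 36, method = "bicubic"))
    tgt <- target_correlation_curves(theoretical_correlation_matrices(cc),
                                     s$psi_grid)
    err[j] <- sqrt(mean((s$C - tgt$C)^2))
  }
  # quadrupling the pattern count should roughly halve the error
  expect_lt(err[2], err[1] * 0.75)
  expect_lt(err[3], err[2] * 0.75)
  expect_lt(err[3], err[1] * 0.45)
})

test_that("full and corner-masked patterns give consistent C curves", {
  model <- make_phantom("blobs", size = 32, voxel_size = 2.5, seed = 7)
  g <- small_geometry()
  kg <- seq(0.04, 0.12, length.out = 3)
  n <- 600
  full <- generate_dataset(model, n, g, seed = 55)
  masked <- full
  masked$mask <- corner_mask(64)
  sf <- finalize(accumulate(full, kg, 36, method = "bicubic"))
  sm <- finalize(accumulate(masked, kg, 36, method = "bicubic"))
  # Monte-Carlo scale of the curves: spread over psi of the full-data curve
  for (pair in list(c(1, 3), c(2, 2))) {
    cf <- sf$C[pair[1], pair[2], ]
    cm <- sm$C[pair[1], pair[2], ]
    mc_scale <- stats::sd(cf - mean(cf)) + 1e-300
    expect_lt(max(abs(cf - cm)) / mc_scale, 1.0)
  }
})
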