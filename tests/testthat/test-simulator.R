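test_that("random orientations are uniform on SO(3)", {
  set.seed(7)
  n <- 1e5
  q <- random_orientation(n)
  expect_equal(max(abs(rowSums(q^2) - 1)), 0, tolerance = 1e-12)
  # mean rotation matrix -> 0 (each entry has variance <= ~1/3 per draw)
  Rsum <- matrix(0, 3, 3)
  for (i in seq_len(2e4)) Rsum <- Rsum + quat_to_matrix(q[i, ])
  expect_lt(max(abs(Rsum / 2e4)), 3 * sqrt(1 / 3) / sqrt(2e4))
  # rotation-angle marginal: density (1 - cos w)/pi on [0, pi]
  w <- 2 * acos(pmin(1, abs(q[, 1])))
  br <- seq(0, pi, length.out = 13)
  obs <- table(cut(w, br))
  pr <- diff(br - sin(br)) / pi
  chi2 <- sum((as.numeric(obs) - n * pr)^2 / (n * pr))
  expect_lt(chi2, qchisq(0.999, df = 11))
  # determinism under a fixed seed
  set.seed(7); a <- random_orientation(5)
  set.seed(7); b <- random_orientation(5)
  expect_identical(a, b)
})

test_that("Ewald mapping reproduces the geometry relations", {
  g <- small_geometry()
  # beam center
  em0 <- ewald_map(g, 0, 0, flat = FALSE)
  expect_equal(em0$k, 0)
  expect_equal(em0$theta, pi / 2)
  # lambda = 1 nm <-> 1239.8 eV
  expect_equal(photon_energy_ev(1), 1239.8, tolerance = 1e-4)
  # k_edge = 0.2 1/nm at lambda = 1: sin(theta_s) = 0.1, so
  # 2 theta_s = 2 asin(0.1) = 11.478 deg and rho/L = tan(2 theta_s) = 0.2031
  rho <- ewald_rho(g, 0.2, flat = FALSE)
  expect_equal(atan(rho / g$distance) * 180 / pi, 2 * asin(0.1) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(rho / g$distance, tan(2 * asin(0.1)), tolerance = 1e-9)
  # flat and curved agree at small angles
  expect_equal(ewald_rho(g, 0.05, flat = TRUE),
               ewald_rho(g, 0.05, flat = FALSE), tolerance = 1e-3)
})

test_that("flat-Ewald patterns are Friedel-symmetric and linear in flux", {
  model <- make_phantom("blobs", size = 32, voxel_size = 2.5, seed = 7)
  cart <- cartesian_intensity(model)
  g <- detector_geometry(1, 100, 0.4, 48)   # even grid, center off-pixel
  set.seed(1)
  q <- random_orientation(1)[1, ]
  p <- simulate_pattern(cart, q, g, flux = 1e13)
  # point reflection through the (fractional) center maps pixel i -> n+1-i
  p_inv <- p[rev(seq_len(48)), rev(seq_len(48))]
  expect_equal(p, p_inv, tolerance = 1e-10)
  p2 <- simulate_pattern(cart, q, g, flux = 2e13)
  expect_equal(p2, 2 * p, tolerance = 1e-12)
})

test_that("noise generator obeys the moment contract", {
  set.seed(5)
  n <- 400
  src <- matrix(100, n, n)
  np <- noise_params(flux = 1e13, alpha = 3e-4, beta = 1e-4)
  out <- add_noise(src, np)
  delta <- out - src
  m <- length(delta)
  expect_lt(abs(mean(delta)), 3 * sqrt(100 / m))
  v_expect <- 100 + 100 * np$alpha + np$beta
  # var of sample variance of ~Poisson(100): approx (mu4 - var^2)/m
  se_var <- sqrt((3 * 100^2 + 100 - 100^2) / m)
  expect_lt(abs(mean(delta^2) - v_expect), 3 * se_var)
  # noise disabled: identity
  np0 <- noise_params(poisson_enabled = FALSE, detector_enabled = FALSE)
  expect_identical(add_noise(src, np0), src)
  # detector noise at alpha, beta ~ 1e-4 is << shot noise at I_s >= 1
  expect_lt(np$alpha * 1 + np$beta, 0.01 * 1)
})

test_that("phantoms are deterministic, non-negative, compactly supported", {
  a <- make_phantom("blobs", size = 32, voxel_size = 1, seed = 5)
  b <- make_phantom("blobs", size = 32, voxel_size = 1, seed = 5)
  expect_identical(a$grid, b$grid)
  expect_gte(min(a$grid), 0)
  ax <- seq_len(32) - 16.5
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  expect_equal(sum(a$grid[r2 > (32 / 4)^2]), 0)
  s <- make_phantom("sphere", size = 24, voxel_size = 1)
  inside <- s$grid[r2[1:24, 1:24, 1:24] < 1]
  expect_true(all(s$grid %in% c(0, 1)))
})

test_that("dataset generation stores reproducible truth", {
  model <- make_phantom("twolobe", size = 24, voxel_size = 2.5)
  g <- detector_geometry(1, 100, 0.6, 24)
  st1 <- generate_dataset(model, 3, g, seed = 13, keep_truth = TRUE)
  st2 <- generate_dataset(model, 3, g, seed = 13, keep_truth = TRUE)
  expect_identical(st1$patterns, st2$patterns)
  # noise-free: stored patterns equal re-sliced truth exactly
  cart <- cartesian_intensity(model)
  kmap <- kamcorr:::detector_kmap(g, TRUE)
  for (i in 1:3) {
    p <- simulate_pattern(cart, st1$truth$quaternions[i, ], g,
                          flux = st1$truth$flux,
                          flux_scale = st1$truth$flux_scale, kmap = kmap)
    expect_identical(p, st1$patterns[, , i])
  }
  # corner mask flags the second/fourth-quadrant corners invalid
  msk <- corner_mask(24)
  st3 <- generate_dataset(model, 2, g, mask = msk, seed = 13)
  expect_false(all(st3$mask))
  expect_false(st3$mask[1, 24])     # second-quadrant corner
  expect_false(st3$mask[24, 1])     # fourth-quadrant corner
  expect_true(st3$mask[12, 12])
})

test_that("MRC round trip preserves the density and voxel size", {
  m <- make_phantom("blobs", size = 16, voxel_size = 0.4, seed = 2)
  path <- tempfile(fileext = ".mrc")
  write_mrc(m, path)
  m2 <- read_mrc(path)
  expect_equal(m2$grid, m$grid, tolerance = 1e-6)
  expect_equal(m2$voxel_size, 0.4, tolerance = 1e-6)
  unlink(path)
})

test_that("backgrounds add per radius and at the configured fraction", {
  model <- make_phantom("blobs", size = 32, voxel_size = 2.5, seed = 7)
  g <- detector_geometry(1, 100, 0.4, 48)
  set.seed(2)
  p <- simulate_pattern(cartesian_intensity(model), random_orientation(1)[1, ], g)
  # constant profile b: every pixel increases by exactly b
  bg <- background_model(instrument_profile = function(k) rep(1.5, length(k)))
  ps <- add_background(p, bg, g)
  expect_equal(ps - p, matrix(1.5, 48, 48), tolerance = 1e-12)
  # 5%-of-coherent instrument profile adds ~5% of the coherent counts
  prof <- instrument_fraction_profile(model, g, fraction = 0.05)
  bg5 <- background_model(instrument_profile = prof)
  kmap <- kamcorr:::detector_kmap(g, TRUE)
  ok <- kmap$k <= 0.95 * max(kmap$k[, 24])
  set.seed(3)
  q <- random_orientation(40)
  tot_c <- tot_b <- 0
  cart <- cartesian_intensity(model)
  for (i in 1:40) {
    pc <- simulate_pattern(cart, q[i, ], g, kmap = kamcorr:::detector_kmap(g, TRUE))
    tot_c <- tot_c + sum(pc[ok])
    tot_b <- tot_b + sum((add_background(pc, bg5, g) - pc)[ok])
  }
  expect_equal(tot_b / tot_c, 0.05, tolerance = 0.3)
})
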