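test_that("SH analysis/synthesis round trip is exact for band-limited volumes", {
  l_max <- 6
  kg <- c(0.1, 0.2, 0.3)
  cc <- random_real_coeffs(l_max, kg, seed = 11)
  g <- sh_grid(l_max)
  vol <- sh_synthesize(cc, g)
  back <- sh_analyze(vol, l_max)
  expect_lt(max(abs(back$coeffs - cc$coeffs)), 1e-10)

  # constant volume: only the monopole survives, equal to a*sqrt(4 pi)
  a <- 2.5
  vc <- intensity_volume(array(a, c(1, g$n_theta, g$n_phi)), 0.1, g)
  ca <- sh_analyze(vc, l_max)
  expect_equal(Re(ca$coeffs[1, 1]), a * sqrt(4 * pi), tolerance = 1e-12)
  expect_lt(max(abs(ca$coeffs[-1, 1])), 1e-10)

  # linearity of synthesis
  cc2 <- random_real_coeffs(l_max, kg, seed = 12)
  vs <- sh_synthesize(sh_coefficients(cc$coeffs + cc2$coeffs, l_max, kg), g)
  expect_equal(vs$values, vol$values + sh_synthesize(cc2, g)$values,
               tolerance = 1e-12)

  # insufficient sampling is rejected
  expect_error(sh_analyze(vol, l_max + 4), "insufficient")
})

test_that("odd-degree coefficients vanish for Friedel-symmetric volumes", {
  l_max <- 8
  kg <- c(0.1, 0.2)
  cc <- random_real_coeffs(l_max, kg, seed = 3)
  g <- sh_grid(l_max, n_phi = 2 * l_max + 2)   # even azimuth count
  vol <- sh_synthesize(cc, g)
  # Friedel-symmetrize on the grid: average with the antipodal value
  sym <- vol
  nth <- g$n_theta; nph <- g$n_phi
  for (ik in 1:2) {
    v <- matrix(vol$values[ik, , ], nth, nph)
    anti <- v[rev(seq_len(nth)), (seq_len(nph) + nph / 2 - 1) %% nph + 1]
    sym$values[ik, , ] <- (v + anti) / 2
  }
  co <- sh_analyze(sym, l_max)$coeffs
  odd <- even <- 0
  for (l in 0:l_max) {
    nrm <- sum(abs(co[kamcorr:::lm_index(rep(l, 2 * l + 1), -l:l), ])^2)
    if (l %% 2 == 1) odd <- odd + nrm else even <- even + nrm
  }
  expect_lt(sqrt(odd), 1e-10 * sqrt(even))
})

test_that("normalized Legendre recurrence matches an independent implementation", {
  x <- seq(-0.95, 0.95, length.out = 7)
  P <- kamcorr:::legendre_normalized(5, x)
  for (l in c(2, 5)) {
    ref <- pracma::legendre(l, x)        # rows m = 0..l, Condon-Shortley
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m))
      expect_equal(P[[m + 1]][, l - m + 1], nrm * ref[m + 1, ],
                   tolerance = 1e-12)
    }
  }
})

test_that("density_to_intensity matches closed-form transforms", {
  g <- sh_grid(4)
  # impulse at the center: flat spectrum
  n <- 16
  imp <- array(0, c(n, n, n)); imp[8, 8, 8] <- 3
  kg <- c(0.05, 0.2, 0.4)
  vol <- density_to_intensity(density_volume(imp, 1), kg, g)
  expect_equal(max(vol$values), min(vol$values), tolerance = 1e-9)
  expect_equal(vol$values[1, 1, 1], 9, tolerance = 1e-9)

  # two points separated by d along z: intensity prop. to cos^2(pi kz d)
  two <- array(0, c(n, n, n)); d <- 4
  two[8, 8, 8 - d / 2] <- 1; two[8, 8, 8 + d / 2] <- 1
  kz <- c(0.125, 0.25)                    # cos^2(pi kz d): zero at kz = 1/(2d)
  vol2 <- density_to_intensity(density_volume(two, 1), kz, g, pad_factor = 4)
  pole <- which.min(g$theta)              # node closest to the +z pole
  ratio <- vol2$values[, pole, 1] / 4
  expect_lt(max(abs(ratio - cos(pi * kz * cos(g$theta[pole]) * d)^2)), 0.02)

  # uniform sphere: first radial zero near k = 0.715/R
  R <- 6
  sph <- make_phantom("sphere", size = 48, voxel_size = 1)
  # support radius of the phantom is size/4 = 12
  ks <- seq(0.02, 0.09, length.out = 40)
  vs <- density_to_intensity(sph, ks, sh_grid(2))
  prof <- apply(vs$values, 1, mean)
  k_zero <- ks[which.min(prof)]
  expect_equal(k_zero, 0.715 / 12, tolerance = 0.1)

  # beyond-Nyquist request is rejected with the limit named
  expect_error(density_to_intensity(sph, 0.6, sh_grid(2)), "Nyquist")
})

test_that("theoretical correlation matrices obey the Gram structure", {
  l_max <- 4
  kg <- c(0.1, 0.2, 0.3)
  cc <- random_real_coeffs(l_max, kg, seed = 21, even_only = TRUE)
  mats <- theoretical_correlation_matrices(cc)
  for (j in seq_along(mats$l_values)) {
    l <- mats$l_values[j]
    ev <- eigen(mats$C[[j]], symmetric = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(abs(ev)))
    expect_lte(sum(ev > 1e-10 * max(abs(ev))), min(2 * l + 1, length(kg)))
    ev_d <- eigen(mats$D[[j]], symmetric = TRUE)$values
    expect_gte(min(ev_d), -1e-10 * max(abs(ev_d)))
  }
  # constant volume: C_0 = a^2, all higher degrees zero
  a <- 1.7
  co <- matrix(0i, (l_max + 1)^2, 1)
  co[1, 1] <- a * sqrt(4 * pi)
  mc <- theoretical_correlation_matrices(sh_coefficients(co, l_max, 0.1))
  expect_equal(mc$C[["l0"]][1, 1], a^2, tolerance = 1e-12)
  expect_lt(max(sapply(mc$C[-1], function(M) max(abs(M)))), 1e-12)
})

test_that("orientation-average oracle confirms the correlation decomposition", {
  l_max <- 4
  kg <- c(0.1, 0.2, 0.3)
  cc <- random_real_coeffs(l_max, kg, seed = 2, even_only = TRUE)
  mats <- theoretical_correlation_matrices(cc)
  psi <- c(0.4, pi / 2, 2.2)
  tgt <- target_correlation_curves(mats, psi)
  set.seed(99)
  N <- 1e5
  q <- random_orientation(N)
  Rall <- array(0, c(3, 3, N))
  for (i in seq_len(N)) Rall[, , i] <- quat_to_matrix(q[i, ])
  u1 <- c(0, 0, 1)
  d1 <- t(apply(Rall, 3, function(R) R %*% u1))
  I1 <- sh_eval(cc, acos(pmin(1, pmax(-1, d1[, 3]))), atan2(d1[, 2], d1[, 1]))
  for (ip in seq_along(psi)) {
    u2 <- c(sin(psi[ip]), 0, cos(psi[ip]))
    d2 <- t(apply(Rall, 3, function(R) R %*% u2))
    I2 <- sh_eval(cc, acos(pmin(1, pmax(-1, d2[, 3]))), atan2(d2[, 2], d2[, 1]))
    for (pair in list(c(1, 3), c(2, 2))) {
      prod <- I1[, pair[1]] * I2[, pair[2]]
      se <- sd(prod) / sqrt(N)
      expect_lt(abs(mean(prod) - tgt$C[pair[1], pair[2], ip]), 3 * se)
    }
  }
})

test_that("target curves evaluate the Legendre series", {
  # single l = 2 matrix entry of 1: curve equals P_2(cos psi)
  kg <- 0.1
  mats <- structure(list(
    C = list(l0 = matrix(0, 1, 1), l2 = matrix(1, 1, 1)),
    T = list(l0 = matrix(0, 1, 1), l2 = matrix(0, 1, 1)),
    D = list(l0 = matrix(0, 1, 1), l2 = matrix(0, 1, 1)),
    l_values = c(0L, 2L), l_max = 2L, k_grid = kg),
    class = "correlation_matrices")
  tgt <- target_correlation_curves(mats, c(0, pi / 2, pi / 3))
  expect_equal(tgt$C[1, 1, ], c(1, -0.5, (3 * 0.25 - 1) / 2),
               tolerance = 1e-12)
})
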