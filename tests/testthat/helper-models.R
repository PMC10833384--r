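# Shared fixtures: all built in code, seeded.

# random band-limited SH coefficients of a real volume; even_only restricts
# to Friedel-symmetric (even-degree) content
random_real_coeffs <- function(l_max, k_grid, seed = 1, even_only = FALSE) {
  set.seed(seed)
  co <- matrix(0i, (l_max + 1)^2, length(k_grid))
  ls <- if (even_only) seq(0, l_max, by = 2) else 0:l_max
  for (l in ls) for (m in 0:l) {
    v <- complex(real = rnorm(length(k_grid)),
                 imaginary = if (m > 0) rnorm(length(k_grid)) else 0)
    co[kamcorr:::lm_index(l, m), ] <- v
    co[kamcorr:::lm_index(l, -m), ] <- (-1)^m * Conj(v)
  }
  sh_coefficients(co, l_max, k_grid)
}

# true unitary column blocks of a model, from its coefficients and a basis
true_unitary_blocks <- function(coeffs, problem) {
  out <- list()
  for (l in problem$active_l) {
    key <- paste0("l", l)
    s <- problem$basis_C$subspaces[[key]]
    rows <- kamcorr:::lm_index(rep(l, 2 * l + 1), -l:l)
    im <- problem$i_max_full[[key]]
    out[[key]] <- coeffs$coeffs[rows, , drop = FALSE] %*%
      s$u[, seq_len(im), drop = FALSE] %*% diag(1 / s$norms[seq_len(im)], im)
  }
  out
}

# standard small detector used across simulator tests
small_geometry <- function(n_pixels = 64) {
  detector_geometry(wavelength = 1.0, distance = 100, pixel_size = 0.5,
                    n_pixels = n_pixels)
}

# quadruple-loop reference accumulator: independent pairwise enumeration in
# canonical (pattern, phi1, phi2) order
brute_force_correlations <- function(vals, valid, n_psi) {
  nk <- dim(vals)[1]; nphi <- dim(vals)[2]; npat <- dim(vals)[3]
  C <- T_ <- D <- N <- array(0, c(nk, nk, n_psi))
  for (p in seq_len(npat)) for (f1 in seq_len(nphi)) for (f2 in seq_len(nphi)) {
    d <- (f2 - f1) %% nphi
    j <- min(d, nphi - d) + 1
    for (i1 in seq_len(nk)) for (i2 in seq_len(nk)) {
      if (!valid[i1, f1, p] || !valid[i2, f2, p]) next
      a <- vals[i1, f1, p]; b <- vals[i2, f2, p]
      C[i1, i2, j] <- C[i1, i2, j] + a * b
      T_[i1, i2, j] <- T_[i1, i2, j] + a * a * b
      D[i1, i2, j] <- D[i1, i2, j] + (a * a) * (b * b)
      N[i1, i2, j] <- N[i1, i2, j] + 1
    }
  }
  list(C = C, T = T_, D = D, counts = N)
}

# Monte-Carlo oracle for the noise-correction formulas: a fixed tiny polar
# pattern, many independent noise realizations, bias measured in
# batch-mean standard errors.
mc_noise_experiment <- function(Is, alpha, beta, n_total = 2e5, nbatch = 10,
                                seed = 77, poisson = TRUE, detector = TRUE) {
  nk <- nrow(Is); nphi <- ncol(Is)
  ref <- finalize(accumulate_polar(NULL, array(Is, c(nk, nphi, 1)),
                                   k_grid = seq_len(nk)))
  pick <- function(s) c(T11 = s$T[1, 1, 3], D11 = s$D[1, 1, 3],
                        T12 = s$T[1, 2, 4], D12 = s$D[1, 2, 4],
                        T21 = s$T[2, 1, 4], D22 = s$D[2, 2, 2])
  set.seed(seed)
  batch <- n_total / nbatch
  corr_b <- uncorr_b <- matrix(0, nbatch, 6)
  for (b in seq_len(nbatch)) {
    vals <- if (poisson)
      array(rpois(nk * nphi * batch, rep(Is, batch)), c(nk, nphi, batch))
    else array(rep(Is, batch), c(nk, nphi, batch))
    if (detector)
      vals <- vals + array(rnorm(nk * nphi * batch, 0,
                                 rep(sqrt(alpha * Is + beta), batch)),
                           c(nk, nphi, batch))
    s <- finalize(accumulate_polar(NULL, vals, k_grid = seq_len(nk)))
    sc <- eliminate_noise(s, alpha, beta)
    corr_b[b, ] <- pick(sc) - pick(ref)
    uncorr_b[b, ] <- pick(s) - pick(ref)
  }
  z <- function(m) colMeans(m) / (apply(m, 2, sd) / sqrt(nbatch))
  list(z_corr = z(corr_b), z_uncorr = z(uncorr_b), ref = pick(ref))
}
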