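# ---------------------------------------------------------------------------
# Phase retrieval (HIO/ER with shrinkwrap), Fourier shell correlation, and
# correlation NRMSE maps.
# ---------------------------------------------------------------------------

#' Embed a spherical intensity volume into a Cartesian Fourier grid
#'
#' Evaluates the spherical-harmonic series at every Cartesian reciprocal
#' voxel inside the radial range (linear interpolation across shells,
#' Friedel-symmetric by construction of the even-degree series), clipping
#' negative interpolation residue at zero. Voxels beyond `max(k_grid)` are
#' unmeasured (NA): phase retrieval leaves them unconstrained.
#'
#' @param coeffs an [sh_coefficients()] object.
#' @param grid_size Cartesian edge length in voxels.
#' @param k_step reciprocal voxel size in 1/nm (default: shell spacing).
#' @return list: `intensity` (array, NA outside the measured ball),
#'   `k_step`, `voxel_size` (real-space voxel of the conjugate grid, nm).
#' @export
embed_intensity <- function(coeffs, grid_size,
                            k_step = diff(coeffs$k_grid[1:2])) {
  n <- as.integer(grid_size)
  ctr <- n %/% 2 + 1L
  ax <- (seq_len(n) - ctr) * k_step
  kx <- array(ax, c(n, n, n))
  ky <- aperm(kx, c(2, 1, 3)); kz <- aperm(kx, c(3, 2, 1))
  kr <- sqrt(kx^2 + ky^2 + kz^2)
  kmax <- max(coeffs$k_grid)
  inside <- which(kr <= kmax)
  th <- acos(pmin(1, pmax(-1, ifelse(kr[inside] > 0, kz[inside] / kr[inside], 1))))
  ph <- atan2(ky[inside], kx[inside])
  vals_shell <- sh_eval(coeffs, th, ph)        # n_inside x n_shells
  # linear radial interpolation (constant extrapolation at the ends)
  kg <- coeffs$k_grid
  pos <- findInterval(kr[inside], kg, all.inside = TRUE)
  t <- (kr[inside] - kg[pos]) / (kg[pos + 1L] - kg[pos])
  t <- pmin(1, pmax(0, t))
  idx <- seq_along(inside)
  v <- (1 - t) * vals_shell[cbind(idx, pos)] + t * vals_shell[cbind(idx, pos + 1L)]
  out <- array(NA_real_, c(n, n, n))
  out[inside] <- pmax(v, 0)
  list(intensity = out, k_step = k_step, voxel_size = 1 / (n * k_step))
}

#' @keywords internal
fftshift3 <- function(a) {
  n <- dim(a)[1]; ctr <- n %/% 2 + 1L
  idx <- c(ctr:n, seq_len(ctr - 1L))
  a[idx, idx, idx]
}

#' @keywords internal
ifftshift3 <- function(a) {
  n <- dim(a)[1]; ctr <- n %/% 2 + 1L
  idx <- c((n - ctr + 2L):n, seq_len(n - ctr + 1L))
  a[idx, idx, idx]
}

#' @keywords internal
gaussian_smooth3 <- function(a, sigma) {
  n <- dim(a)[1]
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1L):1)) / n
  g1 <- exp(-2 * pi^2 * sigma^2 * f^2)
  G <- array(g1, c(n, n, n)) * aperm(array(g1, c(n, n, n)), c(2, 1, 3)) *
    aperm(array(g1, c(n, n, n)), c(3, 2, 1))
  Re(stats::fft(stats::fft(a) * G, inverse = TRUE)) / n^3
}

#' Iterative phase retrieval with support shrinkwrap
#'
#' Recovers a real, non-negative, compact density from Fourier magnitudes
#' by hybrid input-output (beta = 0.9) alternated with error-reduction,
#' updating the support every `shrink_every` iterations by thresholding a
#' Gaussian-smoothed copy of the current object (sigma annealed from 3 to
#' 1.5 voxels). Unmeasured Fourier voxels stay unconstrained. Runs
#' `n_runs` seeded random starts and returns the run with the lowest
#' Fourier residual.
#'
#' @param intensity Cartesian intensity array (NA = unmeasured), centered.
#' @param voxel_size real-space voxel of the output grid in nm.
#' @param n_iterations total iterations per run.
#' @param n_runs random restarts.
#' @param seed integer seed.
#' @param beta HIO feedback parameter.
#' @param shrink_every shrinkwrap cadence in iterations.
#' @param support_frac shrinkwrap threshold as a fraction of the smoothed max.
#' @return list: `density` (a [density_volume()]), `residual` (best
#'   Fourier-space relative residual), `residuals` (per run), `support`.
#' @export
phase_retrieve <- function(intensity, voxel_size, n_iterations = 400L,
                           n_runs = 4L, seed = 1L, beta = 0.9,
                           shrink_every = 30L, support_frac = 0.05) {
  n <- dim(intensity)[1]
  measured <- !is.na(intensity)
  mag_c <- sqrt(pmax(ifftshift3(ifelse(measured, intensity, 0)), 0))
  meas_c <- ifftshift3(measured)
  mag_norm <- sqrt(sum(mag_c[meas_c]^2))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  best <- list(residual = Inf)
  residuals <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    # random-phase start consistent with the measured magnitudes
    phase <- array(stats::runif(n^3, 0, 2 * pi), c(n, n, n))
    G <- mag_c * exp(1i * phase)
    g <- Re(stats::fft(G, inverse = TRUE)) / n^3
    support <- array(TRUE, c(n, n, n))
    for (it in seq_len(n_iterations)) {
      G <- stats::fft(g)
      Gc <- G
      nz <- meas_c & (Mod(G) > 0)
      Gc[nz] <- mag_c[nz] * G[nz] / Mod(G)[nz]
      Gc[meas_c & !nz] <- mag_c[meas_c & !nz]
      gp <- Re(stats::fft(Gc, inverse = TRUE)) / n^3
      er_phase <- it > n_iterations * 0.8 || (it %% 10L) == 0L
      ok <- support & (gp >= 0)
      if (er_phase) {
        gn <- array(0, c(n, n, n)); gn[ok] <- gp[ok]
      } else {
        gn <- g - beta * gp
        gn[ok] <- gp[ok]
      }
      g <- gn
      if (it %% shrink_every == 0L && it < n_iterations * 0.9) {
        sigma <- max(1.5, 3 * (1 - it / n_iterations))
        sm <- gaussian_smooth3(pmax(g, 0), sigma)
        support <- sm >= support_frac * max(sm)
      }
    }
    G <- stats::fft(g)
    res <- sqrt(sum((Mod(G)[meas_c] - mag_c[meas_c])^2)) / mag_norm
    residuals[r] <- res
    if (res < best$residual)
      best <- list(residual = res, g = g, support = support)
  }
  dens <- fftshift3(pmax(best$g, 0))
  list(density = density_volume(dens, voxel_size),
       residual = best$residual, residuals = residuals,
       support = fftshift3(best$support))
}

#' Fourier shell correlation between two density volumes
#'
#' Per-shell normalized cross-correlation of the Fourier transforms; the
#' half-period resolution is `1/(2 k_c)` with `k_c` the first crossing of
#' the threshold (linear interpolation between shells).
#'
#' @param a,b [density_volume()]s on identical grids.
#' @param threshold FSC threshold for the resolution readout.
#' @return an `fsc_curve` list: `k_grid` (1/nm), `fsc`, `threshold`,
#'   `k_c`, `resolution` (nm, NA when the curve never crosses).
#' @export
fsc <- function(a, b, threshold = 0.5) {
  if (!all(dim(a$grid) == dim(b$grid)) ||
      abs(a$voxel_size - b$voxel_size) > 1e-9)
    stop("volumes must share grid size and voxel size")
  n <- dim(a$grid)[1]
  FA <- stats::fft(a$grid); FB <- stats::fft(b$grid)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1L):1))
  fr <- sqrt(array(f, c(n, n, n))^2 + aperm(array(f, c(n, n, n)), c(2, 1, 3))^2 +
               aperm(array(f, c(n, n, n)), c(3, 2, 1))^2)
  shell <- pmin(round(fr), n %/% 2) + 1L
  num <- Re(FA * Conj(FB)); pa <- Mod(FA)^2; pb <- Mod(FB)^2
  sn <- tapply(num, shell, sum); sa <- tapply(pa, shell, sum)
  sb <- tapply(pb, shell, sum)
  ns <- n %/% 2 + 1L
  curve <- as.numeric(sn[seq_len(ns)] / sqrt(sa[seq_len(ns)] * sb[seq_len(ns)]))
  k_grid <- (seq_len(ns) - 1L) / (n * a$voxel_size)
  k_c <- NA_real_
  below <- which(curve < threshold)
  below <- below[below > 1L]
  if (length(below)) {
    j <- below[1]
    f1 <- curve[j - 1L]; f2 <- curve[j]
    t <- (threshold - f1) / (f2 - f1)
    k_c <- k_grid[j - 1L] + t * (k_grid[j] - k_grid[j - 1L])
  }
  structure(list(k_grid = k_grid, fsc = curve, threshold = threshold,
                 k_c = k_c,
                 resolution = if (is.na(k_c)) NA_real_ else 1 / (2 * k_c)),
            class = "fsc_curve")
}

#' Align one density to another (translation and inversion flip)
#'
#' Maximizes the real-space cross-correlation over cyclic translations
#' (computed in Fourier space, refined to subvoxel precision by parabolic
#' peak interpolation and applied as a Fourier phase ramp) of the volume
#' and of its point inversion, and returns the aligned copy. Used before
#' FSC readouts, since phasing determines the density only up to
#' translation and inversion.
#'
#' @param moving,reference [density_volume()]s on identical grids.
#' @return the aligned `moving` volume.
#' @export
align_density <- function(moving, reference) {
  n <- dim(moving$grid)[1]
  FR <- stats::fft(reference$grid)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1L):1)) / n
  best <- NULL; best_s <- -Inf
  for (flip in c(FALSE, TRUE)) {
    g <- moving$grid
    if (flip) {
      rev_idx <- c(1L, n:2L)   # point inversion about the DC voxel
      g <- g[rev_idx, rev_idx, rev_idx]
    }
    FM <- stats::fft(g)
    cc <- Re(stats::fft(FR * Conj(FM), inverse = TRUE))
    w <- which.max(cc)
    sub <- arrayInd(w, dim(cc)) - 1L
    # parabolic subvoxel refinement along each axis
    delta <- numeric(3)
    for (d in 1:3) {
      idx <- sub + 1L
      im <- idx; ip <- idx
      im[d] <- (sub[d] - 1L) %% n + 1L
      ip[d] <- (sub[d] + 1L) %% n + 1L
      y0 <- cc[matrix(im, 1)]; y1 <- cc[matrix(idx, 1)]; y2 <- cc[matrix(ip, 1)]
      den <- y0 - 2 * y1 + y2
      if (abs(den) > 1e-300) delta[d] <- 0.5 * (y0 - y2) / den
    }
    shift <- sub + pmin(pmax(delta, -0.5), 0.5)
    ramp <- exp(-2i * pi * (array(f * shift[1], c(n, n, n)) +
                             aperm(array(f * shift[2], c(n, n, n)), c(2, 1, 3)) +
                             aperm(array(f * shift[3], c(n, n, n)), c(3, 2, 1))))
    gs <- Re(stats::fft(FM * ramp, inverse = TRUE)) / n^3
    s <- sum(gs * reference$grid)
    if (s > best_s) { best <- gs; best_s <- s }
  }
  density_volume(best, moving$voxel_size)
}

#' NRMSE map between two correlation sets
#'
#' For each shell pair, the RMS difference over defined psi bins divided by
#' the RMS magnitude of the target curve. All-zero target curves give NA.
#'
#' @param corrected,target finalized `correlation_set`s on matching grids.
#' @return list of `n_k x n_k` matrices `C`, `T`, `D`.
#' @export
nrmse_map <- function(corrected, target) {
  if (length(corrected$psi_grid) != length(target$psi_grid) ||
      max(abs(corrected$psi_grid - target$psi_grid)) > 1e-9)
    stop("psi grids differ")
  nk <- length(corrected$k_grid)
  out <- list()
  for (f in c("C", "T", "D")) {
    M <- matrix(NA_real_, nk, nk)
    for (i1 in seq_len(nk)) for (i2 in seq_len(nk)) {
      y <- corrected[[f]][i1, i2, ]; t0 <- target[[f]][i1, i2, ]
      ok <- !is.na(y) & !is.na(t0)
      if (!any(ok)) next
      denom <- sqrt(mean(t0[ok]^2))
      if (denom == 0) next
      M[i1, i2] <- sqrt(mean((y[ok] - t0[ok])^2)) / denom
    }
    out[[f]] <- M
  }
  out
}
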