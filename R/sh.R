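# ---------------------------------------------------------------------------
# Spherical-harmonic machinery.
#
# Convention: orthonormal complex spherical harmonics with Condon-Shortley
# phase,
#   Y_lm(theta, phi) = Pbar_l^m(cos theta) * exp(i m phi),
# where Pbar includes the full normalization sqrt((2l+1)/(4pi) (l-m)!/(l+m)!)
# and the (-1)^m phase, so that  integral |Y_lm|^2 dOmega = 1 and
#   Y_{l,-m} = (-1)^m conj(Y_{l,m}).
#
# Coefficient storage: complex matrix of dim ((l_max+1)^2, n_k); the row for
# (l, m) is lm_index(l, m) = l^2 + l + m + 1.
# ---------------------------------------------------------------------------

lm_index <- function(l, m) l * l + l + m + 1L

#' Normalized associated Legendre functions
#'
#' Computes the fully normalized associated Legendre functions
#' \eqn{\bar P_l^m(x)} (Condon-Shortley phase included) for all degrees
#' \eqn{m \le l \le l_{max}} at the given abscissae, using the standard
#' stable three-term recurrence.
#'
#' @param l_max maximum degree.
#' @param x numeric vector of abscissae in \[-1, 1\] (cosine of polar angle).
#' @return a list indexed by `m + 1` (m = 0..l_max); element m holds a
#'   matrix of dim `(length(x), l_max - m + 1)` with columns l = m..l_max.
#' @keywords internal
legendre_normalized <- function(l_max, x) {
  stopifnot(l_max >= 0, all(abs(x) <= 1 + 1e-12))
  x <- pmin(1, pmax(-1, x))
  sint <- sqrt(pmax(0, 1 - x * x))
  out <- vector("list", l_max + 1L)
  pmm <- rep(sqrt(1 / (4 * pi)), length(x))  # Pbar_0^0
  for (m in 0:l_max) {
    nl <- l_max - m + 1L
    P <- matrix(0, length(x), nl)
    P[, 1L] <- pmm
    if (nl >= 2L) {
      P[, 2L] <- x * sqrt(2 * m + 3) * pmm
      if (nl >= 3L) {
        for (l in (m + 2L):l_max) {
          a <- sqrt((4 * l * l - 1) / (l * l - m * m))
          b <- sqrt((((l - 1)^2 - m * m)) / (4 * (l - 1)^2 - 1))
          P[, l - m + 1L] <- a * (x * P[, l - m] - b * P[, l - m - 1L])
        }
      }
    }
    out[[m + 1L]] <- P
    if (m < l_max) {
      # Pbar_{m+1}^{m+1} from Pbar_m^m; minus sign = Condon-Shortley phase
      pmm <- -sqrt((2 * m + 3) / (2 * m + 2)) * sint * pmm
    }
  }
  out
}

#' Angular quadrature grid for spherical-harmonic transforms
#'
#' Gauss-Legendre nodes in the polar direction, uniform nodes in azimuth.
#' Exact analysis/synthesis for volumes band-limited at `l_max` requires
#' `n_theta >= l_max + 1` and `n_phi >= 2 l_max + 1`.
#'
#' @param l_max band limit the grid must support.
#' @param n_theta,n_phi optional overrides of the node counts.
#' @return an `sh_grid` list: `theta`, `phi`, `x` (= cos theta), `w_theta`
#'   (Gauss-Legendre weights), `n_theta`, `n_phi`, `l_max`.
#' @export
sh_grid <- function(l_max, n_theta = NULL, n_phi = NULL) {
  if (is.null(n_theta)) n_theta <- l_max + 1L
  if (is.null(n_phi)) n_phi <- 2L * l_max + 1L
  if (n_theta < l_max + 1L)
    stop("insufficient polar sampling: need n_theta >= l_max + 1 (= ",
         l_max + 1L, "), got ", n_theta)
  if (n_phi < 2L * l_max + 1L)
    stop("insufficient azimuthal sampling: need n_phi >= 2*l_max + 1 (= ",
         2L * l_max + 1L, "), got ", n_phi)
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  structure(list(
    x = gl$x, w_theta = gl$w, theta = acos(gl$x),
    phi = 2 * pi * (seq_len(n_phi) - 1L) / n_phi,
    n_theta = as.integer(n_theta), n_phi = as.integer(n_phi),
    l_max = as.integer(l_max)
  ), class = "sh_grid")
}

#' Spherical-harmonic coefficient container
#'
#' @param coeffs complex matrix `((l_max+1)^2, n_k)`; row `l^2+l+m+1` holds
#'   the coefficient of degree `l`, order `m` on each radial shell.
#' @param l_max band limit.
#' @param k_grid radial spatial frequencies in 1/nm.
#' @return an `sh_coefficients` object.
#' @export
sh_coefficients <- function(coeffs, l_max, k_grid) {
  stopifnot(nrow(coeffs) == (l_max + 1L)^2, ncol(coeffs) == length(k_grid))
  structure(list(coeffs = coeffs, l_max = as.integer(l_max),
                 k_grid = as.numeric(k_grid)),
            class = "sh_coefficients")
}

#' Intensity volume on a spherical grid
#'
#' Real values over (radial shell, polar node, azimuth node).
#'
#' @param values numeric array `(n_k, n_theta, n_phi)`.
#' @param k_grid radial spatial frequencies in 1/nm.
#' @param grid the `sh_grid` the angular axes live on.
#' @export
intensity_volume <- function(values, k_grid, grid) {
  stopifnot(length(dim(values)) == 3L,
            dim(values)[1] == length(k_grid),
            dim(values)[2] == grid$n_theta,
            dim(values)[3] == grid$n_phi)
  structure(list(values = values, k_grid = as.numeric(k_grid), grid = grid),
            class = "intensity_volume")
}

#' Spherical-harmonic analysis of an intensity volume
#'
#' Projects each radial shell onto the orthonormal spherical harmonics using
#' Gauss-Legendre quadrature in the polar direction and an FFT in azimuth.
#' Exact (to round-off) for volumes band-limited at `l_max`.
#'
#' @param volume an [intensity_volume()].
#' @param l_max analysis band limit (must be supported by the grid).
#' @return an [sh_coefficients()] object.
#' @export
sh_analyze <- function(volume, l_max) {
  grid <- volume$grid
  if (grid$n_theta < l_max + 1L || grid$n_phi < 2L * l_max + 1L)
    stop("angular sampling insufficient for l_max = ", l_max,
         ": need n_theta >= ", l_max + 1L, " and n_phi >= ", 2L * l_max + 1L)
  nk <- length(volume$k_grid)
  nth <- grid$n_theta; nph <- grid$n_phi
  P <- legendre_normalized(l_max, grid$x)
  co <- matrix(0i, (l_max + 1L)^2, nk)
  dphi <- 2 * pi / nph
  for (ik in seq_len(nk)) {
    f <- volume$values[ik, , , drop = TRUE]          # n_theta x n_phi
    if (is.null(dim(f))) f <- matrix(f, nth, nph)
    # G[t, m+1] = sum_phi f * exp(-i m phi) * dphi, m = 0..n_phi-1 (wrapped)
    G <- t(stats::mvfft(t(f))) * dphi
    for (m in 0:l_max) {
      gp <- G[, m + 1L]                              # e^{-i m phi} component
      gm <- if (m == 0) gp else G[, nph - m + 1L]    # e^{+i m phi} component
      Pm <- P[[m + 1L]]                              # n_theta x (l_max-m+1)
      wgp <- grid$w_theta * gp
      wgm <- grid$w_theta * gm
      for (l in m:l_max) {
        pl <- Pm[, l - m + 1L]
        co[lm_index(l, m), ik] <- sum(pl * wgp)
        if (m > 0)
          co[lm_index(l, -m), ik] <- (-1)^m * sum(pl * wgm)
      }
    }
  }
  sh_coefficients(co, l_max, volume$k_grid)
}

#' Spherical-harmonic synthesis
#'
#' Evaluates the spherical-harmonic series on an angular quadrature grid.
#' Linear in the coefficients; the output is real whenever the coefficients
#' satisfy the conjugate symmetry of a real volume (the imaginary residue is
#' dropped after a tolerance check).
#'
#' @param coeffs an [sh_coefficients()] object.
#' @param grid an [sh_grid()]; azimuthal node count must exceed `2*l_max`.
#' @param check_real if TRUE, warn when the imaginary residue is large.
#' @return an [intensity_volume()].
#' @export
sh_synthesize <- function(coeffs, grid, check_real = FALSE) {
  l_max <- coeffs$l_max
  if (grid$n_phi < 2L * l_max + 1L)
    stop("grid azimuthal sampling cannot represent l_max = ", l_max)
  nk <- length(coeffs$k_grid)
  nth <- grid$n_theta; nph <- grid$n_phi
  P <- legendre_normalized(l_max, grid$x)
  vals <- array(0, c(nk, nth, nph))
  max_im <- 0
  for (ik in seq_len(nk)) {
    G <- matrix(0i, nth, nph)                        # azimuthal modes
    for (m in 0:l_max) {
      Pm <- P[[m + 1L]]
      ls <- m:l_max
      cp <- coeffs$coeffs[lm_index(ls, rep(m, length(ls))), ik]
      gp <- Pm %*% cp
      G[, m + 1L] <- G[, m + 1L] + gp
      if (m > 0) {
        cm <- coeffs$coeffs[lm_index(ls, rep(-m, length(ls))), ik]
        gm <- (-1)^m * (Pm %*% cm)
        G[, nph - m + 1L] <- G[, nph - m + 1L] + gm
      }
    }
    f <- t(stats::mvfft(t(G), inverse = TRUE))       # sum_m G e^{+im phi}
    mi <- max(abs(Im(f)))
    if (mi > max_im) max_im <- mi
    vals[ik, , ] <- Re(f)
  }
  if (check_real) {
    scale <- max(abs(vals), 1e-300)
    if (max_im / scale > 1e-8)
      warning("synthesized volume has relative imaginary residue ",
              format(max_im / scale, digits = 3))
  }
  intensity_volume(vals, coeffs$k_grid, grid)
}

#' Evaluate a spherical-harmonic series at arbitrary directions
#'
#' @param coeffs an [sh_coefficients()] object.
#' @param theta,phi numeric vectors of equal length (polar/azimuth angles).
#' @return real matrix `(length(theta), n_k)` of synthesized values.
#' @export
sh_eval <- function(coeffs, theta, phi) {
  stopifnot(length(theta) == length(phi))
  l_max <- coeffs$l_max
  np <- length(theta)
  P <- legendre_normalized(l_max, cos(theta))
  acc <- matrix(0i, np, length(coeffs$k_grid))
  for (m in 0:l_max) {
    Pm <- P[[m + 1L]]
    ls <- m:l_max
    cp <- coeffs$coeffs[lm_index(ls, rep(m, length(ls))), , drop = FALSE]
    acc <- acc + (Pm * exp(1i * m * phi)) %*% cp
    if (m > 0) {
      cm <- coeffs$coeffs[lm_index(ls, rep(-m, length(ls))), , drop = FALSE]
      acc <- acc + ((-1)^m * Pm * exp(-1i * m * phi)) %*% cm
    }
  }
  Re(acc)
}

#' Enforce the conjugate symmetry of a real volume on raw coefficients
#' @keywords internal
sh_symmetrize_real <- function(co, l_max) {
  for (l in 0:l_max) for (m in 0:l) {
    a <- co[lm_index(l, m), , drop = FALSE]
    b <- co[lm_index(l, -m), , drop = FALSE]
    avg <- (a + (-1)^m * Conj(b)) / 2
    co[lm_index(l, m), ] <- avg
    co[lm_index(l, -m), ] <- (-1)^m * Conj(avg)
  }
  co
}

#' Squared-volume spherical-harmonic coefficients
#'
#' Squares the synthesized volume on a quadrature grid and re-analyzes it at
#' the requested band limit. The true band limit of the squared volume is
#' `2*l_max`; truncation at `l_max_out` mirrors the use of quadruple
#' correlations only up to the fitted band limit. The quadrature grid must be
#' large enough that the truncated analysis is exact (polar nodes >=
#' (3*l_max)/2 + 1), which [sq_grid()] guarantees.
#'
#' @param coeffs an [sh_coefficients()] for the intensity volume.
#' @param l_max_out band limit of the squared-volume analysis
#'   (default: same as input).
#' @param grid optional quadrature grid override.
#' @return an [sh_coefficients()] for the squared volume.
#' @export
sh_square <- function(coeffs, l_max_out = coeffs$l_max, grid = NULL) {
  if (is.null(grid)) grid <- sq_grid(coeffs$l_max)
  vol <- sh_synthesize(coeffs, grid)
  vol$values <- vol$values^2
  sh_analyze(vol, l_max_out)
}

#' Quadrature grid sized for exact analysis of a squared band-limited volume
#' @keywords internal
sq_grid <- function(l_max) {
  # squared volume has degree 2*l_max; projecting it onto Y_l (l <= l_max)
  # makes the polar integrand a polynomial of degree <= 3*l_max in cos(theta)
  sh_grid(l_max,
          n_theta = max(l_max + 1L, ceiling((3 * l_max + 1) / 2) + 1L),
          n_phi = 3L * l_max + 2L)
}
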