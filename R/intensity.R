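# ---------------------------------------------------------------------------
# Density -> diffraction intensity: |FT(density)|^2 on a Cartesian grid and
# its resampling onto spherical (k, theta, phi) shells.
# ---------------------------------------------------------------------------

#' Cartesian diffraction-intensity grid of a density model
#'
#' Computes `|FT(density)|^2` on a zero-padded Cartesian reciprocal grid.
#' The grid is centered (`fftshift`ed) so that k = 0 sits at index
#' `floor(P/2) + 1`, with frequency step `1/(P * voxel_size)` cycles/nm.
#'
#' @param model a [density_volume()].
#' @param pad_factor zero-padding factor (>= 1); finer reciprocal sampling.
#' @return a `cart_intensity` list: `values` (P^3 array), `k_step` (1/nm),
#'   `center` (1-based index of k = 0), `k_max_cart` (edge of the reliable
#'   trilinear-interpolation range), `i_zero` (forward-scattering intensity).
#' @export
cartesian_intensity <- function(model, pad_factor = 2) {
  n <- dim(model$grid)[1]
  P <- as.integer(round(n * pad_factor))
  pad <- array(0, c(P, P, P))
  pad[seq_len(n), seq_len(n), seq_len(n)] <- model$grid
  F3 <- stats::fft(pad)
  I3 <- Re(F3 * Conj(F3))
  ctr <- P %/% 2 + 1L
  shift_idx <- c(ctr:P, seq_len(ctr - 1L))      # fftshift permutation
  I3 <- I3[shift_idx, shift_idx, shift_idx]
  structure(list(values = I3,
                 k_step = 1 / (P * model$voxel_size),
                 center = ctr,
                 n = P,
                 k_max_cart = (P %/% 2 - 1) / (P * model$voxel_size),
                 i_zero = sum(model$grid)^2,
                 voxel_size = model$voxel_size),
            class = "cart_intensity")
}

#' Trilinear interpolation of a Cartesian intensity grid
#'
#' @param ci a `cart_intensity`.
#' @param q 3-column matrix of reciprocal-space points (cycles/nm).
#' @return numeric vector of interpolated intensities.
#' @keywords internal
interp_cart <- function(ci, q) {
  g <- q / ci$k_step + ci$center               # fractional grid coordinates
  P <- ci$n
  i0 <- pmin(pmax(floor(g), 1), P - 1)
  fr <- g - i0
  v <- ci$values
  idx <- function(dx, dy, dz)
    v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  (1 - fx) * (1 - fy) * (1 - fz) * idx(0, 0, 0) +
    fx * (1 - fy) * (1 - fz) * idx(1, 0, 0) +
    (1 - fx) * fy * (1 - fz) * idx(0, 1, 0) +
    (1 - fx) * (1 - fy) * fz * idx(0, 0, 1) +
    fx * fy * (1 - fz) * idx(1, 1, 0) +
    fx * (1 - fy) * fz * idx(1, 0, 1) +
    (1 - fx) * fy * fz * idx(0, 1, 1) +
    fx * fy * fz * idx(1, 1, 1)
}

#' Resample a density model's diffraction intensity onto spherical shells
#'
#' Standard forward model of coherent diffraction: the intensity is the
#' squared magnitude of the Fourier transform of the (zero-padded) density,
#' interpolated onto a spherical `(k, theta, phi)` grid.
#'
#' @param model a [density_volume()].
#' @param k_grid radial shells in cycles/nm; must stay below the Nyquist
#'   limit `1/(2*voxel_size)`.
#' @param grid an [sh_grid()] giving the angular nodes.
#' @param pad_factor zero-padding factor for the Fourier transform.
#' @param cart optional precomputed [cartesian_intensity()].
#' @return an [intensity_volume()].
#' @export
density_to_intensity <- function(model, k_grid, grid, pad_factor = 2,
                                 cart = NULL) {
  nyq <- 1 / (2 * model$voxel_size)
  if (any(k_grid > nyq + 1e-12))
    stop("k_grid exceeds the Nyquist limit 1/(2*voxel_size) = ",
         format(nyq, digits = 6), " 1/nm")
  if (is.null(cart)) cart <- cartesian_intensity(model, pad_factor)
  nth <- grid$n_theta; nph <- grid$n_phi
  st <- sin(grid$theta); ct <- cos(grid$theta)
  cp <- cos(grid$phi); sp <- sin(grid$phi)
  ux <- outer(st, cp); uy <- outer(st, sp); uz <- outer(ct, rep(1, nph))
  dirs <- cbind(as.vector(ux), as.vector(uy), as.vector(uz))
  vals <- array(0, c(length(k_grid), nth, nph))
  for (ik in seq_along(k_grid)) {
    vals[ik, , ] <- interp_cart(cart, dirs * k_grid[ik])
  }
  intensity_volume(vals, k_grid, grid)
}
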