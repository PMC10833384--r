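# ---------------------------------------------------------------------------
# Synthetic single-particle diffraction data: detector geometry, uniform
# orientations, flat/curved Ewald slicing, backgrounds, shot and detector
# noise, masks, and the dataset generator.
# ---------------------------------------------------------------------------

#' Detector geometry
#'
#' @param wavelength incident wavelength in nm.
#' @param distance sample-to-detector distance in mm.
#' @param pixel_size pixel edge in mm.
#' @param n_pixels pixels per detector edge.
#' @param beam_center beam center in pixel coordinates (1-based; default the
#'   geometric center).
#' @return a `detector_geometry` object.
#' @export
detector_geometry <- function(wavelength, distance, pixel_size, n_pixels,
                              beam_center = rep((n_pixels + 1) / 2, 2)) {
  stopifnot(wavelength > 0, distance > 0, pixel_size > 0, n_pixels >= 2)
  structure(list(wavelength = wavelength, distance = distance,
                 pixel_size = pixel_size, n_pixels = as.integer(n_pixels),
                 beam_center = as.numeric(beam_center)),
            class = "detector_geometry")
}

#' Photon energy of a wavelength
#'
#' @param wavelength_nm wavelength in nm.
#' @return photon energy in eV (h*c / lambda; h*c = 1239.841984 eV nm).
#' @export
photon_energy_ev <- function(wavelength_nm) 1239.841984 / wavelength_nm

#' Map a detector pixel to reciprocal space
#'
#' A pixel at radius `rho` from the beam center scatters through
#' `2*theta_s = atan(rho / L)` and samples the Ewald sphere at
#' `k = (2/lambda) sin(theta_s)` (cycles/nm) with polar angle
#' `theta = pi/2 - theta_s`; the flat-Ewald limit uses `k = rho/(lambda*L)`
#' and forces `theta = pi/2`.
#'
#' @param geometry a [detector_geometry()].
#' @param rho radial pixel distance(s) from the beam center, in mm.
#' @param phi detector azimuth(s) in radians.
#' @param flat logical: flat-Ewald approximation.
#' @return list with `k` (1/nm), `theta`, `phi`.
#' @export
ewald_map <- function(geometry, rho, phi, flat = TRUE) {
  stopifnot(all(rho >= 0))
  if (flat) {
    k <- rho / (geometry$wavelength * geometry$distance)
    theta <- rep(pi / 2, length(k))
  } else {
    ts <- atan(rho / geometry$distance) / 2
    k <- (2 / geometry$wavelength) * sin(ts)
    theta <- pi / 2 - ts
  }
  list(k = k, theta = theta, phi = phi)
}

#' Detector radius sampling a given spatial frequency
#' @param geometry a [detector_geometry()].
#' @param k spatial frequency in 1/nm.
#' @param flat logical: flat-Ewald approximation.
#' @return radius in mm from the beam center.
#' @export
ewald_rho <- function(geometry, k, flat = TRUE) {
  if (flat) return(k * geometry$wavelength * geometry$distance)
  s <- k * geometry$wavelength / 2
  if (any(s > 1)) stop("k not reachable at this wavelength")
  geometry$distance * tan(2 * asin(s))
}

#' Uniform random rotations as unit quaternions
#'
#' Shoemake's construction: three uniform variates map to quaternions
#' uniform on SO(3). Reproducible under R's RNG stream.
#'
#' @param n number of rotations.
#' @return `n x 4` matrix of unit quaternions `(w, x, y, z)`.
#' @export
random_orientation <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  a <- sqrt(1 - u1); b <- sqrt(u1)
  cbind(a * sin(2 * pi * u2), a * cos(2 * pi * u2),
        b * sin(2 * pi * u3), b * cos(2 * pi * u3))
}

#' Rotation matrix of a unit quaternion
#' @param q length-4 numeric (w, x, y, z).
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)),
         3, 3, byrow = TRUE)
}

#' Reciprocal-space coordinates of every detector pixel
#' @keywords internal
detector_kmap <- function(geometry, flat = TRUE) {
  n <- geometry$n_pixels
  px <- (seq_len(n) - geometry$beam_center[1]) * geometry$pixel_size
  py <- (seq_len(n) - geometry$beam_center[2]) * geometry$pixel_size
  X <- matrix(px, n, n); Y <- matrix(py, n, n, byrow = TRUE)
  rho <- sqrt(X^2 + Y^2)
  phi <- atan2(Y, X)
  em <- ewald_map(geometry, as.vector(rho), as.vector(phi), flat = flat)
  st <- sin(em$theta)
  q <- cbind(em$k * st * cos(em$phi), em$k * st * sin(em$phi),
             em$k * cos(em$theta))
  list(q = q, k = matrix(em$k, n, n))
}

#' Simulate one noise-free coherent diffraction pattern
#'
#' Samples the rotated 3D intensity on the (flat or curved) Ewald slice by
#' trilinear interpolation and scales to photons/pixel. The photon scale is
#' `flux * flux_scale` at forward scattering (the normalized slice intensity
#' times a single calibration constant), so relative flux regimes are exact
#' and the absolute scale is one config value.
#'
#' @param cart a [cartesian_intensity()] of the model.
#' @param quaternion unit quaternion orienting the sample.
#' @param geometry a [detector_geometry()].
#' @param flux incident photons per um^2 per shot.
#' @param flux_scale calibration: photons/pixel at k = 0 per unit flux.
#' @param flat logical: flat-Ewald slice.
#' @param kmap optional precomputed [detector_kmap()] result.
#' @return numeric `n_pixels x n_pixels` matrix, photons/pixel.
#' @export
simulate_pattern <- function(cart, quaternion, geometry, flux = 1e13,
                             flux_scale = 2e-10, flat = TRUE, kmap = NULL) {
  if (is.null(kmap)) kmap <- detector_kmap(geometry, flat)
  # reject only when the edge-inscribed circle (the analyzed region)
  # exceeds the model's range; corner pixels beyond it are zero-filled
  n <- geometry$n_pixels
  k_edge <- min(max(kmap$k[, round(geometry$beam_center[2])]),
                max(kmap$k[round(geometry$beam_center[1]), ]))
  if (k_edge > cart$k_max_cart + 1e-12)
    stop("detector edge k = ", format(k_edge, digits = 4),
         " 1/nm exceeds the model's reliable k-range ",
         format(cart$k_max_cart, digits = 4), " 1/nm")
  R <- quat_to_matrix(quaternion)
  qrot <- kmap$q %*% t(R)
  vals <- interp_cart(cart, qrot) / cart$i_zero
  vals[as.vector(kmap$k) > cart$k_max_cart] <- 0
  matrix(vals * flux * flux_scale, n, n)
}

#' Isotropic background model
#'
#' @param compton_profile function of k (1/nm) returning photons/pixel of
#'   incoherent (Compton) scattering.
#' @param instrument_profile function of k returning photons/pixel of
#'   instrument background.
#' @return a `background_model` object.
#' @export
background_model <- function(compton_profile = function(k) rep(0, length(k)),
                             instrument_profile = function(k) rep(0, length(k))) {
  structure(list(compton = compton_profile, instrument = instrument_profile),
            class = "background_model")
}

#' Total background profile I_b(k)
#' @param background a [background_model()].
#' @param k spatial frequencies (1/nm).
#' @return photons/pixel.
#' @export
background_profile <- function(background, k) {
  b <- background$compton(k) + background$instrument(k)
  if (any(b < 0)) stop("background profiles must be non-negative")
  b
}

#' Add isotropic backgrounds to a coherent pattern
#'
#' @param pattern coherent pattern (photons/pixel).
#' @param background a [background_model()].
#' @param geometry a [detector_geometry()].
#' @param flat logical: flat-Ewald mapping for pixel k values.
#' @return the source pattern `I_s = I + I_Compt(k) + I_inst(k)`.
#' @export
add_background <- function(pattern, background, geometry, flat = TRUE) {
  kmap <- detector_kmap(geometry, flat)
  pattern + matrix(background_profile(background, as.vector(kmap$k)),
                   geometry$n_pixels, geometry$n_pixels)
}

#' Noise parameters
#'
#' @param flux incident photons per um^2 per shot.
#' @param alpha Fano-noise coefficient (variance `alpha * I_s` per pixel).
#' @param beta electronic-noise variance in photons^2 per pixel.
#' @param poisson_enabled draw photon shot noise.
#' @param detector_enabled draw detector noise.
#' @return a `noise_params` object.
#' @export
noise_params <- function(flux = 1e13, alpha = 3e-4, beta = 1e-4,
                         poisson_enabled = TRUE, detector_enabled = TRUE) {
  stopifnot(alpha >= 0, beta >= 0, flux > 0)
  structure(list(flux = flux, alpha = alpha, beta = beta,
                 poisson_enabled = poisson_enabled,
                 detector_enabled = detector_enabled),
            class = "noise_params")
}

#' Add photon shot noise and detector noise to a source pattern
#'
#' The measured pattern is `I_d = I_s + Delta_s + Delta_d` with `Delta_s`
#' Poisson shot noise (counts ~ Poisson(I_s), `Delta_s = counts - I_s`) and
#' `Delta_d` zero-mean Gaussian detector noise of variance
#' `alpha * I_s + beta`; only the first two noise moments matter downstream.
#'
#' @param source source pattern `I_s` (photons/pixel, >= 0).
#' @param params a [noise_params()].
#' @return the measured pattern `I_d`.
#' @export
add_noise <- function(source, params) {
  if (any(source < -1e-9)) stop("source intensities must be non-negative")
  out <- source
  if (params$poisson_enabled)
    out <- matrix(stats::rpois(length(source), pmax(source, 0)),
                  nrow(source), ncol(source))
  if (params$detector_enabled) {
    sd_d <- sqrt(params$alpha * pmax(source, 0) + params$beta)
    out <- out + matrix(stats::rnorm(length(source), 0, sd_d),
                        nrow(source), ncol(source))
  }
  out
}

#' Corner mask removing the second and fourth quadrants' corners
#'
#' @param n_pixels detector edge size.
#' @param fraction linear fraction of the edge removed at each corner.
#' @return logical matrix, TRUE = valid pixel.
#' @export
corner_mask <- function(n_pixels, fraction = 0.45) {
  m <- matrix(TRUE, n_pixels, n_pixels)
  w <- round(fraction * n_pixels)
  if (w > 0) {
    for (i in seq_len(w)) {
      # second quadrant corner (x low, y high) and fourth (x high, y low)
      m[i, (n_pixels - w + i):n_pixels] <- FALSE
      m[n_pixels - i + 1L, seq_len(w - i + 1L)] <- FALSE
    }
  }
  m
}

#' Generate a synthetic diffraction dataset
#'
#' Simulates `n_patterns` snapshots at seeded uniform random orientations,
#' with optional backgrounds, noise and a validity mask, and stores ground
#' truth (orientations, parameters, background profile). Each pattern is
#' generated from its own seeded sub-stream so any single pattern can be
#' reproduced independently.
#'
#' @param model a [density_volume()] or precomputed [cartesian_intensity()].
#' @param n_patterns number of snapshots.
#' @param geometry a [detector_geometry()].
#' @param noise a [noise_params()]; `NULL` for noise-free patterns.
#' @param background a [background_model()] or `NULL`.
#' @param mask logical `n x n` validity matrix or `NULL` (all valid).
#' @param seed master integer seed.
#' @param flux_scale photons/pixel at forward scattering per unit flux.
#' @param flat logical: flat-Ewald slices.
#' @param keep_truth store noise-free patterns alongside (memory permitting).
#' @return a `pattern_stack` list: `patterns` (array `n x n x n_patterns`),
#'   `mask`, `geometry`, `truth` (quaternions, params, seeds), `flat`.
#' @export
generate_dataset <- function(model, n_patterns, geometry,
                             noise = NULL, background = NULL, mask = NULL,
                             seed = 1L, flux_scale = 2e-10, flat = TRUE,
                             keep_truth = FALSE) {
  cart <- if (inherits(model, "cart_intensity")) model else cartesian_intensity(model)
  kmap <- detector_kmap(geometry, flat)
  n <- geometry$n_pixels
  flux <- if (is.null(noise)) 1e13 else noise$flux
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  quats <- random_orientation(n_patterns)
  pat_seeds <- sample.int(.Machine$integer.max - 1L, n_patterns)
  bgmat <- if (is.null(background)) NULL else
    matrix(background_profile(background, as.vector(kmap$k)), n, n)
  patterns <- array(0, c(n, n, n_patterns))
  clean <- if (keep_truth) array(0, c(n, n, n_patterns)) else NULL
  for (i in seq_len(n_patterns)) {
    set.seed(pat_seeds[i])
    p <- simulate_pattern(cart, quats[i, ], geometry, flux = flux,
                          flux_scale = flux_scale, flat = flat, kmap = kmap)
    if (keep_truth) clean[, , i] <- p
    if (!is.null(bgmat)) p <- p + bgmat
    if (!is.null(noise)) p <- add_noise(p, noise)
    patterns[, , i] <- p
  }
  structure(list(patterns = patterns, mask = mask, geometry = geometry,
                 flat = flat,
                 truth = list(quaternions = quats, seed = seed,
                              pattern_seeds = pat_seeds, flux = flux,
                              flux_scale = flux_scale, noise = noise,
                              background = background,
                              clean_patterns = clean)),
            class = "pattern_stack")
}

#' Instrument background profile at a fraction of the coherent average
#'
#' Builds an isotropic instrument profile equal to `fraction` of the model's
#' coherent angular-average intensity at every radius, in the same
#' photons/pixel scale a dataset will use.
#'
#' @param model a [density_volume()] or [cartesian_intensity()].
#' @param geometry a [detector_geometry()].
#' @param flux,flux_scale photon scaling as in [generate_dataset()].
#' @param fraction background level relative to the coherent profile.
#' @param flat flat-Ewald mapping.
#' @param n_shells radial resolution of the tabulated profile.
#' @return a function of k (1/nm) returning photons/pixel.
#' @export
instrument_fraction_profile <- function(model, geometry, flux = 1e13,
                                        flux_scale = 2e-10, fraction = 0.05,
                                        flat = TRUE, n_shells = 200) {
  cart <- if (inherits(model, "cart_intensity")) model else cartesian_intensity(model)
  kmap <- detector_kmap(geometry, flat)
  kmax <- max(kmap$k)
  kg <- seq(0, kmax, length.out = n_shells)
  # coherent angular-average: average |FT|^2 over directions at each k
  grid <- sh_grid(8, n_theta = 12, n_phi = 24)
  vol <- density_to_intensity_cart(cart, kg, grid)
  w <- grid$w_theta / 2                       # GL weights integrate to 2
  prof <- sapply(seq_along(kg), function(i)
    sum(w * rowMeans(matrix(vol$values[i, , ], grid$n_theta, grid$n_phi))))
  prof <- prof * flux * flux_scale / cart$i_zero
  f <- stats::approxfun(kg, fraction * prof, rule = 2)
  f
}

#' @keywords internal
density_to_intensity_cart <- function(cart, k_grid, grid) {
  nth <- grid$n_theta; nph <- grid$n_phi
  st <- sin(grid$theta); ct <- cos(grid$theta)
  cp <- cos(grid$phi); sp <- sin(grid$phi)
  dirs <- cbind(as.vector(outer(st, cp)), as.vector(outer(st, sp)),
                as.vector(outer(ct, rep(1, nph))))
  vals <- array(0, c(length(k_grid), nth, nph))
  for (ik in seq_along(k_grid)) vals[ik, , ] <- interp_cart(cart, dirs * k_grid[ik])
  intensity_volume(vals, k_grid, grid)
}
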