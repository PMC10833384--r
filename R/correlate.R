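# ---------------------------------------------------------------------------
# Double, triple and quadruple angular correlations accumulated over a
# pattern stack. The flat-Ewald azimuth-shift structure lets every ordered
# shell pair be cross-correlated with FFTs; masks enter as 0/1 indicator
# rows so pair counts come from the same transform.
# ---------------------------------------------------------------------------

#' Included angle between two Ewald-sphere points
#'
#' `cos psi = cos t1 cos t2 + sin t1 sin t2 cos(phi2 - phi1)` with
#' `t = theta(k)` the polar angle of the Ewald point; the flat limit
#' (`t1 = t2 = pi/2`) reduces to the azimuth difference folded into
#' `[0, pi]` (Friedel equivalence).
#'
#' @param k1,k2 shell frequencies in 1/nm.
#' @param dphi azimuth difference in radians.
#' @param geometry a [detector_geometry()] (needed for the curved case).
#' @param flat logical: flat-Ewald.
#' @return included angle(s) psi in `[0, pi]`.
#' @export
included_angle <- function(k1, k2, dphi, geometry = NULL, flat = TRUE) {
  if (flat) {
    d <- abs(dphi) %% (2 * pi)
    return(pmin(d, 2 * pi - d))
  }
  if (is.null(geometry)) stop("geometry required for the curved Ewald case")
  t1 <- pi / 2 - atan(ewald_rho(geometry, k1, flat = FALSE) / geometry$distance) / 2
  t2 <- pi / 2 - atan(ewald_rho(geometry, k2, flat = FALSE) / geometry$distance) / 2
  acos(pmin(1, pmax(-1, cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(dphi))))
}

#' Polar resampler for a detector geometry
#'
#' Precomputes the interpolation stencil mapping detector pixels to a polar
#' `(k, phi)` grid. `"nearest"` picks the closest pixel (required when noise
#' corrections follow, so the per-bin noise second moment is preserved);
#' `"bicubic"` uses separable cubic-convolution (Keys, a = -0.5) for
#' noise-free analyses. A polar bin is invalid when any contributing pixel
#' is masked or off the detector.
#'
#' @param geometry a [detector_geometry()].
#' @param k_grid radial shells (1/nm), within the detector range.
#' @param n_phi azimuthal bin count.
#' @param method `"nearest"` or `"bicubic"`.
#' @param flat logical: flat-Ewald radius mapping.
#' @return a `polar_sampler` object; apply with [polar_resample()].
#' @export
polar_sampler <- function(geometry, k_grid, n_phi,
                          method = c("nearest", "bicubic"), flat = TRUE) {
  method <- match.arg(method)
  n <- geometry$n_pixels
  rho <- ewald_rho(geometry, k_grid, flat = flat)
  if (max(rho) > (n / 2) * geometry$pixel_size * sqrt(2))
    stop("k_grid reaches beyond the detector corner")
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  X <- outer(rho, cos(phi)) / geometry$pixel_size + geometry$beam_center[1]
  Y <- outer(rho, sin(phi)) / geometry$pixel_size + geometry$beam_center[2]
  nb <- length(X)
  if (method == "nearest") {
    ix <- round(as.vector(X)); iy <- round(as.vector(Y))
    inside <- ix >= 1 & ix <= n & iy >= 1 & iy <= n
    lin <- ifelse(inside, (pmax(pmin(iy, n), 1) - 1) * n + pmax(pmin(ix, n), 1), 1L)
    stencil <- matrix(as.integer(lin), nb, 1)
    weights <- matrix(1, nb, 1)
  } else {
    # separable cubic convolution on the 4x4 neighborhood
    kernel <- function(t) {
      at <- abs(t)
      ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
             ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
    }
    x0 <- floor(as.vector(X)); y0 <- floor(as.vector(Y))
    fx <- as.vector(X) - x0; fy <- as.vector(Y) - y0
    stencil <- matrix(1L, nb, 16); weights <- matrix(0, nb, 16)
    inside <- rep(TRUE, nb)
    cidx <- 1L
    for (dy in -1:2) for (dx in -1:2) {
      px <- x0 + dx; py <- y0 + dy
      ok <- px >= 1 & px <= n & py >= 1 & py <= n
      inside <- inside & ok
      stencil[, cidx] <- as.integer((pmax(pmin(py, n), 1) - 1) * n +
                                      pmax(pmin(px, n), 1))
      weights[, cidx] <- kernel(dx - fx) * kernel(dy - fy)
      cidx <- cidx + 1L
    }
  }
  structure(list(geometry = geometry, k_grid = k_grid, n_phi = as.integer(n_phi),
                 method = method, flat = flat, stencil = stencil,
                 weights = weights, inside = inside,
                 n_k = length(k_grid)),
            class = "polar_sampler")
}

#' Resample a detector pattern in polar coordinates
#'
#' @param pattern `n x n` numeric matrix (photons/pixel).
#' @param sampler a [polar_sampler()].
#' @param mask optional logical validity matrix.
#' @return a `polar_pattern`: `values` (`n_k x n_phi`), `valid` (logical),
#'   `k_grid`, `n_phi`.
#' @export
polar_resample <- function(pattern, sampler, mask = NULL) {
  v <- as.vector(pattern)
  nb <- nrow(sampler$stencil)
  if (ncol(sampler$stencil) == 1L) {
    vals <- v[sampler$stencil[, 1]]
  } else {
    vals <- rowSums(sampler$weights *
                      matrix(v[sampler$stencil], nb, ncol(sampler$stencil)))
  }
  valid <- sampler$inside
  if (!is.null(mask)) {
    mv <- as.vector(mask)
    mok <- matrix(mv[sampler$stencil], nb, ncol(sampler$stencil))
    valid <- valid & (rowSums(!mok) == 0)
  }
  vals[!valid] <- 0
  list(values = matrix(vals, sampler$n_k, sampler$n_phi),
       valid = matrix(valid, sampler$n_k, sampler$n_phi),
       k_grid = sampler$k_grid, n_phi = sampler$n_phi)
}

#' Empty correlation accumulator
#' @keywords internal
empty_corr_set <- function(k_grid, n_phi) {
  if (n_phi %% 2L != 0L) stop("n_phi must be even")
  n_psi <- n_phi %/% 2 + 1L
  nk <- length(k_grid)
  z <- array(0, c(nk, nk, n_psi))
  structure(list(C = z, T = z, D = z, counts = z,
                 psi_grid = pi * (0:(n_psi - 1L)) / (n_psi - 1L),
                 k_grid = k_grid, n_phi = as.integer(n_phi),
                 ibar = rep(0, nk), sbar_raw = rep(0, nk),
                 nbar = rep(0, nk),
                 n_patterns = 0L, finalized = FALSE),
            class = "correlation_set")
}

#' Accumulate correlations from polar patterns
#'
#' Core streaming accumulator: adds `I(k1,phi1) * I(k2,phi2)` to C,
#' `I(k1,phi1)^2 * I(k2,phi2)` to T and `I^2 * I^2` to D for every ordered
#' shell pair and every ordered valid azimuth pair, at the psi bin of the
#' folded azimuth difference, incrementing the pair counts; per-shell sums
#' of I and I^2 feed the angular averages. Masked bins contribute nothing.
#' Accumulation is associative: merging partial sets equals accumulating
#' the union.
#'
#' @param set a `correlation_set` accumulator (or `NULL` to start one).
#' @param values numeric array `(n_k, n_phi)` or `(n_k, n_phi, n_pat)`.
#' @param valid logical array of the same shape (default: all valid).
#' @param k_grid radial shells, needed only when starting a new accumulator
#'   (also read from `attr(values, "k_grid")`).
#' @param engine `"fft"` (azimuthal cross-correlation via FFT, the fast
#'   default) or `"direct"` (explicit shift sums in fixed order, bit-exact
#'   against pairwise enumeration; used at small scale and in validation).
#'   Both engines compute the same sums; they differ only in summation
#'   order, i.e. by round-off.
#' @return the updated (un-finalized) `correlation_set`.
#' @export
accumulate_polar <- function(set, values, valid = NULL, k_grid = NULL,
                             engine = c("fft", "direct")) {
  engine <- match.arg(engine)
  if (is.null(k_grid)) k_grid <- attr(values, "k_grid")
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  nk <- dim(values)[1]; nphi <- dim(values)[2]; npat <- dim(values)[3]
  if (is.null(valid)) valid <- array(TRUE, dim(values))
  if (length(dim(valid)) == 2L) dim(valid) <- c(dim(valid), 1L)
  if (is.null(set)) {
    if (is.null(k_grid)) k_grid <- seq_len(nk)
    set <- empty_corr_set(k_grid, nphi)
  }
  if (set$finalized) stop("cannot accumulate into a finalized set")
  stopifnot(dim(set$C)[1] == nk, set$n_phi == nphi)
  n_psi <- length(set$psi_grid)

  V <- values * valid                      # masked bins carry nothing
  V2 <- V * V
  M <- array(as.numeric(valid), dim(valid))
  if (engine == "direct") {
    # canonical enumeration order (pattern, phi1, phi2): every ordered
    # azimuth pair is added one at a time, so sums are bit-identical to a
    # pairwise enumeration in the same order
    for (p in seq_len(npat)) for (f1 in seq_len(nphi)) for (f2 in seq_len(nphi)) {
      d <- (f2 - f1) %% nphi
      j <- min(d, nphi - d) + 1L
      a <- V[, f1, p]; b <- V[, f2, p]
      mm <- outer(M[, f1, p], M[, f2, p])
      set$C[, , j] <- set$C[, , j] + outer(a, b)
      set$T[, , j] <- set$T[, , j] + outer(a * a, b)
      set$D[, , j] <- set$D[, , j] + outer(a * a, b * b)
      set$counts[, , j] <- set$counts[, , j] + mm
    }
    dim(V) <- c(nk, nphi * npat); dim(V2) <- c(nk, nphi * npat)
    dim(M) <- c(nk, nphi * npat)
    set$ibar <- set$ibar + rowSums(V)
    set$sbar_raw <- set$sbar_raw + rowSums(V2)
    set$nbar <- set$nbar + rowSums(M)
    set$n_patterns <- set$n_patterns + npat
    return(set)
  }
  # azimuthal FFTs: arrays (n_phi, nk, npat)
  ffts <- function(A) {
    A <- aperm(A, c(2, 1, 3)); dim(A) <- c(nphi, nk * npat)
    F <- stats::mvfft(A); dim(F) <- c(nphi, nk, npat); F
  }
  F1 <- ffts(V); F2 <- ffts(V2); FM <- ffts(M)
  # cross-spectra summed over patterns: X[m, k1, k2] = sum_p conj(A) * B
  cross <- function(FA, FB) {
    X <- array(0i, c(nphi, nk, nk))
    for (m in seq_len(nphi)) {
      A <- matrix(FA[m, , ], nk, npat)
      B <- matrix(FB[m, , ], nk, npat)
      X[m, , ] <- Conj(A) %*% t(B)
    }
    X
  }
  shift_sums <- function(FA, FB) {
    X <- cross(FA, FB); dim(X) <- c(nphi, nk * nk)
    S <- Re(stats::mvfft(X, inverse = TRUE)) / nphi   # shift-domain sums
    dim(S) <- c(nphi, nk, nk); S
  }
  fold <- function(S) {
    # shift d and n_phi - d share the same folded psi
    out <- array(0, c(n_psi, nk, nk))
    out[1, , ] <- S[1, , ]
    half <- nphi %/% 2
    for (d in seq_len(half)) {
      acc <- S[d + 1L, , ]
      if (d != nphi - d) acc <- acc + S[nphi - d + 1L, , ]
      out[d + 1L, , ] <- acc
    }
    aperm(out, c(2, 3, 1))
  }
  set$C <- set$C + fold(shift_sums(F1, F1))
  set$T <- set$T + fold(shift_sums(F2, F1))
  set$D <- set$D + fold(shift_sums(F2, F2))
  set$counts <- set$counts + fold(shift_sums(FM, FM))
  dim(V) <- c(nk, nphi * npat); dim(V2) <- c(nk, nphi * npat)
  dim(M) <- c(nk, nphi * npat)
  set$ibar <- set$ibar + rowSums(V)
  set$sbar_raw <- set$sbar_raw + rowSums(V2)
  set$nbar <- set$nbar + rowSums(M)
  set$n_patterns <- set$n_patterns + npat
  set
}

#' Accumulate correlations over a pattern stack
#'
#' Streams the stack in chunks through [polar_resample()] and
#' [accumulate_polar()]; peak memory is governed by the chunk size, not the
#' stack length.
#'
#' @param stack a `pattern_stack` from [generate_dataset()].
#' @param k_grid radial shells (1/nm).
#' @param n_phi azimuthal bins.
#' @param method interpolation method, see [polar_sampler()].
#' @param chunk_size patterns per accumulation chunk.
#' @param set optional existing accumulator to extend.
#' @return an un-finalized `correlation_set`.
#' @export
accumulate <- function(stack, k_grid, n_phi, method = "nearest",
                       chunk_size = 200L, set = NULL) {
  sampler <- polar_sampler(stack$geometry, k_grid, n_phi, method = method,
                           flat = stack$flat)
  if (!is.null(set) && (length(set$k_grid) != length(k_grid) ||
                        max(abs(set$k_grid - k_grid)) > 1e-12 ||
                        set$n_phi != n_phi))
    stop("existing set's grids do not match the requested configuration")
  npat <- dim(stack$patterns)[3]
  per_pattern_mask <- !is.null(stack$mask) && length(dim(stack$mask)) == 3L
  for (s in seq(1L, npat, by = chunk_size)) {
    e <- min(s + chunk_size - 1L, npat)
    nb <- e - s + 1L
    vals <- array(0, c(length(k_grid), n_phi, nb))
    vld <- array(TRUE, c(length(k_grid), n_phi, nb))
    for (j in seq_len(nb)) {
      msk <- if (is.null(stack$mask)) NULL
             else if (per_pattern_mask) stack$mask[, , s + j - 1L]
             else stack$mask
      pp <- polar_resample(stack$patterns[, , s + j - 1L], sampler, mask = msk)
      vals[, , j] <- pp$values
      vld[, , j] <- pp$valid
    }
    attr(vals, "k_grid") <- k_grid
    set <- accumulate_polar(set, vals, vld)
  }
  set
}

#' Merge two partial correlation accumulators
#' @param a,b un-finalized `correlation_set`s on identical grids.
#' @return the combined accumulator.
#' @export
merge_corr <- function(a, b) {
  if (a$finalized || b$finalized) stop("merge operates on un-finalized sets")
  stopifnot(all(dim(a$C) == dim(b$C)), a$n_phi == b$n_phi)
  for (f in c("C", "T", "D", "counts", "ibar", "sbar_raw", "nbar"))
    a[[f]] <- a[[f]] + b[[f]]
  a$n_patterns <- a$n_patterns + b$n_patterns
  a
}

#' Finalize a correlation accumulator
#'
#' Divides the correlation sums by their pair counts and the angular-average
#' sums by their bin counts. Bins that never received a pair are undefined
#' (`NA`), not zero.
#'
#' @param set an un-finalized `correlation_set`.
#' @return the finalized set.
#' @export
finalize <- function(set) {
  if (set$finalized) stop("set is already finalized")
  cnt <- set$counts
  pos <- cnt > 0
  for (f in c("C", "T", "D")) {
    v <- set[[f]]
    v[pos] <- v[pos] / cnt[pos]
    v[!pos] <- NA_real_
    set[[f]] <- v
  }
  nb <- set$nbar
  set$ibar <- ifelse(nb > 0, set$ibar / nb, NA_real_)
  set$sbar_raw <- ifelse(nb > 0, set$sbar_raw / nb, NA_real_)
  set$finalized <- TRUE
  set
}
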