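# ---------------------------------------------------------------------------
# Theoretical ("target") correlations computed directly from a model:
# per-degree partial correlation matrices and their psi-curves.
# ---------------------------------------------------------------------------

#' Legendre polynomial values P_l(x)
#'
#' @param l_values integer vector of degrees.
#' @param x numeric vector of abscissae.
#' @return matrix `(length(x), length(l_values))`.
#' @keywords internal
legendre_poly <- function(l_values, x) {
  l_max <- max(l_values)
  P <- matrix(0, length(x), l_max + 1L)
  P[, 1L] <- 1
  if (l_max >= 1L) P[, 2L] <- x
  if (l_max >= 2L) for (l in 2:l_max)
    P[, l + 1L] <- ((2 * l - 1) * x * P[, l] - (l - 1) * P[, l - 1L]) / l
  P[, l_values + 1L, drop = FALSE]
}

#' Theoretical partial correlation matrices from SH coefficients
#'
#' Under a uniform orientation average, the double correlations of a volume
#' with SH coefficients `I_lm(k)` decompose per degree as
#' `C_l(k1,k2) = (1/4pi) * sum_m I_lm(k1) conj(I_lm(k2))` (the prefactor is
#' forced by the spherical-harmonic addition theorem). The triple/quadruple
#' analogues replace one or both legs by the squared-volume coefficients
#' `S_lm(k)`.
#'
#' @param coeffs_I [sh_coefficients()] of the intensity volume.
#' @param coeffs_S [sh_coefficients()] of the squared intensity volume; when
#'   missing, computed by squaring the synthesized volume on a quadrature
#'   grid and re-analyzing at the same band limit (see [sh_square()]).
#' @return a `correlation_matrices` list with elements `C`, `T`, `D` (each a
#'   list over even degrees `l = 0, 2, ..., l_max` of real `n_k x n_k`
#'   matrices), `l_values`, `l_max`, `k_grid`.
#' @export
theoretical_correlation_matrices <- function(coeffs_I, coeffs_S = NULL) {
  if (is.null(coeffs_S)) coeffs_S <- sh_square(coeffs_I)
  if (coeffs_S$l_max != coeffs_I$l_max ||
      length(coeffs_S$k_grid) != length(coeffs_I$k_grid) ||
      max(abs(coeffs_S$k_grid - coeffs_I$k_grid)) > 1e-12)
    stop("coeffs_I and coeffs_S must share l_max and k_grid")
  l_max <- coeffs_I$l_max
  l_values <- seq(0L, l_max, by = 2L)
  mk <- function(A, B) {
    out <- vector("list", length(l_values))
    names(out) <- paste0("l", l_values)
    for (j in seq_along(l_values)) {
      l <- l_values[j]
      rows <- lm_index(rep(l, 2L * l + 1L), seq(-l, l))
      M <- (Conj(t(A[rows, , drop = FALSE])) %*% B[rows, , drop = FALSE]) / (4 * pi)
      # M[k1,k2] = (1/4pi) sum_m conj(A_lm(k1)) B_lm(k2); real volumes give
      # real matrices -- keep the real part, transposed so the "squared" leg
      # of T sits on k1
      out[[j]] <- Re(t(M))
    }
    out
  }
  structure(list(C = mk(coeffs_I$coeffs, coeffs_I$coeffs),
                 T = mk(coeffs_I$coeffs, coeffs_S$coeffs),
                 D = mk(coeffs_S$coeffs, coeffs_S$coeffs),
                 l_values = l_values, l_max = l_max,
                 k_grid = coeffs_I$k_grid),
            class = "correlation_matrices")
}

#' Target correlation curves from partial correlation matrices
#'
#' Sums the Fourier-Legendre series `C(k1,k2,psi) = sum_l C_l(k1,k2)
#' P_l(cos psi)` (same for T and D) on a psi grid, producing the ground
#' truth a measured correlation set converges to.
#'
#' @param matrices a `correlation_matrices` object.
#' @param psi_grid included angles in radians.
#' @return a `correlation_set` (finalized) with uniform unit counts.
#' @export
target_correlation_curves <- function(matrices, psi_grid) {
  nk <- length(matrices$k_grid)
  npsi <- length(psi_grid)
  P <- legendre_poly(matrices$l_values, cos(psi_grid))   # npsi x n_l
  curves <- function(fam) {
    arr <- array(0, c(nk, nk, npsi))
    for (j in seq_along(matrices$l_values)) {
      Ml <- matrices[[fam]][[j]]
      for (ip in seq_len(npsi))
        arr[, , ip] <- arr[, , ip] + Ml * P[ip, j]
    }
    arr
  }
  structure(list(C = curves("C"), T = curves("T"), D = curves("D"),
                 counts = array(1, c(nk, nk, npsi)),
                 psi_grid = psi_grid, k_grid = matrices$k_grid,
                 ibar = NULL, sbar_raw = NULL,
                 n_patterns = Inf, finalized = TRUE),
            class = "correlation_set")
}

#' Attach angular averages of a model to a target correlation set
#'
#' Fills `ibar` (angular average of I) and `sbar_raw` (angular average of
#' I^2) from the monopole coefficients, so targets can be compared against
#' corrected measured sets.
#'
#' @param target a target `correlation_set` from [target_correlation_curves()].
#' @param coeffs_I,coeffs_S SH coefficients of the volume and its square.
#' @return the target set with `ibar`/`sbar_raw` filled.
#' @export
target_attach_averages <- function(target, coeffs_I, coeffs_S = NULL) {
  if (is.null(coeffs_S)) coeffs_S <- sh_square(coeffs_I)
  # angular mean = (1/4pi) * integral = Y_00 * coeff_00 = coeff_00/sqrt(4pi)
  target$ibar <- Re(coeffs_I$coeffs[lm_index(0, 0), ]) / sqrt(4 * pi)
  target$sbar_raw <- Re(coeffs_S$coeffs[lm_index(0, 0), ]) / sqrt(4 * pi)
  target
}
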