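# ---------------------------------------------------------------------------
# Statistical correction of measured correlations.
#
# Noise model per pixel: I_d = I_s + Delta_s + Delta_d with E[Delta] = 0 and
# E[Delta^2 | I_s] = (1 + alpha) * I_s + beta (Poisson shot variance I_s plus
# detector variance alpha*I_s + beta). Noise at distinct pixels is
# independent, which makes the inversions below the unique unbiased ones;
# each is validated against a brute-force Monte-Carlo oracle in the tests.
# ---------------------------------------------------------------------------

#' Estimate source-intensity angular averages from measured correlations
#'
#' `ibar_s(k)` is the plain angular average of the measured patterns;
#' `sbar_s(k)` corrects the measured second moment for the noise
#' contribution: `sbar_s = mean(I_d^2) - (1 + alpha) * ibar_s - beta`.
#'
#' @param set a finalized `correlation_set`.
#' @param alpha,beta detector noise parameters (>= 0).
#' @return list with `ibar_s`, `sbar_s` on the set's `k_grid`.
#' @export
estimate_source_averages <- function(set, alpha = 0, beta = 0) {
  if (!set$finalized) stop("correlation set must be finalized")
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  ibar_s <- set$ibar
  sbar_s <- set$sbar_raw - (1 + alpha) * ibar_s - beta
  list(ibar_s = ibar_s, sbar_s = sbar_s)
}

#' Eliminate shot/detector noise from measured correlations
#'
#' Double correlations are unbiased already (the noise mean is zero). The
#' triple and quadruple corrections subtract every noise-moment term:
#' \preformatted{
#'   C_s = C_d
#'   T_s(k1,k2) = T_d - (1+a) C_s - b Ibar_s(k2)
#'   D_s(k1,k2) = D_d - (1+a) [T_s(k1,k2) + T_s(k2,k1)]
#'                    - b [Sbar_s(k1) + Sbar_s(k2)]
#'                    - (1+a)^2 C_s - (1+a) b [Ibar_s(k1) + Ibar_s(k2)] - b^2
#' }
#' with `a = alpha`, `b = beta`. Valid for distinct pixels; the
#' self-correlated psi = 0 region should be excluded afterwards with
#' [exclude_small_psi()].
#'
#' @param set a finalized `correlation_set` (measured, `I_d`).
#' @param alpha,beta detector noise parameters.
#' @return a `correlation_set` holding `C_s`, `T_s`, `D_s` with `ibar`,
#'   `sbar_raw` replaced by the source averages `ibar_s`, `sbar_s`.
#' @export
eliminate_noise <- function(set, alpha = 0, beta = 0) {
  if (!set$finalized) stop("correlation set must be finalized")
  av <- estimate_source_averages(set, alpha, beta)
  nk <- length(set$k_grid)
  a1 <- 1 + alpha
  ib1 <- array(av$ibar_s, dim(set$C))                       # Ibar_s(k1)
  ib2 <- aperm(array(av$ibar_s, dim(set$C)[c(2, 1, 3)]), c(2, 1, 3))
  sb1 <- array(av$sbar_s, dim(set$C))
  sb2 <- aperm(array(av$sbar_s, dim(set$C)[c(2, 1, 3)]), c(2, 1, 3))
  C_s <- set$C
  T_s <- set$T - a1 * C_s - beta * ib2
  T_swap <- aperm(T_s, c(2, 1, 3))
  D_s <- set$D - a1 * (T_s + T_swap) - beta * (sb1 + sb2) -
    a1^2 * C_s - a1 * beta * (ib1 + ib2) - beta^2
  set$C <- C_s; set$T <- T_s; set$D <- D_s
  set$ibar <- av$ibar_s; set$sbar_raw <- av$sbar_s
  set
}

#' Subtract isotropic backgrounds from noise-corrected correlations
#'
#' With `b(k) = I_Compt(k) + I_inst(k)` the per-shell background and
#' `I_s = I + b`, every correlation of the source intensity expands
#' binomially in the coherent moments; inverting that expansion (C first,
#' then the squared-intensity average, then T, then D) yields the coherent
#' correlations exactly. Shells where the background exceeds the source
#' average are clipped to zero coherent intensity with a warning.
#'
#' @param set a `correlation_set` after [eliminate_noise()] (source-level
#'   statistics in `C`, `T`, `D`, `ibar`, `sbar_raw`).
#' @param background a [background_model()] or a numeric vector of
#'   `I_b(k)` values on the set's `k_grid` (photons/pixel).
#' @return a `correlation_set` with coherent-signal `C`, `T`, `D`, `ibar`
#'   (coherent angular average) and `sbar_raw` (coherent squared average).
#' @export
subtract_background <- function(set, background) {
  if (!set$finalized) stop("correlation set must be finalized")
  b <- if (inherits(background, "background_model"))
    background_profile(background, set$k_grid) else as.numeric(background)
  if (length(b) != length(set$k_grid))
    stop("background profile length does not match k_grid")
  ibar <- set$ibar - b
  if (any(ibar < -1e-9 * max(abs(set$ibar)), na.rm = TRUE))
    warning("background exceeds the source angular average at some shells; ",
            "clipping the coherent average at 0")
  ibar <- pmax(ibar, 0)
  sbar <- set$sbar_raw - 2 * b * ibar - b^2
  d3 <- dim(set$C)
  e1 <- function(v) array(v, d3)                            # f(k1)
  e2 <- function(v) aperm(array(v, d3[c(2, 1, 3)]), c(2, 1, 3))  # f(k2)
  b1 <- e1(b); b2 <- e2(b)
  i1 <- e1(ibar); i2 <- e2(ibar); s1 <- e1(sbar); s2 <- e2(sbar)
  C <- set$C - b1 * i2 - b2 * i1 - b1 * b2
  T_ <- set$T - 2 * b1 * C - b2 * s1 - b1^2 * i2 - 2 * b1 * b2 * i1 - b1^2 * b2
  T_swap <- aperm(T_, c(2, 1, 3))
  D <- set$D - 2 * b2 * T_ - 2 * b1 * T_swap - 4 * b1 * b2 * C -
    b2^2 * s1 - b1^2 * s2 - 2 * b1 * b2^2 * i1 - 2 * b1^2 * b2 * i2 -
    b1^2 * b2^2
  set$C <- C; set$T <- T_; set$D <- D
  set$ibar <- ibar; set$sbar_raw <- sbar
  set
}

#' Exclude the self-correlated small-psi region
#'
#' Marks psi bins below `min_psi` undefined in every curve (counts zeroed),
#' removing the psi = 0 points where noise at k1 = k2 is self-correlated
#' and cannot be canceled. Errors if too few bins remain to fit the
#' requested band limit.
#'
#' @param set a `correlation_set`.
#' @param min_psi threshold in radians (bins with `psi < min_psi` dropped).
#' @param l_max band limit the remaining bins must still support
#'   (default 0 = no check).
#' @return the set with the small-psi bins undefined.
#' @export
exclude_small_psi <- function(set, min_psi, l_max = 0L) {
  drop <- which(set$psi_grid < min_psi)
  if (length(drop)) {
    set$counts[, , drop] <- 0
    for (f in c("C", "T", "D")) {
      v <- set[[f]]
      v[, , drop] <- NA_real_
      set[[f]] <- v
    }
  }
  remaining <- length(set$psi_grid) - length(drop)
  if (remaining < floor(l_max / 2) + 1L)
    stop("only ", remaining, " psi bins remain; cannot fit l_max = ", l_max)
  set
}
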