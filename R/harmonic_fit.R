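# ---------------------------------------------------------------------------
# Fourier-Legendre fits of correlation curves, partial correlation matrices,
# and eigen-basis extraction.
# ---------------------------------------------------------------------------

#' Fit correlation curves to even-degree Legendre series
#'
#' For each shell pair `(k1, k2)` solves the weighted overdetermined linear
#' system `corr(psi_i) = sum_l M_l P_l(cos psi_i)` over even degrees
#' `l = 0, 2, ..., l_max` (odd degrees vanish by Friedel symmetry and are
#' excluded a priori), weighting sub-equation i by `sqrt(N_i)` pair counts.
#' Undefined psi bins are dropped per curve. C and D matrices are
#' symmetrized as `(M + t(M))/2`; T keeps its ordering (the squared leg on
#' k1).
#'
#' @param set a finalized `correlation_set`.
#' @param l_max even band limit.
#' @param weighted use `sqrt(counts)` weights (TRUE) or uniform weights.
#' @return a `correlation_matrices` object (families C, T, D).
#' @export
fit_legendre <- function(set, l_max, weighted = TRUE) {
  if (!set$finalized) stop("correlation set must be finalized")
  if (l_max %% 2L != 0L) stop("l_max must be even (odd subspaces vanish)")
  l_values <- seq(0L, l_max, by = 2L)
  nk <- length(set$k_grid)
  P <- legendre_poly(l_values, cos(set$psi_grid))    # n_psi x n_l
  fams <- list(C = set$C, T = set$T, D = set$D)
  out <- list()
  for (fam in names(fams)) {
    arr <- fams[[fam]]
    Ml <- lapply(l_values, function(l) matrix(0, nk, nk))
    for (i1 in seq_len(nk)) for (i2 in seq_len(nk)) {
      y <- arr[i1, i2, ]
      w <- set$counts[i1, i2, ]
      ok <- !is.na(y) & w > 0
      if (sum(ok) < length(l_values))
        stop("under-determined Legendre system at shell pair (", i1, ",", i2,
             "): ", sum(ok), " defined psi bins for ", length(l_values),
             " unknowns")
      sw <- if (weighted) sqrt(w[ok]) else rep(1, sum(ok))
      cf <- stats::lsfit(P[ok, , drop = FALSE] * sw, y[ok] * sw,
                         intercept = FALSE)$coefficients
      for (j in seq_along(l_values)) Ml[[j]][i1, i2] <- cf[j]
    }
    names(Ml) <- paste0("l", l_values)
    if (fam != "T") Ml <- lapply(Ml, function(M) (M + t(M)) / 2)
    out[[fam]] <- Ml
  }
  structure(list(C = out$C, T = out$T, D = out$D,
                 l_values = l_values, l_max = as.integer(l_max),
                 k_grid = set$k_grid),
            class = "correlation_matrices")
}

#' Eigen-basis extraction from partial correlation matrices
#'
#' Decomposes each even-degree matrix into orthonormal eigenvectors and
#' norms. The norm of basis vector i is `c_{l,i} = sqrt(4 pi lambda_{l,i})`:
#' the 4 pi factor carries the orientation-average prefactor of the
#' correlation decomposition, so SH coefficient rows reconstruct as unitary
#' mixtures of `c_{l,i} u_{l,i}(k)`. Negative eigenvalues (noise) are
#' clipped to zero and their summed magnitude reported; at most
#' `min(2l+1, k_max)` positive norms are retained per subspace.
#'
#' @param matrices a `correlation_matrices` object.
#' @param family `"C"` or `"D"`.
#' @return a `basis_set`: per degree, `u` (orthonormal columns), `norms`,
#'   plus `l_values`, `k_grid`, `clipped` (summed negative eigenvalue mass
#'   per degree).
#' @export
eigen_basis <- function(matrices, family = c("C", "D")) {
  family <- match.arg(family)
  nk <- length(matrices$k_grid)
  per_l <- vector("list", length(matrices$l_values))
  clipped <- numeric(length(matrices$l_values))
  for (j in seq_along(matrices$l_values)) {
    l <- matrices$l_values[j]
    M <- matrices[[family]][[j]]
    if (max(abs(M - t(M))) > 1e-8 * max(abs(M), 1e-300))
      stop("matrix for l = ", l, " is not symmetric")
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    lam <- eg$values
    clipped[j] <- sum(abs(lam[lam < 0]))
    lam <- pmax(lam, 0)
    keep <- min(2L * l + 1L, nk)
    lam[-seq_len(keep)] <- 0
    pos <- which(lam > 1e-12 * max(lam, 0))    # drop round-off eigenvalues
    per_l[[j]] <- list(l = l,
                       u = eg$vectors[, pos, drop = FALSE],
                       norms = sqrt(4 * pi * lam[pos]))
  }
  names(per_l) <- paste0("l", matrices$l_values)
  structure(list(subspaces = per_l, l_values = matrices$l_values,
                 k_grid = matrices$k_grid, family = family,
                 clipped = clipped),
            class = "basis_set")
}

#' Rank basis vectors globally by norm and select the top ones
#'
#' Sorts every basis vector across subspaces by descending norm (ties broken
#' by lower degree, then lower index) and returns the top `top_n` selection
#' with the induced per-degree counts `i_max,l`.
#'
#' @param basis a `basis_set`.
#' @param top_n number of vectors to keep (>= 1).
#' @return list: `ranking` (data.frame l, i, norm in rank order, full),
#'   `selected` (top_n rows), `i_max` (named integer vector per degree).
#' @export
rank_select <- function(basis, top_n) {
  rows <- do.call(rbind, lapply(basis$subspaces, function(s) {
    if (length(s$norms) == 0) return(NULL)
    data.frame(l = s$l, i = seq_along(s$norms), norm = s$norms)
  }))
  rows <- rows[order(-rows$norm, rows$l, rows$i), , drop = FALSE]
  rownames(rows) <- NULL
  if (top_n < 1) stop("top_n must be >= 1")
  if (top_n > nrow(rows))
    stop("top_n = ", top_n, " exceeds the ", nrow(rows),
         " available positive-norm basis vectors")
  sel <- rows[seq_len(top_n), , drop = FALSE]
  i_max <- integer(length(basis$l_values))
  names(i_max) <- paste0("l", basis$l_values)
  for (r in seq_len(nrow(sel))) {
    key <- paste0("l", sel$l[r])
    i_max[key] <- max(i_max[key], sel$i[r])
  }
  list(ranking = rows, selected = sel, i_max = i_max)
}
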