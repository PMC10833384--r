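# ---------------------------------------------------------------------------
# Restricted unitary matrices from hyperspherical angle variables.
#
# A subspace of degree l has dimension N = 2l+1. Angles are consumed in
# blocks of (N-1), (N-2), ...: block t fixes column t of a special
# orthogonal matrix R_N, so aligning i_max basis vectors needs
# i_max*N - i_max*(i_max+1)/2 angles. A fixed linear map converts the real
# orthogonal columns (indexed by a real spherical-harmonic basis) to
# complex columns obeying U(-m) = (-1)^m conj(U(m)), which keeps every
# synthesized intensity volume real.
# ---------------------------------------------------------------------------

#' Unit vector on the N-sphere from hyperspherical angles
#'
#' Component 1 is `cos a1`; component j is `prod(sin a_1..a_{j-1}) cos a_j`;
#' the last component is the full sine product. Unit norm by construction.
#'
#' @param angles numeric vector of N-1 angles.
#' @return unit vector of length N = length(angles) + 1.
#' @export
hypersphere_vector <- function(angles) {
  n <- length(angles) + 1L
  if (n < 2L) stop("need at least one angle")
  v <- numeric(n)
  sprod <- 1
  for (j in seq_len(n - 1L)) {
    v[j] <- sprod * cos(angles[j])
    sprod <- sprod * sin(angles[j])
  }
  v[n] <- sprod
  v
}

#' Deterministic orthogonal completion of a hyperspherical unit vector
#'
#' Completes the unit vector built from `angles` to an N x N orthogonal
#' matrix whose first column is that vector. Column j+1 is the normalized
#' partial derivative of the hyperspherical map with respect to angle j,
#' which has the branch-free closed form
#' `(0, ..., 0, -sin a_j, cos a_j * hypersphere(a_{j+1}, ...))`. With all
#' angles zero this is the identity; for N = 2 it is the rotation by a1.
#'
#' @param angles numeric vector of N-1 angles.
#' @return N x N orthogonal matrix (determinant +1).
#' @export
orthogonal_complete <- function(angles) {
  n <- length(angles) + 1L
  O <- matrix(0, n, n)
  O[, 1L] <- hypersphere_vector(angles)
  for (j in seq_len(n - 1L)) {
    col <- numeric(n)
    col[j] <- -sin(angles[j])
    if (j < n - 1L) {
      col[(j + 1L):n] <- cos(angles[j]) * hypersphere_vector(angles[(j + 1L):(n - 1L)])
    } else {
      col[n] <- cos(angles[j])
    }
    O[, j + 1L] <- col
  }
  O
}

#' Number of angle variables for a restricted alignment
#'
#' `i_max` aligned basis vectors in a subspace of dimension `N = 2l+1`
#' require `i_max*(2l+1) - i_max*(i_max+1)/2` independent angles; the full
#' alignment (`i_max = N`) gives `N(N-1)/2`.
#'
#' @param l subspace degree.
#' @param i_max number of aligned basis vectors, `1 <= i_max <= 2l+1`.
#' @return integer variable count.
#' @export
count_variables <- function(l, i_max) {
  N <- 2L * l + 1L
  if (i_max < 1L || i_max > N)
    stop("i_max must lie in [1, ", N, "] for l = ", l)
  as.integer(i_max * N - i_max * (i_max + 1L) / 2L)
}

#' Leading columns of a special orthogonal matrix from angles
#'
#' Consumes angles in blocks of (N-1), (N-2), ...; each block builds an
#' orthogonal completion which right-multiplies the trailing columns, so
#' after block t column t is final. Only the leading `i_max` columns are
#' returned.
#'
#' @param angles numeric vector of length `count_variables(l, i_max)` with
#'   `N = 2l+1`.
#' @param N subspace dimension.
#' @param i_max number of columns to construct.
#' @return N x i_max matrix with orthonormal columns.
#' @export
special_orthogonal <- function(angles, N, i_max = N) {
  need <- i_max * N - i_max * (i_max + 1L) / 2L
  if (length(angles) != need)
    stop("expected ", need, " angles for N = ", N, ", i_max = ", i_max,
         "; got ", length(angles))
  R <- diag(N)
  pos <- 0L
  for (t in seq_len(min(i_max, N - 1L))) {
    m <- N - t               # block size
    if (m < 1L) break
    O <- orthogonal_complete(angles[(pos + 1L):(pos + m)])
    pos <- pos + m
    R[, t:N] <- R[, t:N, drop = FALSE] %*% O
  }
  R[, seq_len(i_max), drop = FALSE]
}

#' Real-to-complex conversion of orthogonal columns
#'
#' Maps a real orthonormal column block (rows indexed by the real
#' spherical-harmonic basis of degree l) to complex columns over
#' m = -l..l satisfying the conjugate symmetry
#' `U(-m, i) = (-1)^m conj(U(m, i))`, so any intensity volume synthesized
#' through the block is real. The map is unitary, hence the columns stay
#' orthonormal. Row layout of the real block: row 1 is m = 0, then pairs
#' (cos-like, sin-like) for m = 1..l. For l = 0 pass the 1 x 1 sign matrix
#' directly.
#'
#' @param R_block real N x i_max matrix with orthonormal columns, N = 2l+1.
#' @param l subspace degree.
#' @return complex N x i_max block with rows ordered m = -l..l.
#' @export
to_unitary <- function(R_block, l) {
  N <- 2L * l + 1L
  if (nrow(R_block) != N) stop("block has ", nrow(R_block), " rows; expected ", N)
  if (max(abs(crossprod(R_block) - diag(ncol(R_block)))) > 1e-8)
    stop("input columns are not orthonormal")
  if (l == 0L) return(matrix(as.complex(R_block), 1L))
  U <- matrix(0i, N, ncol(R_block))
  mrow <- function(m) l + m + 1L           # row index for order m
  U[mrow(0), ] <- R_block[1L, ]
  for (m in seq_len(l)) {
    rc <- R_block[2L * m, ]                # cos-like real row
    rs <- R_block[2L * m + 1L, ]           # sin-like real row
    U[mrow(m), ] <- (rc + 1i * rs) / sqrt(2)
    U[mrow(-m), ] <- (-1)^m * (rc - 1i * rs) / sqrt(2)
  }
  U
}

#' Restricted unitary column block from angle variables
#'
#' Convenience composition of [special_orthogonal()] and [to_unitary()].
#' For l = 0 the block is the 1 x 1 sign matrix `[sign]` and consumes no
#' angles.
#'
#' @param angles angle variables (length `count_variables(l, i_max)`).
#' @param l subspace degree.
#' @param i_max number of columns.
#' @param sign l = 0 sign choice (+1 or -1).
#' @return complex `(2l+1) x i_max` block with orthonormal columns.
#' @export
unitary_block <- function(angles, l, i_max, sign = 1) {
  if (l == 0L) {
    if (length(angles) != 0L) stop("l = 0 carries no angles")
    return(matrix(as.complex(sign), 1L, 1L))
  }
  to_unitary(special_orthogonal(angles, 2L * l + 1L, i_max), l)
}
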