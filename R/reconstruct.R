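# ---------------------------------------------------------------------------
# Basis-vector alignment: the constraint error between the triple-correlation
# data and the model implied by an assumed set of restricted unitary
# matrices, minimized by progressive Levenberg-Marquardt least squares.
# ---------------------------------------------------------------------------

#' Set up a reconstruction problem from fitted correlation matrices
#'
#' Extracts the C and D eigen bases, ranks the C basis vectors globally,
#' selects the top `top_n` (the D-side counts are set equal to the C-side
#' counts per subspace), precomputes the data-side constraint matrices and
#' the dense spherical-harmonic synthesis/analysis operators used in the
#' residual evaluation.
#'
#' @param matrices a `correlation_matrices` object (families C, T, D).
#' @param top_n number of ranked basis vectors to align.
#' @return a `recon_problem` list.
#' @export
recon_setup <- function(matrices, top_n) {
  basis_C <- eigen_basis(matrices, "C")
  basis_D <- eigen_basis(matrices, "D")
  sel <- rank_select(basis_C, top_n)
  l_max <- matrices$l_max
  k_grid <- matrices$k_grid
  grid <- sq_grid(l_max)
  # dense node-space operators over all (l, m), l <= l_max
  nth <- grid$n_theta; nph <- grid$n_phi
  P <- legendre_normalized(l_max, grid$x)
  n_lm <- (l_max + 1L)^2
  theta_i <- rep(seq_len(nth), nph)
  phi_v <- rep(grid$phi, each = nth)
  Yb <- matrix(0i, nth * nph, n_lm)
  for (l in 0:l_max) for (m in -l:l) {
    pl <- P[[abs(m) + 1L]][, l - abs(m) + 1L]
    ph <- if (m >= 0) exp(1i * m * phi_v) else (-1)^m * exp(1i * m * phi_v)
    Yb[, lm_index(l, m)] <- pl[theta_i] * ph
  }
  w_node <- (grid$w_theta[theta_i]) * (2 * pi / nph)
  # restrict the node-space operators to even degrees: odd coefficients of
  # a Friedel-symmetric intensity (and of its square's projection onto the
  # even subspaces) are identically zero
  idx_even <- unlist(lapply(seq(0L, l_max, by = 2L), function(l)
    lm_index(rep(l, 2L * l + 1L), seq(-l, l))))
  Yb_even <- Yb[, idx_even, drop = FALSE]
  # active degrees and their basis slices
  i_max <- sel$i_max
  active_l <- matrices$l_values[i_max[paste0("l", matrices$l_values)] > 0]
  W_data <- constraint_rows <- list()
  for (l in active_l) {
    key <- paste0("l", l)
    im <- i_max[[key]]
    jm <- im                                   # j_max = i_max by design
    sC <- basis_C$subspaces[[key]]; sD <- basis_D$subspaces[[key]]
    if (length(sD$norms) < jm)
      stop("D basis for l = ", l, " has only ", length(sD$norms),
           " positive-norm vectors; need ", jm)
    W_data[[key]] <- data_constraints(matrices$T[[key]],
                                      sC$u[, seq_len(im), drop = FALSE],
                                      sC$norms[seq_len(im)],
                                      sD$u[, seq_len(jm), drop = FALSE],
                                      sD$norms[seq_len(jm)])
  }
  structure(list(matrices = matrices, basis_C = basis_C, basis_D = basis_D,
                 selection = sel, l_max = l_max, k_grid = k_grid,
                 grid = grid, Yb = Yb, Yb_even = Yb_even,
                 idx_even = idx_even,
                 rowpos = match(seq_len(n_lm), idx_even),
                 w_node = w_node,
                 i_max_full = i_max, active_l = active_l,
                 W_data = W_data, top_n = as.integer(top_n)),
            class = "recon_problem")
}

#' Data-side constraint matrix for one subspace
#'
#' `W[j, i] = 4 pi * v_j' T_l u_i / (d_j c_i)`: the bilinear projection of
#' the fitted triple-correlation matrix onto the C- and D-eigen bases, with
#' the same orientation-average scale as the correlation decomposition.
#'
#' @param Tl fitted `n_k x n_k` triple-correlation matrix (squared leg on
#'   rows).
#' @param u,cn C-basis columns and norms (i = 1..i_max).
#' @param v,dn D-basis columns and norms (j = 1..j_max).
#' @return real `j_max x i_max` matrix.
#' @export
data_constraints <- function(Tl, u, cn, v, dn) {
  W <- 4 * pi * t(v) %*% Tl %*% u
  sweep(sweep(W, 1, dn, "/"), 2, cn, "/")
}

#' Assemble SH coefficients and intensity from aligned basis vectors
#'
#' `I_lm(k) = sum_i U_{l,m,i} c_{l,i} u_{l,i}(k)` over the active vectors;
#' inactive degrees are zero.
#'
#' @param U_blocks named list (`"l0"`, `"l2"`, ...) of complex
#'   `(2l+1) x i_max` column blocks.
#' @param problem a `recon_problem`.
#' @return an [sh_coefficients()] object.
#' @export
assemble_intensity <- function(U_blocks, problem) {
  A <- matrix(0i, (problem$l_max + 1L)^2, length(problem$k_grid))
  for (l in problem$active_l) {
    key <- paste0("l", l)
    U <- U_blocks[[key]]
    if (is.null(U)) next
    s <- problem$basis_C$subspaces[[key]]
    im <- ncol(U)
    rows <- lm_index(rep(l, 2L * l + 1L), seq(-l, l))
    A[rows, ] <- U %*% (s$norms[seq_len(im)] *
                          t(s$u[, seq_len(im), drop = FALSE]))
  }
  sh_coefficients(A, problem$l_max, problem$k_grid)
}

#' Model-side V-factor blocks from an assembled intensity
#'
#' Squares the assembled volume on the quadrature grid, re-analyzes it, and
#' projects the squared-volume coefficients onto the D-eigen basis:
#' `V[m, j] = (1/d_j) sum_k S'_lm(k) v_j(k)`. Unitarity of the result is
#' not guaranteed away from a true alignment.
#'
#' @param coeffs assembled [sh_coefficients()].
#' @param problem a `recon_problem`.
#' @return named list of complex `(2l+1) x j_max` blocks.
#' @export
derive_V <- function(coeffs, problem) {
  Ae <- coeffs$coeffs[problem$idx_even, , drop = FALSE]
  vals <- Re(problem$Yb_even %*% Ae)             # nodes x nk
  S <- t(Conj(problem$Yb_even) * problem$w_node) %*% (vals * vals)
  rowpos <- problem$rowpos
  out <- list()
  for (l in problem$active_l) {
    key <- paste0("l", l)
    sD <- problem$basis_D$subspaces[[key]]
    jm <- problem$i_max_full[[key]]
    rows <- rowpos[lm_index(rep(l, 2L * l + 1L), seq(-l, l))]
    proj <- S[rows, , drop = FALSE] %*% sD$u[, seq_len(jm), drop = FALSE]
    out[[key]] <- sweep(proj, 2, sD$norms[seq_len(jm)], "/")
  }
  out
}

#' Constraint residual vector and error
#'
#' Concatenates, over active subspaces, the weighted differences
#' `c_i sqrt(d_j) (Wtilde[j,i] - W[j,i])` split into real and imaginary
#' parts, plus, for subspaces with exactly one active D vector, the
#' unit-norm check `d_1 (||V column 1|| - 1)`. The error is the sum of
#' squared residuals.
#'
#' @param U_blocks named list of unitary column blocks (restricted to the
#'   currently active i_max per subspace).
#' @param problem a `recon_problem`.
#' @param i_max_now named integer vector of currently active counts
#'   (default: the full selection).
#' @return numeric residual vector with attribute `"epsilon"`.
#' @export
residual_vector <- function(U_blocks, problem, i_max_now = problem$i_max_full) {
  coeffs <- assemble_intensity(U_blocks, problem)
  Vt <- derive_V(coeffs, problem)
  res <- numeric(0)
  for (l in problem$active_l) {
    key <- paste0("l", l)
    im <- i_max_now[[key]]
    if (is.null(im) || im == 0L) next
    U <- U_blocks[[key]]
    V <- Vt[[key]][, seq_len(im), drop = FALSE]
    sC <- problem$basis_C$subspaces[[key]]
    sD <- problem$basis_D$subspaces[[key]]
    cn <- sC$norms[seq_len(im)]; dn <- sD$norms[seq_len(im)]
    Wt <- t(Conj(t(U)) %*% V)                  # (j, i) = <U_i, V_j>
    W <- problem$W_data[[key]][seq_len(im), seq_len(im), drop = FALSE]
    wgt <- outer(sqrt(dn), cn)                 # c_i * sqrt(d_j)
    dW <- wgt * (Wt - W)
    res <- c(res, Re(dW), Im(dW))
    if (im == 1L)
      res <- c(res, dn[1] * (sqrt(sum(Mod(V[, 1])^2)) - 1))
  }
  attr(res, "epsilon") <- sum(res^2)
  res
}

# --- angle-parameter bookkeeping --------------------------------------------

#' @keywords internal
blocks_from_params <- function(params, problem) {
  out <- list()
  for (l in problem$active_l) {
    key <- paste0("l", l)
    im <- params$i_max[[key]]
    if (is.null(im) || im == 0L) next
    out[[key]] <- unitary_block(params$angles[[key]], l, im,
                                sign = params$sign0)
  }
  out
}

#' @keywords internal
flatten_angles <- function(params, problem) {
  unlist(lapply(problem$active_l, function(l) params$angles[[paste0("l", l)]]),
         use.names = FALSE)
}

#' @keywords internal
unflatten_angles <- function(x, params, problem) {
  pos <- 0L
  for (l in problem$active_l) {
    key <- paste0("l", l)
    n <- length(params$angles[[key]])
    if (n > 0) params$angles[[key]] <- x[(pos + 1L):(pos + n)]
    pos <- pos + n
  }
  params
}

#' Progressive multi-trial alignment optimization
#'
#' Runs `n_trials` independent optimizations from seeded random starting
#' angles. Each trial introduces the ranked basis vectors one at a time (by
#' descending norm); after each introduction all active angles are refit by
#' Levenberg-Marquardt least squares on the constraint residuals, the
#' previous optimum seeding the next stage. The monopole sign is chosen by
#' direct comparison whenever it enters the schedule.
#'
#' @param problem a `recon_problem`.
#' @param n_trials number of independent trials.
#' @param seed master seed for the trial starting points.
#' @param maxiter Levenberg-Marquardt iteration cap per stage.
#' @param ftol relative residual-reduction tolerance.
#' @return a `recon_result`: per trial `params`, `epsilon`, `coeffs`,
#'   `trajectory`; plus the problem and seeds.
#' @export
progressive_optimize <- function(problem, n_trials = 20L, seed = 1L,
                                 maxiter = 100L, ftol = 1e-10) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  sched <- problem$selection$selected
  trials <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    set.seed(trial_seeds[tr])
    params <- list(angles = stats::setNames(
      lapply(problem$active_l, function(l) numeric(0)),
      paste0("l", problem$active_l)),
      i_max = stats::setNames(as.list(rep(0L, length(problem$active_l))),
                              paste0("l", problem$active_l)),
      sign0 = 1)
    traj <- numeric(0)
    hit_cap <- FALSE                        # any stage stopped at maxiter
    for (s in seq_len(nrow(sched))) {
      l <- sched$l[s]
      key <- paste0("l", l)
      new_i <- params$i_max[[key]] + 1L
      params$i_max[[key]] <- new_i
      if (l > 0) {
        blk_len <- (2L * l + 1L) - new_i
        params$angles[[key]] <- c(params$angles[[key]],
                                  stats::runif(blk_len, 0, 2 * pi))
      }
      # monopole sign: discrete 1-bit search at each stage it is active
      if (any(problem$active_l == 0L) && (params$i_max[["l0"]] %||% 0L) > 0L) {
        eps_for <- function(sg) {
          p2 <- params; p2$sign0 <- sg
          attr(residual_vector(blocks_from_params(p2, problem), problem,
                               p2$i_max), "epsilon")
        }
        params$sign0 <- if (eps_for(1) <= eps_for(-1)) 1 else -1
      }
      x0 <- flatten_angles(params, problem)
      if (length(x0) > 0) {
        fn <- function(x) {
          p2 <- unflatten_angles(x, params, problem)
          r <- as.numeric(residual_vector(blocks_from_params(p2, problem),
                                          problem, p2$i_max))
          # least-squares solvers need >= as many residuals as parameters;
          # zero padding leaves the objective unchanged
          if (length(r) < length(x)) r <- c(r, numeric(length(x) - length(r)))
          r
        }
        fit <- withCallingHandlers(
          minpack.lm::nls.lm(par = x0, fn = fn,
                             control = minpack.lm::nls.lm.control(
                               maxiter = maxiter, ftol = ftol,
                               ptol = 1e-10)),
          warning = function(w) {
            if (grepl("maxiter|iterations", conditionMessage(w)))
              invokeRestart("muffleWarning")
          })
        if (fit$info < 1 || fit$info > 4) hit_cap <- TRUE
        params <- unflatten_angles(fit$par, params, problem)
      }
      eps <- attr(residual_vector(blocks_from_params(params, problem),
                                  problem, params$i_max), "epsilon")
      traj <- c(traj, eps)
    }
    coeffs <- assemble_intensity(blocks_from_params(params, problem), problem)
    trials[[tr]] <- list(params = params, epsilon = traj[length(traj)],
                         trajectory = traj, coeffs = coeffs,
                         seed = trial_seeds[tr], converged = !hit_cap)
  }
  structure(list(trials = trials, problem = problem, seed = seed),
            class = "recon_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- trial averaging --------------------------------------------------------

#' @keywords internal
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  a <- w / th
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @keywords internal
grid_directions <- function(grid) {
  nth <- grid$n_theta; nph <- grid$n_phi
  theta <- rep(grid$theta, nph)
  phi <- rep(grid$phi, each = nth)
  list(theta = theta, phi = phi,
       dirs = cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta)))
}

#' @keywords internal
eval_at_rotation <- function(coeffs, gd, R, mirror = FALSE) {
  d <- gd$dirs %*% R                 # row vectors times R: directions R' n
  if (mirror) d[, 2] <- -d[, 2]      # reflection through the xz-plane
  th <- acos(pmin(1, pmax(-1, d[, 3])))
  ph <- atan2(d[, 2], d[, 1])
  sh_eval(coeffs, th, ph)
}

#' Align optimized trials and average their intensity volumes
#'
#' The reconstruction is defined only up to a global rotation and a mirror
#' flip (the correlation-invariant degeneracy). Trials whose final error
#' exceeds `outlier_mult` times the median are dropped; the rest are
#' aligned to the lowest-error trial by a seeded coarse search over
#' rotations (and the flip) maximizing the intensity cross-correlation,
#' refined by Nelder-Mead, then averaged pointwise on the quadrature grid
#' and re-analyzed.
#'
#' A trial counts as an outlier when its error exceeds `outlier_mult`
#' times the best trial's error (with a small floor tied to the scale of
#' the data-side constraints, so that a cluster of near-zero errors is
#' never split by round-off).
#'
#' @param result a `recon_result`.
#' @param n_coarse number of coarse candidate rotations.
#' @param outlier_mult outlier rejection multiple of the best trial error.
#' @param seed seed for the coarse rotation set.
#' @return list: `coeffs` (averaged [sh_coefficients()]), `volume`
#'   (averaged [intensity_volume()]), `used` (trial indices kept),
#'   `transforms` (per-trial rotation + mirror flag).
#' @export
average_trials <- function(result, n_coarse = 300L, outlier_mult = 3,
                           seed = 1L) {
  problem <- result$problem
  eps <- vapply(result$trials, function(t) t$epsilon, 0)
  eps_scale <- sum(vapply(problem$active_l, function(l) {
    key <- paste0("l", l)
    im <- problem$i_max_full[[key]]
    W <- problem$W_data[[key]][seq_len(im), seq_len(im), drop = FALSE]
    cn <- problem$basis_C$subspaces[[key]]$norms[seq_len(im)]
    dn <- problem$basis_D$subspaces[[key]]$norms[seq_len(im)]
    sum((outer(sqrt(dn), cn) * W)^2)
  }, 0))
  keep <- which(eps <= outlier_mult * max(min(eps), 1e-12 * eps_scale))
  if (length(keep) == 0) stop("all trials flagged as outliers")
  ref_i <- keep[which.min(eps[keep])]
  gd <- grid_directions(problem$grid)
  ref_vals <- Re(problem$Yb %*% result$trials[[ref_i]]$coeffs$coeffs)
  wts <- problem$w_node
  score <- function(vals) {
    sum(wts * (ref_vals * vals)) /
      sqrt(sum(wts * ref_vals^2) * sum(wts * vals^2))
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  cand <- rbind(c(1, 0, 0, 0), random_orientation(n_coarse - 1L))
  acc <- 0
  transforms <- vector("list", length(result$trials))
  for (tr in keep) {
    if (tr == ref_i) {
      vals <- Re(problem$Yb %*% result$trials[[tr]]$coeffs$coeffs)
      acc <- acc + vals
      transforms[[tr]] <- list(R = diag(3), mirror = FALSE, score = 1)
      next
    }
    co <- result$trials[[tr]]$coeffs
    best <- list(s = -Inf)
    for (mir in c(FALSE, TRUE)) {
      for (ci in seq_len(nrow(cand))) {
        R <- quat_to_matrix(cand[ci, ])
        s <- score(eval_at_rotation(co, gd, R, mir))
        if (s > best$s) best <- list(s = s, R = R, mirror = mir)
      }
    }
    # local refinement over a rotation-vector perturbation
    obj <- function(w) -score(eval_at_rotation(co, gd,
                                               best$R %*% rotvec_to_matrix(w),
                                               best$mirror))
    op <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                       control = list(maxit = 120, reltol = 1e-8))
    Rb <- best$R %*% rotvec_to_matrix(op$par)
    acc <- acc + eval_at_rotation(co, gd, Rb, best$mirror)
    transforms[[tr]] <- list(R = Rb, mirror = best$mirror, score = -op$value)
  }
  avg_vals <- acc / length(keep)
  nth <- problem$grid$n_theta; nph <- problem$grid$n_phi
  arr <- array(0, c(length(problem$k_grid), nth, nph))
  for (ik in seq_along(problem$k_grid))
    arr[ik, , ] <- matrix(avg_vals[, ik], nth, nph)
  vol <- intensity_volume(arr, problem$k_grid, problem$grid)
  list(coeffs = sh_analyze(vol, problem$l_max), volume = vol,
       used = keep, transforms = transforms)
}
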