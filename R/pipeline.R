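# ---------------------------------------------------------------------------
# Configuration, end-to-end pipeline, artifact I/O with provenance.
# ---------------------------------------------------------------------------

#' Default pipeline configuration
#' @keywords internal
default_config <- function() {
  list(
    # phantom / model
    phantom_kind = "blobs", phantom_size = 48L, voxel_size_nm = 2.5,
    phantom_seed = 3L,
    # geometry (pattern-edge wavenumber 0.2 1/nm at 1 nm wavelength)
    wavelength_nm = 1.0, distance_mm = 100, pixel_size_mm = 0.48,
    n_pixels = 80L, flat_ewald = TRUE,
    # simulation
    n_patterns = 500L, flux = 1e13, flux_scale = 2e-10,
    alpha = 3e-4, beta = 1e-4, poisson = TRUE, detector_noise = TRUE,
    background_instrument_fraction = 0.0, compton_scale = 0.0,
    mask = "none", seed = 1L,
    # correlation
    n_k = 12L, n_phi = 60L, interp = "nearest", k_min_frac = 0.15,
    k_max_frac = 0.95, min_psi_bins = 2L,
    # fit / reconstruction
    l_max = 12L, top_n = 9L, n_trials = 4L, maxiter = 100L,
    # phasing
    phase_grid = 48L, phase_iterations = 300L, phase_runs = 4L
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills defaults, and rejects unknown keys and invalid
#' values (odd `l_max` is disallowed: only even subspaces exist under
#' Friedel symmetry). An empty or missing-body file yields all defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied after the file (flags win).
#' @return a validated named list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  if (cfg$l_max %% 2L != 0L)
    stop("l_max must be even: odd-degree subspaces vanish by Friedel symmetry")
  if (cfg$n_phi %% 2L != 0L) stop("n_phi must be even")
  for (key in c("voxel_size_nm", "wavelength_nm", "distance_mm",
                "pixel_size_mm", "flux"))
    if (cfg[[key]] <= 0) stop(key, " must be positive")
  if (cfg$alpha < 0 || cfg$beta < 0) stop("alpha and beta must be >= 0")
  cfg
}

#' Run the reconstruction pipeline end to end
#'
#' Chains the stages simulate -> correlate -> correct -> fit -> reconstruct
#' -> phase -> validate on a phantom model, in memory, with every stage
#' seeded from the config. Intended both as the scripted interface and as
#' the engine behind the command-line wrapper.
#'
#' @param config a list from [load_config()].
#' @param stages character vector of stages to run (prefix of the chain).
#' @param model optional [density_volume()] overriding the phantom.
#' @param artifacts optional artifact list from a previous partial run.
#' @param verbose print stage progress.
#' @return a named list of artifacts (`model`, `stack`, `corr`,
#'   `corrected`, `matrices`, `recon`, `average`, `phased`, `validation`).
#' @export
run_pipeline <- function(config = load_config(),
                         stages = c("simulate", "correlate", "correct",
                                    "fit", "reconstruct", "phase",
                                    "validate"),
                         model = NULL, artifacts = list(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    v <- force(expr)
    say("[%s] %.1fs", name, as.numeric(difftime(Sys.time(), t0, units = "secs")))
    v
  }
  cfg <- config
  if (is.null(model)) model <- artifacts$model
  if (is.null(model))
    model <- make_phantom(cfg$phantom_kind, cfg$phantom_size,
                          cfg$voxel_size_nm, seed = cfg$phantom_seed)
  artifacts$model <- model
  geom <- detector_geometry(cfg$wavelength_nm, cfg$distance_mm,
                            cfg$pixel_size_mm, cfg$n_pixels)
  kmap <- detector_kmap(geom, cfg$flat_ewald)
  k_edge <- max(kmap$k[, round(geom$beam_center[2])])
  k_grid <- seq(cfg$k_min_frac, cfg$k_max_frac,
                length.out = cfg$n_k) * k_edge
  artifacts$k_grid <- k_grid

  if ("simulate" %in% stages) {
    noise <- if (cfg$poisson || cfg$detector_noise)
      noise_params(cfg$flux, cfg$alpha, cfg$beta, cfg$poisson,
                   cfg$detector_noise) else NULL
    bg <- NULL
    if (cfg$background_instrument_fraction > 0 || cfg$compton_scale > 0) {
      instf <- if (cfg$background_instrument_fraction > 0)
        instrument_fraction_profile(model, geom, cfg$flux, cfg$flux_scale,
                                    cfg$background_instrument_fraction,
                                    cfg$flat_ewald)
      else function(k) rep(0, length(k))
      comf <- if (cfg$compton_scale > 0)
        function(k) rep(cfg$compton_scale, length(k))
      else function(k) rep(0, length(k))
      bg <- background_model(comf, instf)
    }
    msk <- if (identical(cfg$mask, "corners")) corner_mask(cfg$n_pixels) else NULL
    artifacts$stack <- t_stage("simulate",
      generate_dataset(model, cfg$n_patterns, geom, noise = noise,
                       background = bg, mask = msk, seed = cfg$seed,
                       flux_scale = cfg$flux_scale, flat = cfg$flat_ewald))
  }
  if ("correlate" %in% stages) {
    if (is.null(artifacts$stack)) stop("correlate needs a pattern stack; run 'simulate' first")
    artifacts$corr <- t_stage("correlate",
      finalize(accumulate(artifacts$stack, k_grid, cfg$n_phi,
                          method = cfg$interp)))
  }
  if ("correct" %in% stages) {
    if (is.null(artifacts$corr)) stop("correct needs correlations; run 'correlate' first")
    cc <- eliminate_noise(artifacts$corr,
                          alpha = if (cfg$detector_noise) cfg$alpha else 0,
                          beta = if (cfg$detector_noise) cfg$beta else 0)
    bgobj <- artifacts$stack$truth$background
    if (!is.null(bgobj)) cc <- subtract_background(cc, background_profile(bgobj, k_grid))
    min_psi <- cfg$min_psi_bins * diff(cc$psi_grid[1:2])
    artifacts$corrected <- t_stage("correct",
                                   exclude_small_psi(cc, min_psi, cfg$l_max))
  }
  if ("fit" %in% stages) {
    src <- artifacts$corrected %||% artifacts$corr
    if (is.null(src)) stop("fit needs correlations; run 'correlate' first")
    artifacts$matrices <- t_stage("fit", fit_legendre(src, cfg$l_max))
  }
  if ("reconstruct" %in% stages) {
    if (is.null(artifacts$matrices)) stop("reconstruct needs fitted matrices; run 'fit' first")
    problem <- recon_setup(artifacts$matrices, cfg$top_n)
    artifacts$recon <- t_stage("reconstruct",
      progressive_optimize(problem, n_trials = cfg$n_trials,
                           seed = cfg$seed, maxiter = cfg$maxiter))
    artifacts$average <- t_stage("average",
                                 average_trials(artifacts$recon,
                                                seed = cfg$seed))
  }
  if ("phase" %in% stages) {
    if (is.null(artifacts$average)) stop("phase needs a reconstruction; run 'reconstruct' first")
    emb <- embed_intensity(artifacts$average$coeffs, cfg$phase_grid)
    artifacts$phased <- t_stage("phase",
      phase_retrieve(emb$intensity, emb$voxel_size,
                     n_iterations = cfg$phase_iterations,
                     n_runs = cfg$phase_runs, seed = cfg$seed))
  }
  if ("validate" %in% stages) {
    if (is.null(artifacts$phased)) stop("validate needs a phased density; run 'phase' first")
    artifacts$validation <- t_stage("validate",
      validate_against_truth(artifacts$average$coeffs, model,
                             artifacts$phased, k_grid))
  }
  artifacts$config <- cfg
  artifacts
}

#' Validate a reconstruction against the ground-truth model
#'
#' Rotationally aligns the reconstructed intensity to the truth intensity
#' (coarse + refined search including the mirror flip), re-phases on the
#' aligned intensity, translation/inversion-aligns the density to a
#' resampled truth density, and reads out the FSC.
#'
#' @param coeffs reconstructed [sh_coefficients()].
#' @param model ground-truth [density_volume()].
#' @param phased optional [phase_retrieve()] output for the unaligned
#'   intensity (its grid settings are reused).
#' @param k_grid radial shells of the reconstruction.
#' @param n_coarse coarse rotations for the intensity alignment.
#' @param seed seed for alignment and re-phasing.
#' @return list: `fsc` (an `fsc_curve`), `aligned_density`,
#'   `truth_density` (band-matched truth on the same grid),
#'   `intensity_correlation` (post-alignment), `resolution_nm`.
#' @export
validate_against_truth <- function(coeffs, model, phased = NULL, k_grid,
                                   n_coarse = 240L, seed = 1L) {
  l_max <- coeffs$l_max
  grid <- sq_grid(l_max)
  truth_vol <- density_to_intensity(model, k_grid, grid)
  truth_coeffs <- sh_analyze(truth_vol, l_max)
  # align reconstruction onto the truth (rotation + mirror)
  gd <- grid_directions(grid)
  nth <- grid$n_theta; nph <- grid$n_phi
  theta_i <- rep(seq_len(nth), nph)
  wts <- grid$w_theta[theta_i] * (2 * pi / nph)
  ref_vals <- do.call(cbind, lapply(seq_along(k_grid), function(ik)
    as.vector(matrix(truth_vol$values[ik, , ], nth, nph))))
  score <- function(vals) sum(wts * ref_vals * vals) /
    sqrt(sum(wts * ref_vals^2) * sum(wts * vals^2))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  cand <- rbind(c(1, 0, 0, 0), random_orientation(n_coarse - 1L))
  best <- list(s = -Inf)
  for (mir in c(FALSE, TRUE)) for (ci in seq_len(nrow(cand))) {
    R <- quat_to_matrix(cand[ci, ])
    s <- score(eval_at_rotation(coeffs, gd, R, mir))
    if (s > best$s) best <- list(s = s, R = R, mirror = mir)
  }
  obj <- function(w) -score(eval_at_rotation(coeffs, gd,
                                             best$R %*% rotvec_to_matrix(w),
                                             best$mirror))
  op <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                     control = list(maxit = 150, reltol = 1e-8))
  Rb <- best$R %*% rotvec_to_matrix(op$par)
  aligned_vals <- eval_at_rotation(coeffs, gd, Rb, best$mirror)
  arr <- array(0, c(length(k_grid), nth, nph))
  for (ik in seq_along(k_grid)) arr[ik, , ] <- matrix(aligned_vals[, ik], nth, nph)
  aligned_coeffs <- sh_analyze(intensity_volume(arr, k_grid, grid), l_max)
  # phase the aligned intensity
  gsize <- if (!is.null(phased)) dim(phased$density$grid)[1] else 48L
  emb <- embed_intensity(aligned_coeffs, gsize)
  ph <- phase_retrieve(emb$intensity, emb$voxel_size,
                       n_iterations = 300L, n_runs = 4L, seed = seed)
  # band-matched truth on the same Cartesian grid
  truth_emb <- embed_intensity(truth_coeffs, gsize, k_step = emb$k_step)
  truth_dens <- phase_retrieve(truth_emb$intensity, truth_emb$voxel_size,
                               n_iterations = 300L, n_runs = 2L, seed = seed + 1L)
  aligned <- align_density(ph$density, truth_dens$density)
  fc <- fsc(aligned, truth_dens$density)
  list(fsc = fc, aligned_density = aligned,
       truth_density = truth_dens$density,
       intensity_correlation = -op$value,
       resolution_nm = fc$resolution)
}

#' Save / load pipeline artifacts with provenance
#'
#' Artifacts are stored as RDS with the resolved configuration, package
#' version and a content hash of the inputs attached.
#'
#' @param object artifact to save.
#' @param path file path.
#' @param config resolved configuration to embed.
#' @return `path`, invisibly.
#' @export
save_artifact <- function(object, path, config = NULL) {
  attr(object, "provenance") <- list(
    package = "kamcorr",
    version = as.character(utils::packageVersion("kamcorr")),
    config = config, timestamp = format(Sys.time(), tz = "UTC"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_artifact
#' @export
load_artifact <- function(path) readRDS(path)
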