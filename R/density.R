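# ---------------------------------------------------------------------------
# Real-space density volumes: container, phantoms, MRC/CCP4 I/O.
# ---------------------------------------------------------------------------

#' Real-space density volume
#'
#' A cubic voxel grid with a physical voxel size. The grid origin (the voxel
#' index of the physical center) defaults to the middle of the grid.
#'
#' @param grid real cubic 3D array (density, arbitrary units).
#' @param voxel_size voxel edge length in nm (> 0).
#' @param origin grid index (1-based) of the physical center.
#' @return a `density_volume` object.
#' @export
density_volume <- function(grid, voxel_size,
                           origin = rep((dim(grid)[1] + 1) / 2, 3)) {
  d <- dim(grid)
  if (length(d) != 3L || d[1] != d[2] || d[1] != d[3])
    stop("density grid must be cubic")
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be positive")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_volume")
}

#' Seeded phantom density models
#'
#' Deterministic synthetic particles used throughout testing and the worked
#' examples: `"sphere"` (uniform ball), `"twolobe"` (two offset Gaussian
#' lobes of unequal weight), `"blobs"` (a seeded sum of random Gaussian
#' lumps inside a support sphere). All phantoms are non-negative and
#' compactly supported within half the box edge.
#'
#' @param kind one of `"blobs"`, `"sphere"`, `"twolobe"`.
#' @param size grid edge length in voxels.
#' @param voxel_size voxel size in nm.
#' @param seed integer seed (used by `"blobs"`).
#' @param n_blobs number of Gaussian lumps for `"blobs"`.
#' @return a [density_volume()].
#' @export
make_phantom <- function(kind = c("blobs", "sphere", "twolobe"),
                         size = 48L, voxel_size = 1.0, seed = 1L,
                         n_blobs = 6L) {
  kind <- match.arg(kind)
  n <- as.integer(size)
  ax <- seq_len(n) - (n + 1) / 2               # voxel offsets from center
  support_r <- n / 4                            # support within half the box
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  g <- array(0, c(n, n, n))
  if (kind == "sphere") {
    g[r2 <= support_r^2] <- 1
  } else if (kind == "twolobe") {
    s1 <- support_r / 2.6; s2 <- support_r / 3.4; off <- support_r / 2
    d1 <- outer(outer((ax + off)^2, ax^2, `+`), ax^2, `+`)
    d2 <- outer(outer((ax - off)^2, (ax - off / 2)^2, `+`), ax^2, `+`)
    g <- exp(-d1 / (2 * s1^2)) + 0.6 * exp(-d2 / (2 * s2^2))
    g[r2 > support_r^2] <- 0
  } else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(as.integer(seed) %% .Machine$integer.max)
    for (b in seq_len(n_blobs)) {
      # centers inside 0.6 * support radius, widths a fraction of support
      ctr <- stats::runif(3, -0.6, 0.6) * support_r
      sig <- stats::runif(1, 0.12, 0.3) * support_r
      amp <- stats::runif(1, 0.4, 1)
      db <- outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, `+`),
                  (ax - ctr[3])^2, `+`)
      g <- g + amp * exp(-db / (2 * sig^2))
    }
    g[r2 > support_r^2] <- 0
  }
  density_volume(g, voxel_size)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Read an MRC/CCP4 density map
#'
#' Minimal reader for mode-2 (32-bit float) MRC2014/CCP4 maps; voxel size is
#' taken from the cell dimensions in the header. Axis-permuted maps
#' (MAPC/MAPR/MAPS other than 1,2,3) are rearranged to x,y,z order.
#'
#' @param path file path.
#' @return a [density_volume()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024L)
  int_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)],
                                "integer", 1L, 4L, endian = "little")
  flt_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)],
                                "numeric", 1L, 4L, endian = "little")
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  if (mode != 2L) stop("only mode-2 (float32) MRC maps are supported, got mode ", mode)
  mx <- int_at(8); cella_x <- flt_at(11)
  mapc <- int_at(17); mapr <- int_at(18); maps <- int_at(19)
  nsymbt <- int_at(24)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  dat <- readBin(con, "numeric", nx * ny * nz, 4L, endian = "little")
  arr <- array(dat, c(nx, ny, nz))
  perm <- order(c(mapc, mapr, maps))
  if (!all(perm == 1:3)) arr <- aperm(arr, perm)
  voxel <- if (mx > 0 && cella_x > 0) cella_x / mx else 1
  density_volume(arr, voxel)
}

#' Write an MRC/CCP4 density map (mode 2, float32)
#'
#' @param model a [density_volume()].
#' @param path output file path.
#' @export
write_mrc <- function(model, path) {
  n <- dim(model$grid)[1]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  wi(c(n, n, n)); wi(2L); wi(c(0L, 0L, 0L)); wi(c(n, n, n))
  wf(rep(n * model$voxel_size, 3)); wf(c(90, 90, 90))
  wi(c(1L, 2L, 3L))
  wf(c(min(model$grid), max(model$grid), mean(model$grid)))
  wi(c(1L, 0L))
  writeBin(raw(4 * (53 - 25)), con)            # words 25..52 zero
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(model$grid)); wi(0L)
  writeBin(raw(1024 - 4 * 56), con)           # words 57..256 (labels) zero
  wf(as.numeric(model$grid))
  invisible(path)
}
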