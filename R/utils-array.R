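# Shared low-level voxel-grid utilities: separable Gaussian smoothing and
# vectorized trilinear / nearest-neighbour sampling. All grids are plain 3-D
# arrays indexed (x, y, z); voxel coordinates are 0-based throughout.

#' Separable 3D Gaussian smoothing
#'
#' Smooths a 3-D array with an isotropic (or per-axis) Gaussian kernel using
#' three 1-D passes. Boundaries are handled by kernel renormalization
#' (zero-padded convolution divided by the convolved window weight), so
#' constant inputs are reproduced exactly up to floating error.
#'
#' @param x 3-D numeric array.
#' @param sigma Gaussian standard deviation in voxels; scalar or length-3.
#' @return Smoothed array of the same shape.
#' @keywords internal
gauss_smooth3 <- function(x, sigma) {
  stopifnot(length(dim(x)) == 3L)
  sigma <- rep(sigma, length.out = 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    x <- .smooth_axis(x, k, ax)
  }
  x
}

# 1-D renormalized convolution along axis `ax` of a 3-D array.
.smooth_axis <- function(x, k, ax) {
  d <- dim(x)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  n <- dp[1]
  m <- matrix(xp, nrow = n)
  r <- (length(k) - 1L) %/% 2L
  acc <- matrix(0, n, ncol(m))
  wgt <- numeric(n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    acc[ok, ] <- acc[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    wgt[ok] <- wgt[ok] + k[j]
  }
  acc <- acc / wgt
  dim(acc) <- dp
  aperm(acc, order(perm))
}

#' Trilinear sampling of a 3-D array at fractional voxel coordinates
#'
#' @param arr 3-D array.
#' @param coords n x 3 matrix of 0-based voxel coordinates.
#' @param outside Fill value for samples outside the grid.
#' @return Numeric vector of length n.
#' @keywords internal
trilinear_sample <- function(arr, coords, outside = 0) {
  d <- dim(arr)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- numeric(nrow(coords))
  gv <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 & iz >= 0 & iz <= d[3] - 1
    v <- rep(outside, length(ix))
    idx <- (ix[ok] + 1) + iy[ok] * d[1] + iz[ok] * d[1] * d[2]
    v[ok] <- arr[idx]
    v
  }
  out <- gv(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    gv(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    gv(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    gv(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    gv(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    gv(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    gv(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    gv(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out
}

#' Nearest-neighbour sampling of a 3-D array (for label grids)
#' @inheritParams trilinear_sample
#' @keywords internal
nearest_sample <- function(arr, coords, outside = 0) {
  d <- dim(arr)
  ix <- round(coords[, 1]); iy <- round(coords[, 2]); iz <- round(coords[, 3])
  ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 & iz >= 0 & iz <= d[3] - 1
  v <- rep(outside, nrow(coords))
  idx <- (ix[ok] + 1) + iy[ok] * d[1] + iz[ok] * d[1] * d[2]
  v[ok] <- arr[idx]
  v
}

# 0-based voxel-center coordinate grid for a shape, as an n x 3 matrix with x
# fastest (matching R's array linearization).
voxel_grid_coords <- function(shape) {
  cbind(
    rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]),
    rep(rep(seq_len(shape[2]) - 1, each = shape[1]), times = shape[3]),
    rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2])
  )
}

# Smooth standardized white-noise field (unit in-grid sd) used for bias
# fields and elastic displacement components. Deterministic under the
# caller's RNG state.
smooth_noise_field <- function(shape, sigma_vox) {
  f <- array(stats::rnorm(prod(shape)), dim = shape)
  f <- gauss_smooth3(f, sigma_vox)
  s <- stats::sd(f)
  if (s < .Machine$double.eps) {
    array(0, dim = shape)
  } else {
    (f - mean(f)) / s
  }
}

# Deterministic 32-bit seed derived from a base seed and stream offsets.
derive_seed <- function(...) {
  parts <- c(...)
  h <- 0
  for (p in parts) h <- (h * 69069 + as.numeric(p) + 1) %% 2147483629
  as.integer(h)
}
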