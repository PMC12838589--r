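# MRI preprocessing pipeline: z-score normalization within the brain mask,
# log-domain bias-field correction, skull stripping, isotropic resampling,
# affine alignment, channel stacking and sliding-window patch extraction.

#' Z-score normalization within a mask
#'
#' Standardizes in-mask intensities to zero mean and unit variance using the
#' population convention (denominator n); out-of-mask voxels are set to 0.
#'
#' @param channel 3-D intensity array.
#' @param mask Binary 3-D array of the same shape.
#' @return List with `normalized`, `mu`, `sigma`.
#' @export
zscore_normalize <- function(channel, mask) {
  stopifnot(identical(dim(channel), dim(mask)))
  idx <- mask > 0
  n <- sum(idx)
  if (n < 2L) stop("mask must contain at least 2 voxels")
  v <- channel[idx]
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma < .Machine$double.eps)
    stop("zero in-mask intensity variance; cannot z-score normalize")
  out <- array(0, dim = dim(channel))
  out[idx] <- (v - mu) / sigma
  list(normalized = out, mu = mu, sigma = sigma)
}

#' Bias-field correction by log-domain Gaussian smoothing
#'
#' Estimates the smooth multiplicative field `b` as the exponential of the
#' Gaussian-smoothed log-intensity deviation within the mask (an N4-style
#' simplification), extended smoothly outside the mask by normalized
#' convolution. The recovered signal is `t = v / b`, so the multiplicative
#' model `v = b * t` reconstructs the input exactly and the residual term is
#' identically zero under this estimator.
#'
#' @param channel 3-D intensity array (in-mask values must be positive after
#'   an optional recorded shift).
#' @param mask Binary 3-D array.
#' @param smoothness_mm Field correlation length in mm.
#' @param spacing Voxel spacing in mm (scalar or length 3).
#' @return List with `b` (field, 1 outside reach), `t` (recovered signal),
#'   `eps` (residual, all zeros), `shift` (intensity shift used for the log).
#' @export
correct_bias_field <- function(channel, mask, smoothness_mm = 6, spacing = 1) {
  stopifnot(identical(dim(channel), dim(mask)))
  idx <- mask > 0
  if (!any(idx)) stop("empty mask")
  shift <- 0
  mn <- min(channel[idx])
  if (mn <= 0) {
    shift <- 1e-3 * max(abs(channel[idx])) - mn
    if (shift <= 0) shift <- 1
  }
  v <- channel + shift
  if (any(v[idx] <= 0)) stop("nonpositive in-mask intensities after shift")
  sig_vox <- smoothness_mm / mean(spacing)
  lv <- array(0, dim = dim(channel))
  lv[idx] <- log(v[idx])
  w <- array(as.numeric(idx), dim = dim(mask))
  num <- gauss_smooth3(lv * w, sig_vox)
  den <- gauss_smooth3(w, sig_vox)
  sm <- ifelse(den > 1e-8, num / pmax(den, 1e-8), 0)
  dev <- sm - mean(sm[idx])
  dev[den <= 1e-8] <- 0
  b <- exp(dev)
  t <- channel / b
  list(b = b, t = t, eps = channel - b * t, shift = shift)
}

#' Skull stripping
#'
#' Multiplies every sequence channel elementwise by the binary brain mask.
#'
#' @param vol A `labeled_volume`.
#' @return The volume with masked channels (mask unchanged).
#' @export
skull_strip <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  gs <- dim(vol$channels[[1]])
  if (!identical(dim(vol$brain_mask), gs)) stop("mask/channel shape mismatch")
  vol$channels <- lapply(vol$channels, function(ch) ch * vol$brain_mask)
  vol
}

#' Isotropic resampling
#'
#' Resamples all channels to isotropic spacing `delta_mm` (trilinear; masks
#' nearest-neighbour). Output shape per axis is
#' `round(in_shape * in_spacing / delta_mm)`; the affine is scaled to match.
#'
#' @param vol A `labeled_volume`.
#' @param delta_mm Target isotropic spacing (> 0).
#' @return Resampled `labeled_volume`.
#' @export
resample_isotropic <- function(vol, delta_mm) {
  stopifnot(inherits(vol, "labeled_volume"), delta_mm > 0)
  ins <- dim(vol$channels[[1]])
  sp <- vol$spacing
  outs <- pmax(1L, as.integer(round(ins * sp / delta_mm)))
  scale <- delta_mm / sp
  co <- voxel_grid_coords(outs)
  # clamp to the grid (edge extension) so shape round-off cannot sample
  # outside the volume
  src <- cbind(pmin(co[, 1] * scale[1], ins[1] - 1),
               pmin(co[, 2] * scale[2], ins[2] - 1),
               pmin(co[, 3] * scale[3], ins[3] - 1))
  vol$channels <- lapply(vol$channels, function(ch)
    array(trilinear_sample(ch, src), dim = outs))
  vol$brain_mask <- array(as.integer(nearest_sample(vol$brain_mask, src)), dim = outs)
  vol$region_mask <- array(as.integer(nearest_sample(vol$region_mask, src)), dim = outs)
  vol$spacing <- rep(delta_mm, 3)
  vol$affine <- vol$affine %*% diag(c(scale, 1))
  vol
}

#' Resample a volume into a target affine frame
#'
#' Channels are pulled back through `solve(A_current) %*% A_target`
#' (trilinear; masks nearest-neighbour); the output grid keeps the input
#' shape and adopts `A_target` as its affine.
#'
#' @param vol A `labeled_volume` (its `affine` maps voxel indices to mm).
#' @param A_target Invertible 4 x 4 voxel-to-world matrix of the target frame.
#' @return Resampled `labeled_volume`.
#' @export
apply_affine_transform <- function(vol, A_target) {
  stopifnot(inherits(vol, "labeled_volume"), all(dim(A_target) == c(4, 4)))
  if (abs(det(A_target)) < 1e-12) stop("singular target affine")
  M <- solve(vol$affine) %*% A_target
  gs <- dim(vol$channels[[1]])
  co <- cbind(voxel_grid_coords(gs), 1)
  src <- co %*% t(M)
  src <- src[, 1:3, drop = FALSE]
  vol$channels <- lapply(vol$channels, function(ch)
    array(trilinear_sample(ch, src), dim = gs))
  vol$brain_mask <- array(as.integer(nearest_sample(vol$brain_mask, src)), dim = gs)
  vol$region_mask <- array(as.integer(nearest_sample(vol$region_mask, src)), dim = gs)
  vol$affine <- A_target
  vol
}

#' Stack the four MRI sequences channel-wise
#'
#' Channel order is fixed as T1, T1ce, T2, FLAIR.
#'
#' @param t1,t1ce,t2,flair 3-D arrays of identical shape.
#' @return 4-D array (x, y, z, channel).
#' @export
stack_sequences <- function(t1, t1ce, t2, flair) {
  d <- dim(t1)
  if (!identical(d, dim(t1ce)) || !identical(d, dim(t2)) || !identical(d, dim(flair)))
    stop("sequence shapes differ")
  array(c(t1, t1ce, t2, flair), dim = c(d, 4L))
}

unstack_sequences <- function(X) {
  stats::setNames(lapply(1:4, function(c) array(X[, , , c], dim = dim(X)[1:3])),
                  SEQ_NAMES)
}

#' Sliding-window patch origin lattice
#'
#' Origins per axis are `0, stride, 2*stride, ...` plus a final origin flush
#' to the end when the remainder is not a multiple of the stride, so patch
#' footprints cover the whole grid.
#'
#' @param vol_shape Volume shape (length 3).
#' @param patch_shape Patch shape (length 3, each <= volume shape).
#' @param stride Positive integer stride.
#' @return Object of class `patch_grid` with an `origins` matrix (0-based).
#' @export
patch_grid <- function(vol_shape, patch_shape, stride) {
  vol_shape <- as.integer(vol_shape); patch_shape <- as.integer(rep(patch_shape, length.out = 3))
  stride <- as.integer(stride)
  stopifnot(stride > 0)
  if (any(patch_shape > vol_shape)) stop("patch larger than volume")
  ax <- lapply(1:3, function(a) {
    last <- vol_shape[a] - patch_shape[a]
    og <- seq(0L, last, by = stride)
    if (og[length(og)] != last) og <- c(og, last)
    og
  })
  origins <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  structure(list(patch_shape = patch_shape, stride = stride,
                 origins = origins, vol_shape = vol_shape),
            class = "patch_grid")
}

#' Extract sliding-window patches from a stacked 4-channel tensor
#'
#' @param X 4-D array (x, y, z, channel).
#' @param patch_shape Patch shape (scalar or length 3).
#' @param stride Positive integer stride.
#' @return List of patches, each a list with `data` (4-D array) and `origin`
#'   (0-based offsets); the patch grid rides along as attribute `grid`.
#' @export
extract_patches <- function(X, patch_shape, stride) {
  stopifnot(length(dim(X)) == 4L)
  pg <- patch_grid(dim(X)[1:3], patch_shape, stride)
  ps <- pg$patch_shape
  out <- lapply(seq_len(nrow(pg$origins)), function(i) {
    o <- pg$origins[i, ]
    list(data = X[o[1] + seq_len(ps[1]), o[2] + seq_len(ps[2]),
                  o[3] + seq_len(ps[3]), , drop = FALSE],
         origin = o)
  })
  attr(out, "grid") <- pg
  out
}

#' Reassemble patches into a volume, averaging overlaps
#'
#' @param patches Output of [extract_patches()].
#' @param vol_shape Original volume shape (length 3).
#' @return 4-D array.
#' @export
reassemble_patches <- function(patches, vol_shape) {
  nc <- dim(patches[[1]]$data)[4]
  acc <- array(0, dim = c(vol_shape, nc))
  cnt <- array(0, dim = vol_shape)
  ps <- dim(patches[[1]]$data)[1:3]
  for (p in patches) {
    ix <- p$origin[1] + seq_len(ps[1]); iy <- p$origin[2] + seq_len(ps[2])
    iz <- p$origin[3] + seq_len(ps[3])
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] + p$data
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  sweep(acc, 1:3, cnt, "/")
}

#' Standard preprocessing of a labeled volume
#'
#' Applies the pipeline used by the trainer: per-sequence z-score
#' normalization within the brain mask, optional bias-field correction,
#' skull stripping and channel stacking.
#'
#' @param vol A `labeled_volume`.
#' @param bias_correct Estimate and divide out a bias field first.
#' @param smoothness_mm Bias-field smoothness when `bias_correct = TRUE`.
#' @return List with `X` (4-D stacked tensor), `norm_params`, and the input
#'   volume's masks and labels.
#' @export
preprocess_volume <- function(vol, bias_correct = FALSE, smoothness_mm = 6) {
  stopifnot(inherits(vol, "labeled_volume"))
  mask <- vol$brain_mask
  norm_params <- list()
  chans <- vol$channels
  for (s in names(chans)) {
    ch <- chans[[s]]
    if (bias_correct) ch <- correct_bias_field(ch, mask, smoothness_mm, vol$spacing)$t
    zn <- zscore_normalize(ch, mask)
    chans[[s]] <- zn$normalized
    norm_params[[s]] <- c(mu = zn$mu, sigma = zn$sigma)
  }
  X <- stack_sequences(chans$t1, chans$t1ce, chans$t2, chans$flair)
  list(X = X, norm_params = norm_params, brain_mask = mask,
       region_mask = vol$region_mask, class_label = vol$class_label,
       domain = vol$domain, anatomy_seed = vol$anatomy_seed)
}
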