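# Preprocessing pipeline: normalization, bias correction, stripping,
# resampling, affine alignment, stacking and patch extraction.

test_that("z-score normalization matches the hand-evaluated population form", {
  ch <- array(0, dim = c(3, 1, 1)); ch[, 1, 1] <- c(1, 2, 3)
  msk <- array(1L, dim = c(3, 1, 1))
  z <- zscore_normalize(ch, msk)
  expect_equal(z$mu, 2)
  expect_equal(z$sigma, sqrt(2 / 3))
  expect_equal(as.numeric(z$normalized), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  # idempotence on standardized input
  z2 <- zscore_normalize(z$normalized, msk)
  expect_equal(z2$mu, 0, tolerance = 1e-12)
  expect_equal(z2$sigma, 1, tolerance = 1e-12)
  expect_equal(z2$normalized, z$normalized, tolerance = 1e-12)
  # out-of-mask voxels zeroed, in-mask moments exact
  set.seed(1)
  ch <- array(rnorm(4^3, 5, 2), dim = c(4, 4, 4))
  msk <- array(rbinom(4^3, 1, 0.7), dim = c(4, 4, 4))
  z <- zscore_normalize(ch, msk)
  expect_true(all(z$normalized[msk == 0] == 0))
  expect_equal(mean(z$normalized[msk == 1]), 0, tolerance = 1e-12)
  expect_equal(mean(z$normalized[msk == 1]^2), 1, tolerance = 1e-12)
  # zero-variance guard
  expect_error(zscore_normalize(array(3, dim = c(2, 2, 2)),
                                array(1L, dim = c(2, 2, 2))), "variance")
})

test_that("bias-field correction recovers flat fields and the generative field", {
  flat <- array(2, dim = c(8, 8, 8))
  msk <- array(1L, dim = c(8, 8, 8))
  bm <- correct_bias_field(flat, msk, smoothness_mm = 4)
  expect_equal(bm$b, array(1, dim = dim(flat)), tolerance = 1e-10)
  expect_equal(bm$t, flat, tolerance = 1e-10)
  expect_equal(max(abs(bm$eps)), 0, tolerance = 1e-12)

  a <- generate_anatomy(tiny_spec(grid = 16L), anatomy_seed = 8L)
  st <- domain_style(1L, bias_field_amplitude = 0.3, bias_field_smoothness = 6,
                     noise_sigma = 0)
  r <- render_domain(a, st, render_seed = 1L)
  bm <- correct_bias_field(r$channels$t1, r$brain_mask, smoothness_mm = 6,
                           spacing = r$spacing)
  msk <- r$brain_mask > 0
  expect_gt(cor(bm$b[msk], r$bias_field[msk]), 0.9)
  # reconstruction is exact: v = b * t
  expect_equal(r$channels$t1, bm$b * bm$t, tolerance = 1e-10)
  # correction reduces within-tissue dispersion (coefficient of variation)
  tiss <- msk & a$region_mask == 0
  cv <- function(x) sd(x) / mean(x)
  expect_lte(cv(bm$t[tiss]), cv(r$channels$t1[tiss]))
})

test_that("skull stripping is a masked identity and idempotent", {
  ds <- tiny_dataset(n = 1L)
  v <- ds$volumes[[1]]
  s1 <- skull_strip(v)
  expect_equal(s1$channels$t1, v$channels$t1 * v$brain_mask)
  expect_identical(skull_strip(s1)$channels, s1$channels)
  v1 <- v; v1$brain_mask <- array(1L, dim = dim(v$brain_mask))
  expect_identical(skull_strip(v1)$channels, v1$channels)
  v0 <- v; v0$brain_mask <- array(0L, dim = dim(v$brain_mask))
  expect_true(all(skull_strip(v0)$channels$flair == 0))
})

test_that("isotropic resampling follows the shape formula", {
  mk_vol <- function(shape, spacing, value = NULL) {
    arr <- if (is.null(value)) array(rnorm(prod(shape)), dim = shape)
           else array(value, dim = shape)
    damlm:::new_labeled_volume(
      list(t1 = arr, t1ce = arr, t2 = arr, flair = arr), spacing,
      array(1L, dim = shape), array(0L, dim = shape), 0L, 0L)
  }
  v <- mk_vol(c(20, 20, 10), c(1, 1, 2))
  out <- resample_isotropic(v, 1)
  expect_equal(dim(out$channels$t1), c(20L, 20L, 20L))
  expect_equal(out$spacing, c(1, 1, 1))
  # already isotropic: same shape, same values
  v2 <- mk_vol(c(10, 10, 10), c(1, 1, 1))
  out2 <- resample_isotropic(v2, 1)
  expect_equal(dim(out2$channels$t1), c(10L, 10L, 10L))
  expect_equal(out2$channels$t1, v2$channels$t1, tolerance = 1e-6)
  # constants stay constant
  v3 <- mk_vol(c(12, 12, 6), c(1, 1, 2), value = 3.5)
  out3 <- resample_isotropic(v3, 1)
  expect_equal(as.numeric(out3$channels$t1),
               rep(3.5, prod(dim(out3$channels$t1))), tolerance = 1e-10)
})

test_that("affine application is invertible up to interpolation error", {
  set.seed(2)
  shape <- c(14, 14, 14)
  arr <- damlm:::gauss_smooth3(array(rnorm(prod(shape)), shape), 1.5)
  v <- damlm:::new_labeled_volume(
    list(t1 = arr, t1ce = arr, t2 = arr, flair = arr), c(1, 1, 1),
    array(1L, dim = shape), array(0L, dim = shape), 0L, 0L)
  expect_equal(apply_affine_transform(v, diag(4))$channels$t1, arr,
               tolerance = 1e-10)
  # +3 then -3 voxel translation round-trip (compare away from the border)
  Tp <- diag(4); Tp[1, 4] <- 3
  Tm <- diag(4); Tm[1, 4] <- -3
  fwd <- apply_affine_transform(v, Tp)
  fwd$affine <- diag(4)   # reinterpret in its own frame
  back <- apply_affine_transform(fwd, Tm)
  core <- 5:10
  expect_lt(max(abs(back$channels$t1[core, core, core] -
                    arr[core, core, core])), 1e-5)
  expect_error(apply_affine_transform(v, matrix(0, 4, 4)), "singular")
})

test_that("sequence stacking fixes the channel order", {
  g <- function(k) array(k, dim = c(3, 3, 3))
  X <- stack_sequences(g(1), g(2), g(3), g(4))
  for (c in 1:4) expect_true(all(X[, , , c] == c))
  u <- damlm:::unstack_sequences(X)
  expect_equal(u$t1, g(1)); expect_equal(u$flair, g(4))
  expect_error(stack_sequences(g(1), g(2), g(3), array(0, dim = c(2, 2, 2))),
               "shapes differ")
})

test_that("patch lattices cover the volume with a flush final origin", {
  pg <- patch_grid(c(96, 96, 96), 96, 48)
  expect_equal(nrow(pg$origins), 1L)
  expect_equal(unname(pg$origins[1, ]), c(0, 0, 0))
  pg2 <- patch_grid(c(144, 144, 144), 96, 48)
  expect_equal(nrow(pg2$origins), 8L)
  # flush-to-end behaviour when the remainder is not a multiple of the stride
  pg3 <- patch_grid(c(20, 20, 20), 8, 5)
  expect_equal(sort(unique(pg3$origins[, 1])), c(0, 5, 10, 12))
  expect_error(patch_grid(c(4, 4, 4), 8, 4), "larger than volume")
})

test_that("patch extraction and overlap-averaged reassembly are exact inverses", {
  set.seed(3)
  X <- array(rnorm(20^3 * 4), dim = c(20, 20, 20, 4))
  patches <- extract_patches(X, 8, 5)
  rec <- reassemble_patches(patches, dim(X)[1:3])
  expect_equal(rec, X, tolerance = 1e-12)
  # coverage: every voxel visited at least once
  cnt <- array(0, dim = dim(X)[1:3])
  for (p in patches) {
    ix <- p$origin + 1
    cnt[ix[1]:(ix[1] + 7), ix[2]:(ix[2] + 7), ix[3]:(ix[3] + 7)] <-
      cnt[ix[1]:(ix[1] + 7), ix[2]:(ix[2] + 7), ix[3]:(ix[3] + 7)] + 1
  }
  expect_true(all(cnt >= 1))
})

test_that("the composed pipeline produces finite, mask-consistent tensors", {
  ds <- tiny_dataset(n = 2L)
  pp <- preprocess_volume(ds$volumes[[1]], bias_correct = TRUE)
  expect_true(all(is.finite(pp$X)))
  expect_equal(dim(pp$X), c(dim(ds$volumes[[1]]$channels$t1), 4L))
  expect_true(all(pp$X[cbind(which(pp$brain_mask == 0, arr.ind = TRUE), 1)] == 0))
})
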