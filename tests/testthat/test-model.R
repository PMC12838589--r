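# Encoder, heads and their contracts.

test_that("residual blocks with zero kernels are identities at fixed resolution", {
  cfg <- encoder_config(channels = 4L, conv_depth = 2L, transformer_depth = 1L,
                        in_channels = 4L, strided_blocks = integer(0),
                        seg_head = FALSE)
  W <- init_weights(cfg, seed = 1L)
  for (i in 1:2) {
    W[[sprintf("stem.b%d.w3", i)]][] <- 0
    W[[sprintf("stem.b%d.w5", i)]][] <- 0
  }
  p <- rand_patch(grid = 6L, C = 4L)
  out <- conv_stem_forward(p, cfg, W)
  expect_equal(out$features, p, tolerance = 1e-12)
})

test_that("strided stems downsample by 2 per declared block", {
  cfg <- encoder_config(channels = 8L, conv_depth = 2L, transformer_depth = 1L,
                        seg_head = FALSE)   # block 2 strided by default
  W <- init_weights(cfg, seed = 2L)
  out <- conv_stem_forward(rand_patch(grid = 8L), cfg, W)
  expect_equal(out$grid, c(4L, 4L, 4L))
  expect_equal(dim(out$features), c(4L, 4L, 4L, 8L))
})

test_that("channel attention is a bounded sigmoid gate", {
  set.seed(3)
  F0 <- array(rnorm(4^3 * 6), dim = c(4, 4, 4, 6))
  # zero weights: every gate is exactly 1/2
  ca0 <- channel_attention(F0, matrix(0, 6, 3), matrix(0, 3, 6))
  expect_equal(ca0$s, rep(0.5, 6))
  expect_equal(ca0$refined, 0.5 * F0, tolerance = 1e-12)
  # gates strictly inside (0, 1) for any finite weights
  ca <- channel_attention(F0, matrix(rnorm(18), 6, 3), matrix(rnorm(18), 3, 6))
  expect_true(all(ca$s > 0 & ca$s < 1))
  # pooling linearity: doubling the features doubles the pooled descriptor
  m1 <- apply(F0, 4, mean); m2 <- apply(2 * F0, 4, mean)
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
})

test_that("tokenization adds positions that distinguish grid axes", {
  cfg <- encoder_config(channels = 9L, conv_depth = 1L, transformer_depth = 1L,
                        seg_head = FALSE)
  F0 <- array(rnorm(2^3 * 9), dim = c(2, 2, 2, 9))
  tk <- tokenize(F0, cfg)
  expect_equal(dim(tk$tokens), c(8L, 9L))
  # round trip with positions removed
  expect_equal(detokenize(tk$tokens - tk$P, tk$grid), F0, tolerance = 1e-12)
  # all 8 grid positions get distinct encodings
  expect_equal(nrow(unique(round(tk$P, 10))), 8L)
  # learned variant starts at zero
  cfgl <- encoder_config(channels = 9L, conv_depth = 1L, transformer_depth = 1L,
                         positional_encoding = "learned", seg_head = FALSE)
  tkl <- tokenize(F0, cfgl)
  expect_true(all(tkl$P == 0))
})

test_that("a transformer layer is token-permutation equivariant", {
  cfg <- encoder_config(channels = 8L, conv_depth = 1L, transformer_depth = 1L,
                        seg_head = FALSE)
  W <- init_weights(cfg, seed = 4L)
  set.seed(5)
  Z <- matrix(rnorm(12 * 8), 12, 8)
  out <- transformer_layer(Z, W, cfg, layer = 1L)
  perm <- sample(12)
  out_p <- transformer_layer(Z[perm, ], W, cfg, layer = 1L)
  expect_equal(out_p, out[perm, ], tolerance = 1e-10)
  # single token: attention over one item is that item's value projection
  z1 <- matrix(rnorm(8), 1, 8)
  zn <- damlm:::cpp_attention_fwd(z1, z1, z1, 1L, sqrt(8))
  expect_equal(zn$out, z1, tolerance = 1e-12)
  expect_equal(as.numeric(zn$P), 1)
})

test_that("encode pools tokens consistently across backbone modes", {
  p <- rand_patch(grid = 8L)
  for (mode in c("hybrid", "cnn_only", "transformer_only")) {
    cfg <- encoder_config(channels = 8L, conv_depth = 2L, transformer_depth = 1L,
                          backbone_mode = mode, seg_head = FALSE)
    W <- init_weights(cfg, seed = 6L)
    enc <- encode(p, cfg, W)
    expect_length(enc$g, 8L)
    expect_equal(enc$g, colMeans(enc$tokens), tolerance = 1e-12)
  }
  # hybrid with no transformer layers equals cnn_only
  cfg_h <- encoder_config(channels = 8L, conv_depth = 2L, transformer_depth = 0L,
                          seg_head = FALSE)
  cfg_c <- encoder_config(channels = 8L, conv_depth = 2L, transformer_depth = 1L,
                          backbone_mode = "cnn_only", seg_head = FALSE)
  Wh <- init_weights(cfg_h, seed = 7L)
  g_h <- encode(p, cfg_h, Wh)$g
  Wc <- init_weights(cfg_c, seed = 7L)
  for (nm in names(Wh)) Wc[[nm]] <- Wh[[nm]]
  g_c <- encode(p, cfg_c, Wc)$g
  expect_equal(g_h, g_c, tolerance = 1e-12)
  # constant patch + zero stem kernels in cnn_only: all tokens equal, g = token
  cfg0 <- encoder_config(channels = 4L, conv_depth = 1L, transformer_depth = 1L,
                         in_channels = 4L, strided_blocks = integer(0),
                         backbone_mode = "cnn_only", seg_head = FALSE)
  W0 <- init_weights(cfg0, seed = 8L)
  W0[["stem.b1.w3"]][] <- 0; W0[["stem.b1.w5"]][] <- 0
  pc <- array(2, dim = c(4, 4, 4, 4))
  enc0 <- encode(pc, cfg0, W0)
  expect_equal(max(abs(sweep(enc0$tokens, 2, enc0$g))), 0, tolerance = 1e-12)
})

test_that("global pooling is the token mean with the obvious symmetries", {
  Z <- matrix(rnorm(10 * 4), 10, 4)
  h <- global_pool(Z)
  expect_equal(h, colMeans(Z))
  expect_equal(global_pool(Z[sample(10), ]), h)
  v <- rnorm(4)
  expect_equal(global_pool(rbind(v, v, v)), v, ignore_attr = TRUE)
  a <- rnorm(4); b <- rnorm(4)
  expect_equal(global_pool(rbind(a, b)), (a + b) / 2, ignore_attr = TRUE)
})

test_that("the classifier softmax is stable and shift-invariant", {
  cl <- classify(rep(0, 3), matrix(0, 3, 3), rep(0, 3))
  expect_equal(cl$prob, rep(1 / 3, 3))
  W <- matrix(rnorm(12), 4, 3); b <- rnorm(3); h <- rnorm(4)
  p1 <- classify(h, W, b)$prob
  p2 <- classify(h, W, b + 7)$prob    # constant logit shift
  expect_equal(p1, p2, tolerance = 1e-12)
  # hand case o = (ln 2, 0)
  cl2 <- classify(1, matrix(c(log(2), 0), 1, 2), c(0, 0))
  expect_equal(cl2$prob, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # extreme logits stay finite
  cl3 <- classify(1, matrix(c(1000, -1000), 1, 2), c(0, 0))
  expect_true(all(is.finite(cl3$prob)))
})

test_that("cross-entropy matches its closed forms", {
  expect_equal(classification_loss(c(1, 0, 0), c(1, 0, 0)), 0, tolerance = 1e-9)
  expect_equal(classification_loss(rep(0.25, 4), c(0, 1, 0, 0)), log(4),
               tolerance = 1e-12)
  expect_equal(classification_loss(c(0.25, 0.5, 0.25), c(1, 0, 0)), -log(0.25),
               tolerance = 1e-12)
})

test_that("the segmentation decoder emits per-voxel distributions at input shape", {
  for (depth in 1:2) {
    cfg <- encoder_config(channels = 8L, conv_depth = depth,
                          transformer_depth = 1L, seg_head = TRUE)
    W <- init_weights(cfg, seed = 9L)
    p <- rand_patch(grid = 8L)
    pr <- segment_decode(p, cfg, W)
    expect_equal(dim(pr), c(8L, 8L, 8L, 4L))
    sums <- apply(pr, 1:3, sum)
    expect_equal(as.numeric(sums), rep(1, 512), tolerance = 1e-6)
  }
  cfg_t <- encoder_config(channels = 8L, backbone_mode = "transformer_only",
                          seg_head = FALSE)
  W_t <- init_weights(cfg_t, seed = 9L)
  expect_error(segment_decode(rand_patch(8L), cfg_t, W_t), "grid")
})

test_that("soft Dice matches hand-evaluated overlaps", {
  # perfect prediction: loss ~ 0; disjoint: loss ~ 1
  mask <- sample(0:3, 50, replace = TRUE)
  oh <- one_hot(mask, 4L)
  expect_lt(dice_loss(oh, mask), 1e-4)
  wrong <- (mask + 1L) %% 4L
  expect_gt(dice_loss(one_hot(wrong, 4L), mask), 0.95)
  # half-overlap toy on one foreground class (others empty-empty score 1)
  truth <- rep(0L, 20); truth[1:6] <- 1L
  pred <- matrix(0, 20, 4); pred[, 1] <- 1
  pred[4:7, ] <- 0; pred[4:7, 2] <- 1       # predicts 4 voxels, 3 overlap
  expected <- 1 - mean(c(2 * 3 / (4 + 6), 1, 1))
  expect_equal(dice_loss(pred, truth), expected, tolerance = 1e-4)
})

test_that("checkpoints round-trip bit-stably", {
  td <- tiny_dataset(n = 4L)
  fit <- damlm_fit(td, tiny_model_config(), tiny_train_config(epochs = 1L),
                   adaptation_weights(), seed = 3L)
  path <- file.path(tempdir(), "damlm_ckpt.bin")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  for (nm in names(fit$weights))
    expect_identical(back$arrays[[nm]], fit$weights[[nm]])
  expect_identical(back$arrays[["disc.w1"]], fit$disc$w1)
  unlink(path)
})
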