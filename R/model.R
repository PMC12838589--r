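# Hybrid 3D CNN-transformer encoder and task heads.
#
# Architecture: a convolutional stem of multi-scale residual blocks (parallel
# 3x3x3 and 5x5x5 branches summed before the residual add, batch-normalized,
# PReLU), squeeze-style channel attention, sinusoidal positional encodings,
# pre-LayerNorm transformer layers (single-head by default), global average
# pooling into a classifier head, and a mirrored transposed-convolution
# decoder with skip connections for voxel-wise region probabilities.

#' Encoder configuration
#'
#' @param channels Feature width C produced by the stem (divisible by
#'   `attention_heads`).
#' @param conv_depth Number of residual blocks L_c in the stem.
#' @param transformer_depth Number of self-attention layers L_t.
#' @param attention_heads Attention head count (default 1).
#' @param positional_encoding `"sinusoidal"` (default) or `"learned"`
#'   (zero-initialized, trained with the encoder).
#' @param attention_scale `"sqrt_C"` (default) or `"C"` -- the denominator of
#'   the attention softmax.
#' @param backbone_mode `"hybrid"` (default), `"cnn_only"` (transformer
#'   skipped) or `"transformer_only"` (linear patch embedding replaces the
#'   stem).
#' @param in_channels Input channel count (4 MRI sequences).
#' @param n_classes Number of diagnostic classes K.
#' @param n_regions Segmentation classes (background, edema, core, enhancing).
#' @param strided_blocks Indices of stem blocks applying stride-2
#'   downsampling (default: blocks 2 and 4 where present).
#' @param seg_head Attach the segmentation decoder.
#' @param ff_mult Width multiplier of the transformer feed-forward hidden
#'   layer.
#' @return Object of class `encoder_config`.
#' @export
encoder_config <- function(channels = 16L, conv_depth = 2L,
                           transformer_depth = 2L, attention_heads = 1L,
                           positional_encoding = c("sinusoidal", "learned"),
                           attention_scale = c("sqrt_C", "C"),
                           backbone_mode = c("hybrid", "cnn_only", "transformer_only"),
                           in_channels = 4L, n_classes = 2L, n_regions = 4L,
                           strided_blocks = NULL, seg_head = TRUE,
                           ff_mult = 2L) {
  positional_encoding <- match.arg(positional_encoding)
  attention_scale <- match.arg(attention_scale)
  backbone_mode <- match.arg(backbone_mode)
  channels <- as.integer(channels); conv_depth <- as.integer(conv_depth)
  transformer_depth <- as.integer(transformer_depth)
  stopifnot(channels %% attention_heads == 0L)
  if (backbone_mode == "hybrid") stopifnot(conv_depth >= 1L)
  if (is.null(strided_blocks)) strided_blocks <- intersect(c(2L, 4L), seq_len(conv_depth))
  structure(list(channels = channels, conv_depth = conv_depth,
                 transformer_depth = transformer_depth,
                 attention_heads = as.integer(attention_heads),
                 positional_encoding = positional_encoding,
                 attention_scale = attention_scale,
                 backbone_mode = backbone_mode,
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 n_regions = as.integer(n_regions),
                 strided_blocks = as.integer(strided_blocks),
                 seg_head = isTRUE(seg_head), ff_mult = as.integer(ff_mult)),
            class = "encoder_config")
}

kaiming_uniform <- function(fan_in, n) {
  b <- sqrt(6 / fan_in)
  stats::runif(n, -b, b)
}

kw <- function(nrow_, ncol_) matrix(kaiming_uniform(nrow_, nrow_ * ncol_), nrow_, ncol_)

#' Initialize model weights
#'
#' Kaiming-uniform initialization of the encoder, classifier, segmentation
#' decoder and batch-norm parameters, returned as a flat named list of
#' arrays. Deterministic given `seed`.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed.
#' @return Named list of weight arrays.
#' @export
init_weights <- function(config, seed = 0L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(59L, seed))
  C <- config$channels
  W <- list()
  if (config$backbone_mode == "transformer_only") {
    f <- 2L^length(config$strided_blocks)
    W[["embed.w"]] <- kw(f^3 * config$in_channels, C)
    W[["embed.b"]] <- rep(0, C)
  } else {
    cin <- config$in_channels
    for (i in seq_len(config$conv_depth)) {
      p <- sprintf("stem.b%d.", i)
      W[[paste0(p, "w3")]] <- kw(27L * cin, C)
      W[[paste0(p, "w5")]] <- kw(125L * cin, C)
      W[[paste0(p, "bias")]] <- rep(0, C)
      W[[paste0(p, "bn.gamma")]] <- rep(1, C)
      W[[paste0(p, "bn.beta")]] <- rep(0, C)
      W[[paste0(p, "alpha")]] <- 0.25
      strided <- i %in% config$strided_blocks
      if (strided || cin != C) W[[paste0(p, "proj")]] <- kw(cin, C)
      cin <- C
    }
    ch <- max(2L, C %/% 2L)
    W[["ca.w1"]] <- kw(C, ch)
    W[["ca.w2"]] <- kw(ch, C)
  }
  if (config$backbone_mode != "cnn_only") {
    for (l in seq_len(config$transformer_depth)) {
      p <- sprintf("tf.l%d.", l)
      W[[paste0(p, "ln1.gamma")]] <- rep(1, C); W[[paste0(p, "ln1.beta")]] <- rep(0, C)
      W[[paste0(p, "wq")]] <- kw(C, C); W[[paste0(p, "wk")]] <- kw(C, C)
      W[[paste0(p, "wv")]] <- kw(C, C)
      W[[paste0(p, "ln2.gamma")]] <- rep(1, C); W[[paste0(p, "ln2.beta")]] <- rep(0, C)
      H <- C * config$ff_mult
      W[[paste0(p, "ff.w1")]] <- kw(C, H); W[[paste0(p, "ff.b1")]] <- rep(0, H)
      W[[paste0(p, "ff.w2")]] <- kw(H, C); W[[paste0(p, "ff.b2")]] <- rep(0, C)
    }
  }
  W[["cls.w"]] <- kw(C, config$n_classes)
  W[["cls.b"]] <- rep(0, config$n_classes)
  if (config$seg_head && config$backbone_mode != "transformer_only") {
    nup <- length(config$strided_blocks)
    for (j in seq_len(nup)) {
      p <- sprintf("dec.u%d.", j)
      W[[paste0(p, "w")]] <- kw(C, 8L * C)
      W[[paste0(p, "b")]] <- rep(0, C)
      q <- sprintf("dec.c%d.", j)
      W[[paste0(q, "w")]] <- kw(27L * C, C)
      W[[paste0(q, "b")]] <- rep(0, C)
      W[[paste0(q, "alpha")]] <- 0.25
    }
    W[["dec.out.w"]] <- kw(C, config$n_regions)
    W[["dec.out.b"]] <- rep(0, config$n_regions)
  }
  W[vapply(W, is.null, logical(1))] <- NULL
  W
}

# fresh batch-norm running state for a weight set
init_bn_state <- function(config) {
  st <- new.env(parent = emptyenv())
  for (i in seq_len(config$conv_depth)) {
    e <- new.env(parent = emptyenv())
    e$mean <- rep(0, config$channels); e$var <- rep(1, config$channels)
    st[[sprintf("bn%d", i)]] <- e
  }
  st
}

clone_bn_state <- function(state, config) {
  st <- new.env(parent = emptyenv())
  for (i in seq_len(config$conv_depth)) {
    key <- sprintf("bn%d", i)
    e <- new.env(parent = emptyenv())
    e$mean <- state[[key]]$mean; e$var <- state[[key]]$var
    st[[key]] <- e
  }
  st
}

#' Sinusoidal positional encodings for a 3-D token grid
#'
#' Per-axis sinusoids over C/3 sub-bands, concatenated and truncated/padded
#' to C columns; depends only on the grid shape and channel count. Tokens
#' are ordered x-fastest.
#'
#' @param grid Token grid shape (length 3).
#' @param C Channel count.
#' @return N x C matrix, N = prod(grid).
#' @export
positional_encoding <- function(grid, C) {
  co <- voxel_grid_coords(grid)
  per_axis <- ceiling(C / 3)
  cols <- list()
  for (ax in 1:3) {
    pos <- co[, ax]
    k <- seq_len(per_axis)
    freq <- 1 / (100^((k - 1) / max(1, per_axis)))
    block <- matrix(0, nrow(co), per_axis)
    for (j in k) {
      block[, j] <- if (j %% 2L == 1L) sin(pos * freq[j]) else cos(pos * freq[j])
    }
    cols[[ax]] <- block
  }
  P <- do.call(cbind, cols)
  if (ncol(P) >= C) P[, seq_len(C), drop = FALSE]
  else cbind(P, matrix(0, nrow(P), C - ncol(P)))
}

# ---- tape-level forward passes -----------------------------------------

# wrap a flat weight list as leaf nodes (named list of ad nodes); marked as
# parameters so gradient computation is not skipped for them
wrap_params <- function(W) {
  lapply(W, function(w) { n <- ad_leaf(w); n$param <- TRUE; n })
}

# one multi-scale residual block; returns the activation node
.fwd_stem_block <- function(x, P, i, config, state, training, update_stats) {
  p <- sprintf("stem.b%d.", i)
  strided <- i %in% config$strided_blocks
  s <- if (strided) 2L else 1L
  y3 <- ad_conv3d(x, P[[paste0(p, "w3")]], NULL, kshape = 3L, stride = s)
  y5 <- ad_conv3d(x, P[[paste0(p, "w5")]], NULL, kshape = 5L, stride = s)
  y <- ad_addbias(ad_add(y3, y5), P[[paste0(p, "bias")]])
  y <- ad_batchnorm(y, P[[paste0(p, "bn.gamma")]], P[[paste0(p, "bn.beta")]],
                    state[[sprintf("bn%d", i)]], training = training,
                    update_stats = update_stats,
                    momentum = if (is.null(state$momentum)) 0.9 else state$momentum)
  y <- ad_prelu(y, P[[paste0(p, "alpha")]])
  shortcut <- if (!is.null(P[[paste0(p, "proj")]])) {
    ad_conv3d(x, P[[paste0(p, "proj")]], NULL, kshape = 1L, stride = s, pad = 0L)
  } else x
  ad_add(shortcut, y)
}

.fwd_channel_attention <- function(f0, P) {
  pooled <- ad_gap(f0)                              # (B, C)
  s <- ad_sigmoid(ad_matmul(ad_relu(ad_matmul(pooled, P[["ca.w1"]])), P[["ca.w2"]]))
  list(refined = ad_chanscale(f0, s), s = s)
}

.fwd_transformer_layer <- function(z, P, l, config) {
  p <- sprintf("tf.l%d.", l)
  C <- config$channels
  H <- config$attention_heads
  zn <- ad_layernorm(z, P[[paste0(p, "ln1.gamma")]], P[[paste0(p, "ln1.beta")]])
  q <- ad_matmul(zn, P[[paste0(p, "wq")]])
  k <- ad_matmul(zn, P[[paste0(p, "wk")]])
  v <- ad_matmul(zn, P[[paste0(p, "wv")]])
  dh <- C %/% H
  scale <- switch(config$attention_scale, sqrt_C = sqrt(dh), C = dh)
  heads <- lapply(seq_len(H), function(h) {
    idx <- (h - 1L) * dh + seq_len(dh)
    qs <- if (H == 1L) q else ad_cols(q, idx)
    ks <- if (H == 1L) k else ad_cols(k, idx)
    vs <- if (H == 1L) v else ad_cols(v, idx)
    ad_attention(qs, ks, vs, scale)
  })
  attn <- if (H == 1L) heads[[1]] else ad_cbind(heads)
  an <- ad_layernorm(attn, P[[paste0(p, "ln2.gamma")]], P[[paste0(p, "ln2.beta")]])
  ff <- ad_addbias(ad_matmul(ad_relu(
    ad_addbias(ad_matmul(an, P[[paste0(p, "ff.w1")]]), P[[paste0(p, "ff.b1")]])),
    P[[paste0(p, "ff.w2")]]), P[[paste0(p, "ff.b2")]])
  ad_add(z, ff)
}

# full encoder on a batch matrix; returns nodes for tokens, pooled g, skips
fwd_encoder <- function(P, xmat, config, state, training = FALSE,
                        update_stats = FALSE) {
  x <- ad_leaf(xmat)
  skips <- list()
  if (config$backbone_mode == "transformer_only") {
    f <- 2L^length(config$strided_blocks)
    feat <- ad_conv3d(x, P[["embed.w"]], P[["embed.b"]], kshape = f,
                      stride = f, pad = 0L)
    s <- NULL
  } else {
    h <- x
    for (i in seq_len(config$conv_depth)) {
      h <- .fwd_stem_block(h, P, i, config, state, training, update_stats)
      skips[[i]] <- h
    }
    ca <- .fwd_channel_attention(h, P)
    feat <- ca$refined
    s <- ca$s
  }
  grid <- feat$grid
  # tokenization: the layout already is (tokens x C); add positional encoding
  z <- feat
  if (config$backbone_mode != "cnn_only" && config$transformer_depth > 0L) {
    if (config$positional_encoding == "sinusoidal") {
      B <- feat$nsamp
      Pm <- positional_encoding(grid, config$channels)
      z <- ad_shift(z, do.call(rbind, replicate(B, Pm, simplify = FALSE)))
    } else if (!is.null(P[["pos.p"]])) {
      z <- ad_addpos(z, P[["pos.p"]])
    }  # learned encodings start at zero until allocated by the trainer
    for (l in seq_len(config$transformer_depth))
      z <- .fwd_transformer_layer(z, P, l, config)
  }
  g <- ad_gap(z)
  list(tokens = z, g = g, skips = skips, channel_weights = s, grid = grid)
}

fwd_classifier <- function(P, g) {
  ad_addbias(ad_matmul(g, P[["cls.w"]]), P[["cls.b"]])
}

# decoder: token grid -> per-voxel region probabilities at input resolution
fwd_decoder <- function(P, tokens, skips, config) {
  if (config$backbone_mode == "transformer_only")
    stop("segmentation decoding requires a convolutional grid (hybrid or cnn_only mode)")
  nup <- length(config$strided_blocks)
  h <- tokens
  if (nup > 0) {
    for (j in seq_len(nup)) {
      p <- sprintf("dec.u%d.", j); q <- sprintf("dec.c%d.", j)
      h <- ad_convT3d(h, P[[paste0(p, "w")]], P[[paste0(p, "b")]], factor = 2L)
      # add the finest stem feature map matching this resolution, if any
      match_grid <- h$grid
      for (sk in skips) {
        if (identical(sk$grid, match_grid)) { h <- ad_add(h, sk); break }
      }
      h <- ad_prelu(ad_addbias(ad_conv3d(h, P[[paste0(q, "w")]], NULL, kshape = 3L),
                               P[[paste0(q, "b")]]), P[[paste0(q, "alpha")]])
    }
  }
  logits <- ad_addbias(ad_conv3d(h, P[["dec.out.w"]], NULL, kshape = 1L, pad = 0L),
                       P[["dec.out.b"]])
  ad_rowsoftmax(logits)
}

# ---- losses -------------------------------------------------------------

# mean categorical cross-entropy over a batch: probs (B, K), onehot (B, K)
ad_cross_entropy <- function(probs, onehot, eps = 1e-12) {
  pv <- probs$value
  B <- nrow(pv)
  v <- -sum(onehot * log(pmax(pv, eps))) / B
  ad_node(v, list(probs), function(g) {
    list(-g * onehot / pmax(pv, eps) / B)
  })
}

# batch-pooled soft Dice loss over foreground classes; probs (S*B, R) from a
# per-voxel softmax, onehot same shape. Background (column 1) is excluded.
ad_dice_loss <- function(probs, onehot, eps = 1e-5) {
  pv <- probs$value
  fg <- 2:ncol(pv)
  inter <- colSums(pv[, fg, drop = FALSE] * onehot[, fg, drop = FALSE])
  psum <- colSums(pv[, fg, drop = FALSE])
  gsum <- colSums(onehot[, fg, drop = FALSE])
  dice <- (2 * inter + eps) / (psum + gsum + eps)
  v <- 1 - mean(dice)
  nfg <- length(fg)
  ad_node(v, list(probs), function(g) {
    gp <- matrix(0, nrow(pv), ncol(pv))
    for (j in seq_along(fg)) {
      c0 <- fg[j]
      den <- psum[j] + gsum[j] + eps
      gp[, c0] <- -(2 * onehot[, c0] * den - (2 * inter[j] + eps)) / den^2 / nfg
    }
    list(g * gp)
  })
}

# ---- plain (non-tape) user-facing wrappers ------------------------------

#' Convolutional stem forward pass
#'
#' Runs the multi-scale residual stem on a single 4-channel patch.
#'
#' @param patch 4-D array (x, y, z, channel).
#' @param config An [encoder_config()].
#' @param weights Weight list from [init_weights()].
#' @param state Optional batch-norm state (fresh by default).
#' @param training Use batch statistics instead of running estimates.
#' @return List with `features` (4-D array h' x w' x d' x C) and `grid`.
#' @export
conv_stem_forward <- function(patch, config, weights, state = NULL,
                              training = FALSE) {
  if (is.null(state)) state <- init_bn_state(config)
  P <- wrap_params(weights)
  x <- ad_leaf(patch_to_mat(patch))
  h <- x
  for (i in seq_len(config$conv_depth))
    h <- .fwd_stem_block(h, P, i, config, state, training, FALSE)
  grid <- h$grid
  list(features = array(h$value, dim = c(grid, config$channels)), grid = grid)
}

#' Channel attention
#'
#' Computes the sigmoid channel-importance vector
#' `s = sigmoid(W2 relu(W1 GAP(F0)))` and the channel-refined tensor
#' `F0* = s_c * F0`.
#'
#' @param features 4-D feature array (x, y, z, C).
#' @param W1,W2 Weight matrices (C x H and H x C).
#' @return List with `refined` (same shape) and `s` (length C, in (0,1)).
#' @export
channel_attention <- function(features, W1, W2) {
  m <- patch_to_mat(features)
  P <- list(`ca.w1` = ad_leaf(W1), `ca.w2` = ad_leaf(W2))
  ca <- .fwd_channel_attention(ad_leaf(m), P)
  list(refined = array(ca$refined$value, dim = dim(features)),
       s = as.numeric(ca$s$value))
}

#' Tokenize a feature tensor
#'
#' Reshapes the grid (x fastest) into an N x C token matrix and adds
#' positional encodings.
#'
#' @param features 4-D feature array (x, y, z, C).
#' @param config An [encoder_config()] (controls the encoding variant).
#' @return List with `tokens` (N x C), `P` (the encoding matrix) and `grid`.
#' @export
tokenize <- function(features, config) {
  grid <- dim(features)[1:3]
  C <- dim(features)[4]
  Z <- matrix(features, nrow = prod(grid), ncol = C)
  Pm <- if (config$positional_encoding == "sinusoidal")
    positional_encoding(grid, C) else matrix(0, prod(grid), C)
  list(tokens = Z + Pm, P = Pm, grid = grid)
}

#' Invert tokenization (positions removed by the caller if added)
#' @param tokens N x C matrix.
#' @param grid Token grid shape.
#' @return 4-D array (grid, C).
#' @export
detokenize <- function(tokens, grid) {
  array(tokens, dim = c(grid, ncol(tokens)))
}

#' One transformer encoder layer
#'
#' Pre-LayerNorm single- or multi-head self-attention followed by a residual
#' two-layer feed-forward: `Z_l = Z_{l-1} + FF(LN(Attn(LN(Z))))`.
#'
#' @param Z N x C token matrix.
#' @param weights Weight list containing the `tf.l<layer>.` entries.
#' @param config An [encoder_config()].
#' @param layer Layer index within `weights`.
#' @return N x C matrix.
#' @export
transformer_layer <- function(Z, weights, config, layer = 1L) {
  m <- Z
  attr(m, "grid") <- c(nrow(Z), 1L, 1L)
  attr(m, "nsamp") <- 1L
  out <- .fwd_transformer_layer(ad_leaf(m), wrap_params(weights), layer, config)
  v <- out$value
  attributes(v) <- list(dim = dim(Z))
  v
}

#' Encode a patch
#'
#' Full backbone composition: stem, channel attention, tokenization with
#' positional encodings, transformer layers, and token-mean pooling.
#' `cnn_only` mode skips the transformer; `transformer_only` replaces the
#' stem with a strided linear patch embedding.
#'
#' @param patch 4-D array (x, y, z, channel), or a list of such arrays for a
#'   batch.
#' @param config An [encoder_config()].
#' @param weights Weight list from [init_weights()].
#' @param state Optional batch-norm state.
#' @param training Use batch statistics in the stem's batch norm.
#' @return List with `tokens` (N x C for a single patch), `g` (pooled
#'   C-vector or B x C matrix) and `grid`.
#' @export
encode <- function(patch, config, weights, state = NULL, training = FALSE) {
  if (is.null(state)) state <- init_bn_state(config)
  m <- if (is.list(patch)) patches_to_mat(patch) else patch_to_mat(patch)
  enc <- fwd_encoder(wrap_params(weights), m, config, state, training, FALSE)
  g <- enc$g$value
  if (!is.list(patch)) g <- as.numeric(g)
  list(tokens = enc$tokens$value, g = g, grid = enc$grid)
}

#' Global average pooling of tokens
#' @param Z N x C token matrix.
#' @return Length-C vector `h = mean of token rows`.
#' @export
global_pool <- function(Z) colMeans(Z)

#' Linear classifier with stable softmax
#'
#' @param h Pooled feature vector (length C) or B x C matrix.
#' @param W_c C x K weight matrix.
#' @param b_c Length-K bias.
#' @return List with `logits` and `prob` (softmax with max-subtraction).
#' @export
classify <- function(h, W_c, b_c) {
  hm <- if (is.matrix(h)) h else matrix(h, nrow = 1)
  o <- sweep(hm %*% W_c, 2, b_c, "+")
  p <- exp(o - apply(o, 1, max))
  p <- p / rowSums(p)
  if (!is.matrix(h)) { o <- as.numeric(o); p <- as.numeric(p) }
  list(logits = o, prob = p)
}

#' Categorical cross-entropy
#'
#' `L = -sum_k y_k log(p_k)`, with probabilities clamped at a machine-epsilon
#' guard before the log.
#'
#' @param prob Predicted class probabilities (vector or B x K matrix).
#' @param y_onehot One-hot ground truth of matching shape.
#' @return Scalar loss (mean over rows for matrix input).
#' @export
classification_loss <- function(prob, y_onehot, eps = 1e-12) {
  pm <- if (is.matrix(prob)) prob else matrix(prob, nrow = 1)
  ym <- if (is.matrix(y_onehot)) y_onehot else matrix(y_onehot, nrow = 1)
  mean(-rowSums(ym * log(pmax(pm, eps))))
}

#' One-hot encode integer class labels (0-based)
#' @param y Integer labels in 0..K-1.
#' @param K Class count.
#' @return length(y) x K matrix.
#' @export
one_hot <- function(y, K) {
  m <- matrix(0, length(y), K)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

#' Segmentation decoding
#'
#' Re-grids the token sequence, upsamples with transposed convolutions
#' mirroring the stem's stride-2 blocks (adding stem skip features at
#' matching resolutions), and emits per-voxel softmax probabilities over the
#' region classes.
#'
#' @param patch 4-D input patch (run through the encoder internally).
#' @param config An [encoder_config()] with `seg_head = TRUE`.
#' @param weights Weight list.
#' @param state Optional batch-norm state.
#' @param training Stem batch-norm mode.
#' @return 4-D array (x, y, z, n_regions) of per-voxel probabilities.
#' @export
segment_decode <- function(patch, config, weights, state = NULL, training = FALSE) {
  if (is.null(state)) state <- init_bn_state(config)
  P <- wrap_params(weights)
  m <- patch_to_mat(patch)
  enc <- fwd_encoder(P, m, config, state, training, FALSE)
  probs <- fwd_decoder(P, enc$tokens, enc$skips, config)
  array(probs$value, dim = c(probs$grid, config$n_regions))
}

#' Soft Dice segmentation loss
#'
#' `1 - mean over foreground classes of (2 sum p g + eps) / (sum p + sum g + eps)`.
#' Voxels may come from a single patch (4-D arrays) or a flattened matrix.
#'
#' @param pred Per-voxel class probabilities, 4-D array (x, y, z, R) or
#'   (V x R) matrix.
#' @param region_mask Integer label grid (0 = background) or one-hot matrix.
#' @param eps Smoothing constant.
#' @return Scalar loss in [0, 1 + eps).
#' @export
dice_loss <- function(pred, region_mask, eps = 1e-5) {
  if (length(dim(pred)) == 4L) {
    R <- dim(pred)[4]
    pred <- matrix(pred, ncol = R)
  }
  R <- ncol(pred)
  onehot <- if (is.matrix(region_mask) && ncol(region_mask) == R) region_mask
            else one_hot(as.integer(region_mask), R)
  fg <- 2:R
  inter <- colSums(pred[, fg, drop = FALSE] * onehot[, fg, drop = FALSE])
  psum <- colSums(pred[, fg, drop = FALSE])
  gsum <- colSums(onehot[, fg, drop = FALSE])
  1 - mean((2 * inter + eps) / (psum + gsum + eps))
}
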