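# 3D convolution ops for the autodiff tape, built on C++ im2col/col2im
# kernels (src/conv_im2col.cpp) and BLAS matrix multiplication.
#
# Feature maps follow the package layout: (S*B) x C matrices, rows grouped
# by sample, spatial order x-fastest; the grid and sample count live on the
# tape nodes. Kernel weights are stored as (K * C_in) x C_out matrices, taps
# ordered x-fastest over the kernel window, tap index fastest within each
# input-channel block.

conv_out_grid <- function(grid, kshape, stride, pad) {
  as.integer((grid + 2L * pad - kshape) %/% stride + 1L)
}

#' 3D convolution node
#'
#' @param x Input node, (S*B) x C_in layout with node-level grid/nsamp.
#' @param W Weight node, (K*C_in) x C_out.
#' @param bias Optional bias node of length C_out.
#' @param kshape Kernel shape (scalar or length 3).
#' @param stride Stride (scalar or length 3).
#' @param pad Zero padding per side (scalar or length 3); defaults to
#'   (k-1)/2, which preserves spatial shape for odd kernels at stride 1.
#' @keywords internal
ad_conv3d <- function(x, W, bias = NULL, kshape, stride = 1L, pad = NULL) {
  xv <- x$value
  grid <- x$grid; B <- x$nsamp
  kshape <- as.integer(rep(kshape, length.out = 3L))
  stride <- as.integer(rep(stride, length.out = 3L))
  if (is.null(pad)) pad <- (kshape - 1L) %/% 2L
  pad <- as.integer(rep(pad, length.out = 3L))
  ogrid <- conv_out_grid(grid, kshape, stride, pad)
  Wv <- W$value
  v <- cpp_conv3d_fwd(xv, Wv, grid, kshape, stride, pad, B)
  if (!is.null(bias)) v <- sweep(v, 2, bias$value, "+")
  parents <- if (is.null(bias)) list(x, W) else list(x, W, bias)
  x_needs <- !is.null(x$backfn) || isTRUE(x$param)
  ad_node(v, parents, function(g) {
    dW <- cpp_conv3d_bwd_w(xv, g, grid, kshape, stride, pad, B)
    dx <- if (x_needs) cpp_conv3d_bwd_x(g, Wv, grid, kshape, stride, pad, B) else NULL
    if (is.null(bias)) list(dx, dW) else list(dx, dW, colSums(g))
  }, grid = ogrid, nsamp = B)
}

#' Transposed 3D convolution with kernel = stride (exact upsampling)
#'
#' Each input voxel emits a factor^3 output block; blocks do not overlap, so
#' the op is a matmul followed by a bijective scatter. Weights are stored as
#' C_in x (K * C_out), tap index fastest within each output-channel block.
#' @keywords internal
ad_convT3d <- function(x, W, bias = NULL, factor = 2L) {
  xv <- x$value
  grid <- x$grid; B <- x$nsamp
  f <- as.integer(factor)
  ogrid <- grid * f
  S <- prod(grid); So <- prod(ogrid); K <- f^3
  Wv <- W$value
  Cout <- ncol(Wv) / K
  key <- paste("T", paste(c(grid, f, B), collapse = "_"), sep = "_")
  if (is.null(.convT_cache[[key]])) {
    oc <- voxel_grid_coords(ogrid)
    ixc <- oc %/% f
    kxc <- oc %% f
    ii <- ixc[, 1] + ixc[, 2] * grid[1] + ixc[, 3] * grid[1] * grid[2] + 1L
    kk <- kxc[, 1] + kxc[, 2] * f + kxc[, 3] * f * f + 1L
    MAP <- integer(So * B)
    for (b in seq_len(B))
      MAP[(b - 1L) * So + seq_len(So)] <- (b - 1L) * S + ii + (kk - 1L) * S * B
    .convT_cache[[key]] <- MAP
  }
  MAP <- .convT_cache[[key]]
  Z <- xv %*% Wv                      # (S*B, K*Cout), tap fastest
  dim(Z) <- c(S * B * K, Cout)
  v <- Z[MAP, , drop = FALSE]
  if (!is.null(bias)) v <- sweep(v, 2, bias$value, "+")
  parents <- if (is.null(bias)) list(x, W) else list(x, W, bias)
  ad_node(v, parents, function(g) {
    dZ <- matrix(0, S * B * K, Cout)
    dZ[MAP, ] <- g
    dim(dZ) <- c(S * B, K * Cout)
    dW <- crossprod(xv, dZ)
    dx <- dZ %*% t(Wv)
    if (is.null(bias)) list(dx, dW) else list(dx, dW, colSums(g))
  }, grid = ogrid, nsamp = B)
}

.convT_cache <- new.env(parent = emptyenv())

# fused single-head scaled-dot-product attention node (C++ kernels); the
# per-sample softmax matrix is cached for the backward pass
ad_attention <- function(q, k, v, scale) {
  B <- q$nsamp
  fw <- cpp_attention_fwd(q$value, k$value, v$value, B, scale)
  qv <- q$value; kv <- k$value; vv <- v$value
  ad_node(fw$out, list(q, k, v), function(g) {
    bw <- cpp_attention_bwd(fw$P, qv, kv, vv, g, B, scale)
    list(bw$dQ, bw$dK, bw$dV)
  })
}

# convert a single 4-D patch array (x, y, z, channel) to the internal layout
patch_to_mat <- function(patch) {
  d <- dim(patch)
  stopifnot(length(d) == 4L)
  m <- matrix(patch, nrow = prod(d[1:3]), ncol = d[4])
  attr(m, "grid") <- d[1:3]
  attr(m, "nsamp") <- 1L
  m
}

# stack a list of equally shaped patch arrays into one batch matrix
patches_to_mat <- function(patches) {
  d <- dim(patches[[1]])
  m <- do.call(rbind, lapply(patches, function(p) matrix(p, nrow = prod(d[1:3]))))
  attr(m, "grid") <- d[1:3]
  attr(m, "nsamp") <- length(patches)
  m
}

mat_to_patch <- function(m, grid, sample = 1L) {
  S <- prod(grid)
  rows <- (sample - 1L) * S + seq_len(S)
  array(m[rows, ], dim = c(grid, ncol(m)))
}
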