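# Minimal reverse-mode automatic differentiation on arrays.
#
# The model's forward passes build a tape of nodes; ad_backward() traverses
# the tape in reverse topological order and accumulates gradients into leaf
# nodes. Nodes are environments (mutable, cheap); differentiable arguments
# of an op must be nodes, non-differentiable arguments are plain numerics
# captured in the backward closure. Every op's backward returns a list of
# gradients aligned with its parent list.
#
# Activation layout convention used throughout the model code:
#   a feature map over a batch is a (S*B) x C matrix, rows grouped by sample
#   (all rows of sample 1 first), each sample's rows in x-fastest spatial
#   order. The spatial grid (nx, ny, nz) and the sample count ride on the
#   NODE (fields $grid and $nsamp), never as array attributes, so large
#   values are never copied just to tag them.

.ad_counter <- new.env(parent = emptyenv())
.ad_counter$n <- 0

ad_node <- function(value, parents = list(), backfn = NULL,
                    grid = NULL, nsamp = NULL) {
  e <- new.env(parent = emptyenv())
  .ad_counter$n <- .ad_counter$n + 1
  e$id <- .ad_counter$n
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  if (is.null(grid) && length(parents)) {
    # inherit geometry from the first parent that carries one
    for (p in parents) {
      if (!is.null(p$grid)) { grid <- p$grid; nsamp <- p$nsamp; break }
    }
  }
  e$grid <- grid
  e$nsamp <- nsamp
  class(e) <- "ad_node"
  e
}

is_ad <- function(x) inherits(x, "ad_node")

#' Wrap a numeric array as an autodiff leaf
#'
#' Geometry attributes (`grid`, `nsamp`) attached to the value by
#' [patch_to_mat()] / [patches_to_mat()] are lifted onto the node.
#' @param value Numeric array/matrix/vector.
#' @return An autodiff leaf node.
#' @keywords internal
ad_leaf <- function(value) {
  ad_node(value, grid = attr(value, "grid"), nsamp = attr(value, "nsamp"))
}

ad_value <- function(x) if (is_ad(x)) x$value else x

#' Reverse-mode gradient sweep
#'
#' Seeds the root node (typically a scalar loss) with gradient 1 and
#' accumulates gradients into every ancestor node's `$grad`. Interior
#' gradients are released as soon as they have been consumed.
#' @param root Output node.
#' @param seed Gradient seed (defaults to 1 for scalar losses).
#' @keywords internal
ad_backward <- function(root, seed = 1) {
  topo <- vector("list", 256L)
  nt <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L))
  ns <- 1L
  while (ns > 0L) {
    fr <- stack[[ns]]
    node <- fr$node
    key <- as.character(node$id)
    if (fr$i == 0L && !is.null(visited[[key]])) { ns <- ns - 1L; next }
    visited[[key]] <- TRUE
    if (fr$i < length(node$parents)) {
      stack[[ns]]$i <- fr$i + 1L
      child <- node$parents[[fr$i + 1L]]
      ckey <- as.character(child$id)
      if (is.null(visited[[ckey]])) {
        ns <- ns + 1L
        stack[[ns]] <- list(node = child, i = 0L)
      }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
      ns <- ns - 1L
    }
  }
  root$grad <- if (length(root$value) == 1L) seed else array(seed, dim = dim(root$value))
  for (i in seq(nt, 1L)) {
    node <- topo[[i]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    grads <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      g <- grads[[j]]
      if (is.null(g)) next
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!identical(node, root)) node$grad <- NULL
  }
  invisible(root)
}

# ---- elementwise / linear algebra ops ----------------------------------

ad_add <- function(a, b) ad_node(a$value + b$value, list(a, b), function(g) list(g, g))

ad_sub <- function(a, b) ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))

ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# multiply by a plain constant (scalar or array)
ad_scale <- function(a, k) ad_node(a$value * k, list(a), function(g) list(g * k))

# add a plain constant array/scalar
ad_shift <- function(a, k) ad_node(a$value + k, list(a), function(g) list(g))

ad_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

# x: (R x C) node, bias: length-C node added to every row
ad_addbias <- function(x, bias) {
  xv <- x$value
  ones <- rep(1, ncol(xv))
  ad_node(cpp_affine_cols(xv, ones, bias$value), list(x, bias),
          function(g) list(g, colSums(g)))
}

# ---- activations --------------------------------------------------------

ad_relu <- function(x) {
  xv <- x$value
  m <- xv > 0
  ad_node(xv * m, list(x), function(g) list(g * m))
}

# PReLU with a single learned slope (scalar node)
ad_prelu <- function(x, alpha) {
  xv <- x$value
  a <- as.numeric(alpha$value)
  v <- cpp_prelu_fwd(xv, a)
  ad_node(v, list(x, alpha), function(g) {
    r <- cpp_prelu_bwd(g, xv, a)
    list(r$dx, r$dalpha)
  })
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, list(x), function(g) list(g * s * (1 - s)))
}

# numerically stable row-wise softmax (rows are independent distributions)
ad_rowsoftmax <- function(x) {
  xv <- x$value
  m <- xv[cbind(seq_len(nrow(xv)), max.col(xv, ties.method = "first"))]
  e <- exp(xv - m)
  p <- e / rowSums(e)
  ad_node(p, list(x), function(g) list(p * (g - rowSums(g * p))))
}

# ---- reductions ---------------------------------------------------------

ad_sum <- function(x) {
  xv <- x$value
  ad_node(sum(xv), list(x), function(g) {
    list(array(g, dim = if (is.null(dim(xv))) length(xv) else dim(xv)))
  }, grid = NULL)
}

ad_mean <- function(x) ad_scale(ad_sum(x), 1 / length(x$value))

# weighted sum of scalar nodes: sum_i w_i * s_i
ad_wsum <- function(nodes, weights) {
  stopifnot(length(nodes) == length(weights))
  vals <- vapply(nodes, function(n) as.numeric(n$value), numeric(1))
  ad_node(sum(vals * weights), nodes, function(g) {
    lapply(weights, function(w) g * w)
  }, grid = NULL)
}

# ---- batched / structured ops ------------------------------------------

# per-sample global average pool: (S*B, C) -> (B, C)
ad_gap <- function(x) {
  xv <- x$value
  B <- x$nsamp; S <- nrow(xv) / B
  grp <- rep(seq_len(B), each = S)
  v <- rowsum(xv, grp) / S
  ad_node(v, list(x), function(g) list(g[grp, , drop = FALSE] / S), grid = NULL)
}

# scale each sample's channels: x (S*B, C) by s (B, C)
ad_chanscale <- function(x, s) {
  xv <- x$value; sv <- s$value
  B <- x$nsamp; S <- nrow(xv) / B
  grp <- rep(seq_len(B), each = S)
  se <- sv[grp, , drop = FALSE]
  ad_node(xv * se, list(x, s), function(g) {
    list(g * se, rowsum(g * xv, grp))
  }, grid = x$grid, nsamp = B)
}

# per-sample matmul blocks. transb = TRUE computes A_b %*% t(B_b) (attention
# scores) with A, B both (N*B, C); transb = FALSE computes A_b %*% B_b with
# A (N*B, N), B (N*B, C).
ad_bmm <- function(a, b, transb = FALSE) {
  av <- a$value; bv <- b$value
  B <- a$nsamp
  N <- nrow(av) / B
  Nb <- nrow(bv) / B
  outc <- if (transb) Nb else ncol(bv)
  v <- matrix(0, N * B, outc)
  for (s in seq_len(B)) {
    ra <- ((s - 1) * N + 1):(s * N)
    rb <- ((s - 1) * Nb + 1):(s * Nb)
    v[ra, ] <- if (transb) tcrossprod(av[ra, , drop = FALSE], bv[rb, , drop = FALSE])
               else av[ra, , drop = FALSE] %*% bv[rb, , drop = FALSE]
  }
  ad_node(v, list(a, b), function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    gb <- matrix(0, nrow(bv), ncol(bv))
    for (s in seq_len(B)) {
      ra <- ((s - 1) * N + 1):(s * N)
      rb <- ((s - 1) * Nb + 1):(s * Nb)
      gs <- g[ra, , drop = FALSE]
      if (transb) {
        ga[ra, ] <- gs %*% bv[rb, , drop = FALSE]
        gb[rb, ] <- crossprod(gs, av[ra, , drop = FALSE])
      } else {
        ga[ra, ] <- tcrossprod(gs, bv[rb, , drop = FALSE])
        gb[rb, ] <- crossprod(av[ra, , drop = FALSE], gs)
      }
    }
    list(ga, gb)
  })
}

# row slice with scatter backward (per-domain feature splits)
ad_rows <- function(x, idx) {
  xv <- x$value
  ad_node(xv[idx, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[idx, ] <- g
    list(gx)
  }, grid = NULL)
}

# column slice with scatter backward (multi-head channel splits)
ad_cols <- function(x, idx) {
  xv <- x$value
  ad_node(xv[, idx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[, idx] <- g
    list(gx)
  })
}

ad_cbind <- function(nodes) {
  vals <- lapply(nodes, `[[`, "value")
  widths <- vapply(vals, ncol, integer(1))
  v <- do.call(cbind, vals)
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_node(v, nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

# add a learned per-token matrix p (N, C) to every sample block of x (N*B, C)
ad_addpos <- function(x, p) {
  xv <- x$value; pv <- p$value
  B <- x$nsamp
  pe <- do.call(rbind, replicate(B, pv, simplify = FALSE))
  ad_node(xv + pe, list(x, p), function(g) {
    N <- nrow(pv)
    list(g, rowsum(g, rep(seq_len(N), times = B)))
  })
}

# identity forward, gradient multiplied by `scale` on the way back
# (gradient-reversal layer when scale < 0)
ad_gradscale <- function(x, scale) {
  ad_node(x$value, list(x), function(g) list(g * scale))
}

# cut the tape: value passes, gradient does not
ad_detach <- function(x) {
  n <- ad_node(x$value)
  n$grid <- x$grid; n$nsamp <- x$nsamp
  n
}

# ---- normalization layers ----------------------------------------------

# batch normalization over all rows per column (channel); training mode uses
# biased batch variance (the joint mixed-batch statistics), eval mode uses
# running estimates. `state` is an environment with $mean and $var; updated
# with momentum only when update_stats = TRUE.
ad_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         update_stats = training, eps = 1e-5, momentum = 0.9) {
  xv <- x$value
  gv <- gamma$value; bv <- beta$value
  if (training) {
    cs <- cpp_colstats(xv)
    mu <- cs$mean; va <- cs$var
    if (update_stats) {
      state$mean <- momentum * state$mean + (1 - momentum) * mu
      state$var <- momentum * state$var + (1 - momentum) * va
    }
  } else {
    mu <- state$mean
    va <- state$var
  }
  istd <- 1 / sqrt(va + eps)
  v <- cpp_affine_cols(xv, gv * istd, bv - mu * istd * gv)
  ad_node(v, list(x, gamma, beta), function(g) {
    r <- cpp_bn_bwd(g, xv, gv, mu, istd, training)
    list(r$dx, r$dgamma, r$dbeta)
  })
}

# layer normalization across columns of each row
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  gv <- gamma$value; bv <- beta$value
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xh <- xc * istd
  v <- sweep(sweep(xh, 2, gv, "*"), 2, bv, "+")
  ad_node(v, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xh)
    dbeta <- colSums(g)
    gxh <- sweep(g, 2, gv, "*")
    dx <- istd * (gxh - rowMeans(gxh) - xh * rowMeans(gxh * xh))
    list(dx, dgamma, dbeta)
  })
}

# L2-normalize each row (contrastive embeddings)
ad_l2norm_rows <- function(x, eps = 1e-12) {
  xv <- x$value
  nr <- sqrt(rowSums(xv^2)) + eps
  v <- xv / nr
  ad_node(v, list(x), function(g) {
    list(g / nr - v * (rowSums(g * v) / nr))
  })
}
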