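# Trilevel adaptation objective: discriminator, adversarial confusion,
# contrastive regularization, covariance alignment, and update routing.

test_that("the discriminator is a bounded two-layer perceptron", {
  D0 <- init_discriminator(8L, seed = 1L)
  for (nm in names(D0)) D0[[nm]][] <- 0
  expect_equal(discriminator_forward(rnorm(8), D0), 0.5)
  D <- init_discriminator(8L, seed = 1L)
  set.seed(2)
  p <- discriminator_forward(matrix(rnorm(40), 5, 8), D)
  expect_true(all(p > 0 & p < 1))
})

test_that("discriminator BCE matches closed forms", {
  expect_equal(discriminator_loss(0.5, 0), log(2), tolerance = 1e-12)
  expect_equal(discriminator_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(discriminator_loss(0.8, 1), -log(0.8), tolerance = 1e-12)
  expect_lt(discriminator_loss(1 - 1e-9, 1), 1e-6)
})

test_that("the confusion loss is minimized exactly at maximal uncertainty", {
  expect_equal(adversarial_confusion_loss(0.5), log(2), tolerance = 1e-12)
  expect_equal(adversarial_confusion_loss(0.9),
               -0.5 * (log(0.9) + log(0.1)), tolerance = 1e-12)
  # symmetry and global minimum at 1/2
  ps <- seq(0.01, 0.99, by = 0.01)
  ls <- vapply(ps, adversarial_confusion_loss, numeric(1))
  expect_equal(ls, rev(ls), tolerance = 1e-12)
  expect_equal(ps[which.min(ls)], 0.5)
  expect_true(all(ls >= log(2) - 1e-12))
  # stationary at the minimum: numerical derivative ~ 0
  h <- 1e-6
  expect_lt(abs(adversarial_confusion_loss(0.5 + h) -
                adversarial_confusion_loss(0.5 - h)) / (2 * h), 1e-6)
})

test_that("temperature-scaled similarity matches hand values", {
  z <- c(1, 0, 0)
  expect_equal(similarity(z, z, 0.1), 10, tolerance = 1e-12)
  expect_equal(similarity(c(1, 0), c(0, 1), 0.1), 0, tolerance = 1e-12)
  expect_equal(similarity(c(2, 0), c(-3, 0), 0.5), -2, tolerance = 1e-12)
  # defensive normalization: magnitudes do not matter
  expect_equal(similarity(5 * z, 0.3 * z, 0.1), 10, tolerance = 1e-12)
})

test_that("contrastive loss matches closed forms and the batched kernel", {
  a <- c(1, 0, 0, 0)
  # equal similarities with 3 negatives: -log(1/4)
  negs <- list(a, a, a)
  expect_equal(contrastive_loss(a, a, negs, temperature = 1), log(4),
               tolerance = 1e-12)
  # hand case: s+ = 2, two negatives at 0
  l <- -log(exp(2) / (exp(2) + 2))
  z_pos <- c(cos(0), sin(0)); anchor <- c(1, 0)
  expect_equal(contrastive_loss(c(1, 0), c(1, 0),
                                list(c(0, 1), c(0, -1)), temperature = 0.5),
               l, tolerance = 1e-10)
  # dominant positive drives the loss to zero
  expect_lt(contrastive_loss(c(1, 0), c(1, 0), list(c(0, 1)), temperature = 0.01),
            1e-6)
  expect_error(contrastive_loss(a, a, list()), "negative")
  # batched tape kernel equals the per-anchor average of the plain function
  set.seed(3)
  m <- 4L
  z <- matrix(rnorm(2 * m * 5), 2 * m, 5)
  z <- z / sqrt(rowSums(z^2))
  tau <- 0.2
  node <- damlm:::ad_infonce(damlm:::ad_leaf(z), m, tau)
  manual <- mean(vapply(seq_len(2 * m), function(i) {
    pos <- if (i <= m) i + m else i - m
    cand <- if (i <= m) (m + 1):(2 * m) else 1:m
    negs <- setdiff(cand, pos)
    contrastive_loss(z[i, ], z[pos, ], lapply(negs, function(j) z[j, ]), tau)
  }, numeric(1)))
  expect_equal(as.numeric(node$value), manual, tolerance = 1e-10)
})

test_that("covariance alignment matches an explicit double-loop oracle", {
  # identical batches: zero
  set.seed(4)
  A <- matrix(rnorm(20), 5, 4)
  expect_equal(covariance_loss(A, A), 0, tolerance = 1e-12)
  # symmetry
  B <- matrix(rnorm(20), 5, 4)
  expect_equal(covariance_loss(A, B), covariance_loss(B, A), tolerance = 1e-12)
  # 2D two-point toy: exact value 8
  fb <- rbind(c(1, 0), c(-1, 0)); fr <- rbind(c(0, 1), c(0, -1))
  expect_equal(covariance_loss(fb, fr), 8, tolerance = 1e-12)
  # double-loop covariance oracle on random batches
  oracle_cov <- function(X) {
    n <- nrow(X); mu <- colMeans(X)
    S <- matrix(0, ncol(X), ncol(X))
    for (i in seq_len(n))
      S <- S + tcrossprod(X[i, ] - mu)
    S / (n - 1)
  }
  for (rep in 1:5) {
    X <- matrix(rnorm(20), 5, 4); Y <- matrix(rnorm(24), 6, 4)
    expect_equal(covariance_loss(X, Y),
                 sum((oracle_cov(X) - oracle_cov(Y))^2), tolerance = 1e-10)
  }
  expect_error(covariance_loss(A[1, , drop = FALSE], B), "2 samples")
})

test_that("the combined objective is the weighted sum of its terms", {
  w <- adaptation_weights()          # 0.5 / 1.0 / 0.1
  expect_equal(combine_domain_losses(1, 1, 1, w), 1.6, tolerance = 1e-12)
  w0 <- adaptation_weights(0, 0, 0)
  expect_equal(combine_domain_losses(5, 7, 9, w0), 0)
  # zeroing one term reproduces the matching ablation
  expect_equal(combine_domain_losses(1, 1, 1, adaptation_weights(lambda_adv = 0)),
               1.1, tolerance = 1e-12)
})

test_that("discriminator training separates linearly separable domains", {
  set.seed(5)
  g <- rbind(matrix(rnorm(50 * 4, -1), 50, 4), matrix(rnorm(50 * 4, 1), 50, 4))
  y <- c(rep(0, 50), rep(1, 50))
  disc <- init_discriminator(4L, seed = 2L)
  opt <- adamw_init(disc)
  losses <- numeric(100)
  for (i in 1:100) {
    st <- discriminator_step(disc, opt, g, y, lr = 5e-3)
    disc <- st$disc; opt <- st$opt; losses[i] <- st$loss
  }
  expect_lt(losses[100], 0.5 * losses[1])
  # broadly monotone: smoothed trajectory never increases
  sm <- stats::filter(losses, rep(1 / 5, 5), sides = 1)[5:100]
  expect_true(all(diff(sm) < 1e-3))
})

test_that("gradient-reversal and confusion-loss formulations give equal encoder updates", {
  set.seed(6)
  g <- matrix(rnorm(6 * 8), 6, 8)
  disc <- init_discriminator(8L, seed = 3L)
  lam <- 0.5
  enc_grad <- function(grl) {
    leaf <- damlm:::ad_leaf(g); leaf$param <- TRUE
    Dc <- damlm:::wrap_params(disc)
    gin <- if (grl) damlm:::ad_gradscale(leaf, -1) else leaf
    p <- damlm:::fwd_discriminator(Dc, gin)
    l <- damlm:::ad_confusion(p)
    total <- damlm:::ad_wsum(list(l), if (grl) -lam else lam)
    damlm:::ad_backward(total)
    leaf$grad
  }
  expect_equal(enc_grad(TRUE), enc_grad(FALSE), tolerance = 1e-12)
})

test_that("gradient descent on the covariance loss aligns linearly shifted domains", {
  set.seed(1)
  C <- 3L
  zB <- matrix(rnorm(40 * C), 40, C)
  M <- diag(C) + 0.4 * matrix(rnorm(C * C), C, C)
  zR <- matrix(rnorm(40 * C), 40, C) %*% M
  A <- diag(C)                       # learnable map applied to domain R
  gap0 <- sqrt(covariance_loss(zB, zR %*% A))   # Frobenius norm of the gap
  lr <- 0.08
  for (i in 1:500) {
    leaf <- damlm:::ad_leaf(A); leaf$param <- TRUE
    mapped <- damlm:::ad_matmul(damlm:::ad_leaf(zR), leaf)
    l <- damlm:::ad_cov_loss(damlm:::ad_leaf(zB), mapped)
    damlm:::ad_backward(l)
    A <- A - lr * leaf$grad
  }
  expect_lt(sqrt(covariance_loss(zB, zR %*% A)), 0.01 * gap0)
})

test_that("one adversarial alternation pushes domain predictions toward 1/2", {
  # 2-point toy: fixed, well-separated embeddings; a pre-trained confident
  # discriminator; one encoder step on the confusion loss must reduce the
  # mean distance of predictions from 1/2
  set.seed(7)
  emb <- rbind(rep(-1, 4), rep(1, 4))
  disc <- init_discriminator(4L, seed = 4L)
  opt <- adamw_init(disc)
  for (i in 1:200) {
    st <- discriminator_step(disc, opt, emb, c(0, 1), lr = 1e-2)
    disc <- st$disc; opt <- st$opt
  }
  p0 <- discriminator_forward(emb, disc)
  expect_gt(mean(abs(p0 - 0.5)), 0.2)  # discriminator is confident
  leaf <- damlm:::ad_leaf(emb); leaf$param <- TRUE
  p <- damlm:::fwd_discriminator(damlm:::wrap_params(disc), leaf)
  l <- damlm:::ad_confusion(p)
  damlm:::ad_backward(l)
  emb2 <- emb - 0.5 * leaf$grad      # one gradient step on the embeddings
  p1 <- discriminator_forward(emb2, disc)
  expect_lt(mean(abs(p1 - 0.5)), mean(abs(p0 - 0.5)))
})
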