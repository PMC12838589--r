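# Optimization machinery: splits, batching, augmentation, schedule, AdamW,
# batch statistics, loss assembly and the fitted-model interface.

test_that("stratified splits allocate by largest remainder per class", {
  s <- stratified_split(rep(0, 100), split_spec(c(0.70, 0.15, 0.15)))
  expect_equal(lengths(s), c(train = 70L, val = 15L, test = 15L))
  s2 <- stratified_split(rep(0, 10), split_spec(c(0.80, 0.10, 0.10)))
  expect_equal(lengths(s2), c(train = 8L, val = 1L, test = 1L))
  # two classes 60/40: train gets 42/28
  labs <- c(rep(0, 60), rep(1, 40))
  s3 <- stratified_split(labs, split_spec(c(0.70, 0.15, 0.15)))
  expect_equal(sum(labs[s3$train] == 0), 42L)
  expect_equal(sum(labs[s3$train] == 1), 28L)
  # disjoint and exhaustive
  all_idx <- sort(as.integer(unlist(s3)))
  expect_equal(all_idx, seq_along(labs))
  # deterministic given seed, different across seeds
  expect_identical(stratified_split(labs, split_spec(seed = 5L)),
                   stratified_split(labs, split_spec(seed = 5L)))
  expect_false(identical(stratified_split(labs, split_spec(seed = 5L)),
                         stratified_split(labs, split_spec(seed = 6L))))
  expect_error(split_spec(c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("mixed batches are half-and-half without replacement", {
  b <- make_mixed_batches(1:20, 21:40, batch_size = 16L, seed = 1L)
  expect_equal(length(b), 2L)
  for (bt in b) {
    expect_length(bt$source, 8L)
    expect_length(bt$target, 8L)
    expect_true(all(bt$source <= 20) && all(bt$target >= 21))
  }
  # no repeats within the epoch
  expect_false(any(duplicated(c(b[[1]]$source, b[[2]]$source))))
  # pools of 8 + 8 with batch 16: a single batch holding every item
  b2 <- make_mixed_batches(1:8, 9:16, batch_size = 16L, seed = 2L)
  expect_equal(length(b2), 1L)
  expect_setequal(c(b2[[1]]$source, b2[[1]]$target), 1:16)
  expect_identical(make_mixed_batches(1:20, 21:40, 16L, seed = 3L),
                   make_mixed_batches(1:20, 21:40, 16L, seed = 3L))
  expect_error(make_mixed_batches(1:4, 5:8, batch_size = 7L), "even")
  expect_error(make_mixed_batches(integer(0), 1:4, 4L), "nonempty")
})

test_that("augmentation honors its toggles and printed bounds", {
  set.seed(1)
  X <- array(rnorm(10^3 * 4), dim = c(10, 10, 10, 4))
  rm_ <- array(sample(0:3, 1000, TRUE), dim = c(10, 10, 10))
  bm_ <- array(1L, dim = c(10, 10, 10))
  off <- list(elastic = FALSE, intensity = FALSE, rotation = FALSE, dropout = FALSE)
  a0 <- augment_patch(X, rm_, bm_, off, seed = 1L)
  expect_identical(a0$X, X)
  expect_identical(a0$region_mask, rm_)
  # intensity-only: any change is a global scale within +/- 10%
  int_only <- list(elastic = FALSE, intensity = TRUE, rotation = FALSE,
                   dropout = FALSE)
  for (s in 1:20) {
    a <- augment_patch(X, rm_, bm_, int_only, seed = s)
    ratio <- a$X[abs(X) > 1e-8] / X[abs(X) > 1e-8]
    expect_true(all(abs(ratio - ratio[1]) < 1e-12))
    expect_true(abs(ratio[1] - 1) <= 0.10 + 1e-12)
  }
  # geometric ops keep masks on the label alphabet and co-transform them
  geo <- list(elastic = TRUE, intensity = FALSE, rotation = TRUE, dropout = FALSE)
  a2 <- augment_patch(X, rm_, bm_, geo, seed = 7L)
  expect_true(all(a2$region_mask %in% 0:3))
  expect_identical(dim(a2$X), dim(X))
  # determinism
  expect_identical(augment_patch(X, rm_, bm_, geo, seed = 9L),
                   augment_patch(X, rm_, bm_, geo, seed = 9L))
})

test_that("the cosine schedule hits its closed-form anchors", {
  expect_equal(cosine_lr(0, 1000), 3e-4, tolerance = 1e-15)
  expect_equal(cosine_lr(1000, 1000), 1e-6, tolerance = 1e-15)
  expect_equal(cosine_lr(500, 1000), (3e-4 + 1e-6) / 2, tolerance = 1e-15)
  # closed form at every step
  T_ <- 40
  for (t in 0:T_) {
    expect_equal(cosine_lr(t, T_, 0.01, 0.001),
                 0.001 + 0.5 * (0.01 - 0.001) * (1 + cos(pi * t / T_)),
                 tolerance = 1e-15)
  }
  expect_error(cosine_lr(5, 4))
})

test_that("AdamW updates match hand-derived steps", {
  p <- list(w = c(1, -2, 3))
  opt <- adamw_init(p)
  # zero gradients, no decay: untouched
  up <- adamw_step(p, list(w = c(0, 0, 0)), opt, lr = 0.1, weight_decay = 0)
  expect_equal(up$params$w, p$w, tolerance = 1e-12)
  # zero gradients with decay: pure multiplicative shrinkage
  up2 <- adamw_step(p, list(w = c(0, 0, 0)), opt, lr = 0.1, weight_decay = 0.01)
  expect_equal(up2$params$w, p$w * (1 - 0.1 * 0.01), tolerance = 1e-12)
  # first bias-corrected step from theta = 0, g = 1
  p0 <- list(w = 0)
  st <- adamw_step(p0, list(w = 1), adamw_init(p0), lr = 0.05, weight_decay = 0)
  expect_equal(st$params$w, -0.05 / (1 + 1e-8), tolerance = 1e-12)
  expect_equal(st$opt$t, 1L)
})

test_that("joint batch statistics pool the mixed batch, never per domain", {
  a <- matrix(2.5, 6, 3)
  js <- joint_batch_stats(a)
  expect_equal(js$mean, rep(2.5, 3))
  expect_equal(js$var, rep(0, 3))
  # equal halves with means m0 and m1 pool to their midpoint
  half <- rbind(matrix(1, 4, 2), matrix(3, 4, 2))
  expect_equal(joint_batch_stats(half)$mean, c(2, 2))
  # double-loop oracle on random activations
  set.seed(2)
  act <- matrix(rnorm(16 * 8), 16, 8)
  js2 <- joint_batch_stats(act)
  for (c in 1:8) {
    m <- 0; for (i in 1:16) m <- m + act[i, c]
    m <- m / 16
    v <- 0; for (i in 1:16) v <- v + (act[i, c] - m)^2
    expect_equal(js2$mean[c], m, tolerance = 1e-10)
    expect_equal(js2$var[c], v / 16, tolerance = 1e-10)
  }
})

test_that("the total objective composes linearly", {
  expect_equal(total_loss(2, 3, 4, lambda_DA = 0, lambda_seg = 0), 2)
  expect_equal(total_loss(1, 1, 1, lambda_DA = 1, lambda_seg = 1), 3)
  expect_equal(total_loss(1, 2, 3, lambda_DA = 0.5, lambda_seg = 2), 6.5)
  expect_equal(combined_val_score(0.9, 0.8, 1), 0.9)
  expect_equal(combined_val_score(0.9, 0.8, 0.5), 0.85)
  a <- combined_val_score(0.7, 0.9, 0.3)
  expect_true(a >= 0.7 && a <= 0.9)
})

test_that("fitting runs, records history, and is reproducible bit for bit", {
  ds <- tiny_dataset(n = 6L)
  cfg <- tiny_train_config(epochs = 2L)
  f1 <- damlm_fit(ds, tiny_model_config(), cfg, adaptation_weights(), seed = 11L)
  f2 <- damlm_fit(ds, tiny_model_config(), cfg, adaptation_weights(), seed = 11L)
  expect_identical(f1$history, f2$history)
  for (nm in names(f1$weights)) expect_identical(f1$weights[[nm]], f2$weights[[nm]])
  expect_equal(nrow(f1$history), 2L)
  expect_true(all(c("loss_total", "loss_cls", "loss_adv", "loss_con",
                    "loss_cov", "loss_disc", "lr", "alpha_val") %in%
                  names(f1$history)))
  expect_true(all(is.finite(unlist(f1$weights))))
  # predictions have the right shape and type
  pr <- predict(f1, ds$volumes[1:3], type = "prob")
  expect_equal(dim(pr), c(3L, 2L))
  expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-9)
  expect_true(all(predict(f1, ds$volumes[1:2]) %in% 0:1))
  emb <- predict(f1, ds$volumes[1:2], type = "embedding")
  expect_equal(dim(emb), c(2L, 8L))
  # method surface
  expect_output(print(f1), "hybrid")
  expect_output(print(summary(f1)), "parameters")
  expect_named(coef(f1))
  pdf(NULL); plot(f1); dev.off()
})

test_that("early stopping obeys the patience contract exactly", {
  ds <- tiny_dataset(n = 6L)
  cfg <- tiny_train_config(epochs = 10L)
  cfg$patience <- 1L
  # strictly worsening injected validation score: stop after exactly 2 epochs
  fit <- damlm_fit(ds, tiny_model_config(), cfg, adaptation_weights(), seed = 1L,
                   .val_score_fn = function(epoch, a, b) 1 - 0.1 * epoch)
  expect_equal(nrow(fit$history), 2L)
  expect_equal(fit$best_epoch, 1L)
})

test_that("with adaptation off, the discriminator cannot influence the encoder", {
  ds <- tiny_dataset(n = 6L)
  cfg <- tiny_train_config(epochs = 2L)
  off <- adaptation_weights(0, 0, 0)
  f1 <- damlm_fit(ds, tiny_model_config(), cfg, off, seed = 4L)
  f2 <- damlm_fit(ds, tiny_model_config(), cfg, off, seed = 4L,
                  .disc_seed = 99L)   # different discriminator trajectory
  expect_identical(f1$history$loss_cls, f2$history$loss_cls)
  for (nm in names(f1$weights)) expect_identical(f1$weights[[nm]], f2$weights[[nm]])
  expect_false(identical(f1$disc, f2$disc))
})

test_that("degenerate datasets are rejected", {
  ds <- tiny_dataset(n = 4L)
  only_src <- list(volumes = ds$volumes[ds$manifest$domain == 0],
                   manifest = ds$manifest[ds$manifest$domain == 0, ])
  expect_error(damlm_fit(only_src, tiny_model_config(), tiny_train_config()),
               "both domains")
})
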