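# Metrics and measurement harnesses, each checked against brute-force
# oracles or hand evaluations.

test_that("classification metrics match hand evaluation", {
  m <- classification_metrics(c(0, 0, 1), c(0, 1, 1))
  expect_equal(m$acc, 2 / 3, tolerance = 1e-12)
  expect_equal(m$f1_macro, 2 / 3, tolerance = 1e-12)
  # balanced accuracy identity
  expect_equal(m$bal_acc, (m$sensitivity + m$specificity) / 2, tolerance = 1e-15)
  expect_error(classification_metrics(integer(0), integer(0)), "empty")
})

test_that("metrics equal brute-force oracles on random problems", {
  oracle_auc <- function(lab, sc) {
    pos <- sc[lab == 1]; neg <- sc[lab == 0]
    tot <- 0
    for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(10:60, 1); K <- sample(2:4, 1)
    y <- sample(0:(K - 1), n, replace = TRUE)
    if (length(unique(y)) < K) next
    pred <- sample(0:(K - 1), n, replace = TRUE)
    sc <- matrix(runif(n * K), n, K)
    sc <- sc / rowSums(sc)
    if (rep %% 3 == 0) sc <- round(sc, 1)   # force score ties
    m <- classification_metrics(y, pred, sc, K = K)
    expect_equal(m$acc, sum(y == pred) / n, tolerance = 1e-12)
    # macro F1 oracle
    f1s <- sapply(0:(K - 1), function(k) {
      tp <- sum(pred == k & y == k); fp <- sum(pred == k & y != k)
      fn <- sum(pred != k & y == k)
      pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
      if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    })
    expect_equal(m$f1_macro, mean(f1s), tolerance = 1e-12)
    for (k in 0:(K - 1)) {
      expect_equal(m$auc_per_class[k + 1],
                   oracle_auc(as.integer(y == k), sc[, k + 1]), tolerance = 1e-9)
    }
  }
  # perfect ranking gives AUC 1; monotone transforms leave it unchanged
  lab <- c(0, 0, 1, 1); sc <- c(0.1, 0.2, 0.8, 0.9)
  expect_equal(roc_auc(lab, sc), 1)
  set.seed(11)
  lab2 <- rbinom(40, 1, 0.5); sc2 <- runif(40)
  expect_equal(roc_auc(lab2, sc2), roc_auc(lab2, exp(3 * sc2)), tolerance = 1e-12)
})

test_that("region overlap scores follow the nested WT/TC/ET convention", {
  m <- array(sample(0:3, 4^3, TRUE), dim = c(4, 4, 4))
  dj <- region_dice_jaccard(m, m)
  expect_equal(dj$dice, rep(1, 3))
  expect_equal(dj$jaccard, rep(1, 3))
  # hand toy: pred 4 voxels, truth 6, overlap 3 (single region type)
  p <- array(0L, dim = c(4, 4, 4)); g <- array(0L, dim = c(4, 4, 4))
  g[1:6] <- 3L; p[4:7] <- 3L
  dj2 <- region_dice_jaccard(p, g)
  expect_equal(dj2$dice[dj2$region == "ET"], 0.6, tolerance = 1e-12)
  expect_equal(dj2$jaccard[dj2$region == "ET"], 3 / 7, tolerance = 1e-12)
  # dice = 2J/(1+J) on random masks
  set.seed(12)
  for (rep in 1:10) {
    a <- array(sample(0:3, 64, TRUE), dim = c(4, 4, 4))
    b <- array(sample(0:3, 64, TRUE), dim = c(4, 4, 4))
    dj3 <- region_dice_jaccard(a, b)
    expect_equal(dj3$dice, 2 * dj3$jaccard / (1 + dj3$jaccard), tolerance = 1e-9)
  }
  # empty-vs-empty convention
  z <- array(0L, dim = c(2, 2, 2))
  expect_equal(region_dice_jaccard(z, z)$dice, rep(1, 3))
})

test_that("cross-domain evaluation matches manual recomputation", {
  tt <- trained_tiny_fit()
  vols <- tt$ds$volumes[tt$fit$pools$test$tgt]
  ce <- cross_domain_eval(tt$fit, vols)
  y <- vapply(vols, `[[`, integer(1), "class_label")
  pr <- predict(tt$fit, vols, type = "prob")
  manual <- classification_metrics(y, max.col(pr) - 1L, pr, K = 2L)
  expect_equal(ce$metrics$acc, manual$acc)
  expect_equal(ce$metrics$f1_macro, manual$f1_macro)
  expect_equal(ce$mean_loss, classification_loss(pr, one_hot(y, 2L)),
               tolerance = 1e-12)
  # a maximally uninformative classifier scores cross-entropy log(2)
  unif <- tt$fit
  unif$weights$cls.w[] <- 0; unif$weights$cls.b[] <- 0
  ce2 <- cross_domain_eval(unif, vols)
  expect_equal(ce2$mean_loss, log(2), tolerance = 1e-9)
})

test_that("relative degradation is zero at identity and consistent with its ratio", {
  tt <- trained_tiny_fit()
  vols <- tt$ds$volumes[c(tt$fit$pools$test$src, tt$fit$pools$test$tgt)]
  rep_id <- robustness_degradation(tt$fit, vols, kinds = "gaussian_noise",
                                   severities = "none")
  expect_equal(rep_id$table$r_deg, 0, tolerance = 1e-12)
  rp <- robustness_degradation(tt$fit, vols, kinds = "gaussian_noise",
                               severities = c("low", "high"), seed = 1L)
  expect_equal(rp$table$r_deg, 1 - rp$table$metric / rp$baseline,
               tolerance = 1e-12)
  # arithmetic of the ratio itself
  expect_equal(1 - 0.81 / 0.9, 0.1, tolerance = 1e-12)
})

test_that("scanner-shift displacement preserves sign and is zero at identity", {
  tt <- trained_tiny_fit()
  vols <- tt$ds$volumes[c(tt$fit$pools$test$src, tt$fit$pools$test$tgt)]
  d0 <- scanner_shift_eval(tt$fit, vols, profiles = "identity")
  expect_equal(d0$d_shift, 0, tolerance = 1e-12)
  d1 <- scanner_shift_eval(tt$fit, vols, profiles = c("low_field", "bias_field"))
  expect_equal(d1$d_shift, attr(d1, "baseline") - d1$metric, tolerance = 1e-12)
})

test_that("stability intervals follow the five-run convention", {
  s <- stability_ci(rep(90, 5))
  expect_equal(s$mean, 90); expect_equal(s$ci95_halfwidth, 0)
  s2 <- stability_ci(1:5)
  expect_equal(s2$mean, 3)
  expect_equal(s2$sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(s2$ci95_halfwidth, 1.96 * sqrt(2.5) / sqrt(5), tolerance = 1e-12)
  # halfwidth scales as 1/sqrt(n)
  x <- rep(c(1, 2), 10)
  h20 <- stability_ci(x)$ci95_halfwidth
  h5 <- stability_ci(x[1:5])$ci95_halfwidth
  expect_equal(h20 / h5, (stats::sd(x) / stats::sd(x[1:5])) * sqrt(5 / 20),
               tolerance = 1e-12)
})

test_that("paired t-tests handle degeneracies and match the closed form", {
  expect_equal(paired_metric_ttest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_warning(r <- paired_metric_ttest(c(2, 3, 4), c(1, 2, 3)), "zero-variance")
  expect_equal(r$p, 0)
  # diffs {1, 2, 3}: t = mean/(sd/sqrt(n)) = 2 / (1/sqrt(3))
  a <- c(2, 4, 6); b <- c(1, 2, 3)
  out <- paired_metric_ttest(a, b)
  expect_equal(out$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(out$p, 2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-9)
  expect_false(out$significant)
})

test_that("the ablation harness tabulates one row per configuration", {
  ds <- tiny_dataset(n = 6L)
  tc <- tiny_train_config(epochs = 1L)
  tab0 <- ablation_harness(ds, tiny_model_config(), tc, adaptation_weights(),
                           components = character(0), seeds = 0L)
  expect_equal(nrow(tab0), 1L)
  expect_equal(tab0$configuration, "full")
  tab <- ablation_harness(ds, tiny_model_config(), tc, adaptation_weights(),
                          components = c("no_adv", "cnn_only"), seeds = 0:1)
  expect_equal(nrow(tab), 3L)
  runs <- attr(tab, "runs")
  expect_equal(tab$mean_acc, unname(rowMeans(runs)), tolerance = 1e-12)
})
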