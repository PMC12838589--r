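# Measurement machinery: classification metrics, overlap scores for nested
# tumor regions, cross-domain transfer evaluation, perturbation robustness
# (relative degradation), scanner-shift displacement, multi-seed stability
# intervals, paired t-tests, and the ablation harness.

#' Classification metrics
#'
#' Accuracy, macro-F1 (one-vs-rest precision/recall, 0/0 treated as 0),
#' per-class and macro one-vs-rest ROC AUC (trapezoidal rule with tied
#' scores grouped per threshold), sensitivity/specificity (binary, or
#' macro-averaged one-vs-rest for K > 2) and balanced accuracy.
#'
#' @param y_true,y_pred Integer labels in 0..K-1.
#' @param scores Optional n x K matrix of per-class probabilities (enables
#'   the AUC entries).
#' @param K Class count (inferred when missing).
#' @return List of metrics (class `metric_report`).
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL, K = NULL) {
  n <- length(y_true)
  if (n == 0L) stop("empty input")
  stopifnot(length(y_pred) == n)
  if (is.null(K)) K <- max(y_true, y_pred) + 1L
  acc <- mean(y_true == y_pred)
  f1 <- sens <- spec <- auc <- numeric(K)
  for (k in seq_len(K) - 1L) {
    tp <- sum(y_pred == k & y_true == k)
    fp <- sum(y_pred == k & y_true != k)
    fn <- sum(y_pred != k & y_true == k)
    tn <- sum(y_pred != k & y_true != k)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[k + 1] <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    sens[k + 1] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec[k + 1] <- if (tn + fp == 0) 0 else tn / (tn + fp)
    if (!is.null(scores))
      auc[k + 1] <- roc_auc(as.integer(y_true == k), scores[, k + 1])
  }
  if (K == 2L) {
    # binary convention: class 1 is the positive class
    sensitivity <- sens[2]; specificity <- spec[2]
  } else {
    sensitivity <- mean(sens); specificity <- mean(spec)
  }
  structure(list(
    acc = acc, f1_macro = mean(f1), f1_per_class = f1,
    auc_per_class = if (is.null(scores)) NULL else auc,
    auc_macro = if (is.null(scores)) NA_real_ else mean(auc),
    sensitivity = sensitivity, specificity = specificity,
    bal_acc = (sensitivity + specificity) / 2, n = n, K = K),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("n=%d  Acc=%.4f  F1_macro=%.4f  AUC=%.4f  Sens=%.4f  Spec=%.4f  BalAcc=%.4f\n",
              x$n, x$acc, x$f1_macro, x$auc_macro, x$sensitivity,
              x$specificity, x$bal_acc))
  invisible(x)
}

#' One-vs-rest ROC AUC by the trapezoidal rule
#'
#' Thresholds sweep the distinct score values (ties grouped), tracing the
#' ROC from (0,0) to (1,1); the area is accumulated trapezoid by trapezoid.
#'
#' @param labels Binary 0/1 vector.
#' @param score Numeric scores (higher = more positive).
#' @return AUC in [0, 1]; NA when only one class is present.
#' @export
roc_auc <- function(labels, score) {
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  lab <- labels[ord]; sc <- score[ord]
  grp <- cumsum(!duplicated(sc))
  tp_g <- rowsum(as.numeric(lab == 1), grp)
  fp_g <- rowsum(as.numeric(lab == 0), grp)
  tpr <- c(0, cumsum(tp_g) / P)
  fpr <- c(0, cumsum(fp_g) / N)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Dice and Jaccard for the nested tumor regions
#'
#' Regions follow the standard nesting: whole tumor (WT) = edema, core and
#' enhancing; tumor core (TC) = core and enhancing; enhancing tumor (ET) =
#' enhancing only. Two empty masks score 1 by convention.
#'
#' @param pred,truth Integer region grids (0 background, 1 edema, 2
#'   core/necrosis, 3 enhancing).
#' @return Data frame with one row per region (`region`, `dice`, `jaccard`).
#' @export
region_dice_jaccard <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  sel <- list(WT = c(1L, 2L, 3L), TC = c(2L, 3L), ET = 3L)
  rows <- lapply(names(sel), function(r) {
    p <- pred %in% sel[[r]]
    g <- truth %in% sel[[r]]
    i <- sum(p & g); u <- sum(p | g); sp <- sum(p); sg <- sum(g)
    if (sp + sg == 0) {
      dice <- 1; jac <- 1
    } else {
      dice <- 2 * i / (sp + sg)
      jac <- i / u
    }
    data.frame(region = r, dice = dice, jaccard = jac)
  })
  do.call(rbind, rows)
}

#' Cross-domain transfer evaluation
#'
#' Evaluates a trained model on a held-out set with no fine-tuning,
#' returning the mean per-sample cross-entropy and the full metric report.
#'
#' @param fit A fitted [damlm_fit()] model.
#' @param volumes List of `labeled_volume`s (the target-domain test set for
#'   src -> tgt transfer).
#' @return List with `metrics` (a `metric_report`) and `mean_loss`.
#' @export
cross_domain_eval <- function(fit, volumes) {
  stopifnot(inherits(fit, "damlm"))
  y <- vapply(volumes, `[[`, integer(1), "class_label")
  pr <- predict(fit, volumes, type = "prob")
  cls <- max.col(pr, ties.method = "first") - 1L
  mean_loss <- classification_loss(pr, one_hot(y, fit$n_classes))
  list(metrics = classification_metrics(y, cls, pr, K = fit$n_classes),
       mean_loss = mean_loss)
}

.eval_metric <- function(fit, volumes, metric = c("accuracy", "wt_dice")) {
  metric <- match.arg(metric)
  if (metric == "accuracy") {
    y <- vapply(volumes, `[[`, integer(1), "class_label")
    mean(predict(fit, volumes, type = "class") == y)
  } else {
    scores <- vapply(volumes, function(v) {
      samp <- .make_sample(v, fit$train_config)
      pr <- segment_decode(samp$X, fit$model_config, fit$weights, fit$state)
      pm <- array(max.col(matrix(pr, ncol = dim(pr)[4]), ties.method = "first") - 1L,
                  dim = dim(pr)[1:3])
      dj <- region_dice_jaccard(pm, array(samp$region, dim = dim(pr)[1:3]))
      dj$dice[dj$region == "WT"]
    }, numeric(1))
    mean(scores)
  }
}

#' Perturbation robustness: relative degradation ratio
#'
#' For every (kind, severity) pair, perturbs each evaluation volume with a
#' severity-specific fixed seed and reports
#' `R_deg = 1 - M(perturbed) / M(baseline)`; smaller values mean greater
#' robustness, identity perturbations give exactly 0. A zero baseline makes
#' the ratio undefined and is reported as NA with a warning.
#'
#' @param fit A fitted model.
#' @param volumes Evaluation volumes.
#' @param kinds Perturbation kinds to test.
#' @param severities Severity levels.
#' @param metric `"accuracy"` or `"wt_dice"`.
#' @param seed Base seed for the perturbation draws.
#' @return Object of class `robustness_report`: data.frame of R_deg values
#'   plus the baseline metric.
#' @export
robustness_degradation <- function(fit, volumes, kinds = PERTURBATION_KINDS,
                                   severities = c("low", "medium", "high"),
                                   metric = "accuracy", seed = 0L) {
  baseline <- .eval_metric(fit, volumes, metric)
  rows <- list()
  for (k in kinds) {
    for (s in severities) {
      pv <- lapply(seq_along(volumes), function(i)
        apply_perturbation(volumes[[i]], perturbation_spec(k, s),
                           seed = derive_seed(seed, match(s, SEVERITY_LEVELS), i)))
      m <- .eval_metric(fit, pv, metric)
      r <- if (baseline == 0) {
        warning("baseline metric is 0; R_deg undefined")
        NA_real_
      } else 1 - m / baseline
      rows[[length(rows) + 1L]] <- data.frame(kind = k, severity = s,
                                              metric = m, r_deg = r)
    }
  }
  structure(list(table = do.call(rbind, rows), baseline = baseline,
                 metric = metric), class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness report (metric: %s, baseline %.4f)\n", x$metric, x$baseline))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Scanner-shift displacement
#'
#' `D_shift(S) = M_baseline - M_profile` on the metric's native scale; the
#' sign is preserved (an improvement under shift is reported as negative),
#' and the identity profile gives exactly 0.
#'
#' @param fit A fitted model.
#' @param volumes Evaluation volumes.
#' @param profiles Scanner profile ids or [scanner_profile()] objects.
#' @param metric `"accuracy"` or `"wt_dice"`.
#' @param seed Base seed for the profile field/noise draws.
#' @return Data frame with `profile`, `metric` and `d_shift`.
#' @export
scanner_shift_eval <- function(fit, volumes,
                               profiles = setdiff(SCANNER_PROFILES, "identity"),
                               metric = "accuracy", seed = 0L) {
  baseline <- .eval_metric(fit, volumes, metric)
  rows <- lapply(profiles, function(p) {
    prof <- if (is.character(p)) scanner_profile(p) else p
    pv <- lapply(seq_along(volumes), function(i)
      apply_scanner_profile(volumes[[i]], prof, seed = derive_seed(seed, i)))
    m <- .eval_metric(fit, pv, metric)
    data.frame(profile = prof$profile_id, metric = m, d_shift = baseline - m)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- baseline
  out
}

#' Multi-seed stability summary
#'
#' Mean, sample standard deviation (ddof = 1) and the 95% confidence-
#' interval halfwidth `1.96 * sd / sqrt(n)` over repeated runs.
#'
#' @param values Per-run metric values (default protocol: 5 seeded runs).
#' @return List with `mean`, `sd`, `ci95_halfwidth`, `lower`, `upper`, `n`.
#' @export
stability_ci <- function(values) {
  n <- length(values)
  stopifnot(n >= 1)
  m <- mean(values)
  s <- if (n > 1) stats::sd(values) else 0
  hw <- 1.96 * s / sqrt(n)
  list(mean = m, sd = s, ci95_halfwidth = hw, lower = m - hw, upper = m + hw, n = n)
}

#' Paired two-tailed t-test between metric runs
#'
#' Degenerate conventions: identical runs (all differences zero) return
#' p = 1; constant nonzero differences (zero variance) return p = 0 with a
#' warning. Otherwise delegates to the standard paired t-test.
#'
#' @param runs_a,runs_b Equal-length paired metric vectors (n >= 2).
#' @param alpha Significance threshold for the returned flag.
#' @return List with `t`, `p`, `significant`, `mean_diff`, `n`.
#' @export
paired_metric_ttest <- function(runs_a, runs_b, alpha = 0.05) {
  stopifnot(length(runs_a) == length(runs_b), length(runs_a) >= 2)
  d <- runs_a - runs_b
  if (all(d == 0))
    return(list(t = 0, p = 1, significant = FALSE, mean_diff = 0, n = length(d)))
  if (stats::sd(d) < .Machine$double.eps) {
    warning("zero-variance nonzero differences; p reported as 0")
    return(list(t = sign(mean(d)) * Inf, p = 0, significant = TRUE,
                mean_diff = mean(d), n = length(d)))
  }
  tt <- stats::t.test(runs_a, runs_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha, mean_diff = mean(d), n = length(d))
}

#' Ablation harness
#'
#' Retrains the model across seeds for the full configuration and each
#' requested ablation (`cnn_only`, `transformer_only`, `no_adv`, `no_con`,
#' `no_cov`), evaluates each run on the held-out target-domain test set, and
#' tabulates mean +/- sd with a paired t-test against the full model.
#'
#' @param dataset A paired dataset from [build_dataset()].
#' @param model_config Base [encoder_config()].
#' @param train_config A [damlm_config()].
#' @param adapt Base [adaptation_weights()].
#' @param components Character vector of ablations (may be empty).
#' @param seeds Integer seeds (one run per seed per configuration).
#' @return Data frame, one row per configuration.
#' @export
ablation_harness <- function(dataset, model_config = encoder_config(),
                             train_config = damlm_config(),
                             adapt = adaptation_weights(),
                             components = c("cnn_only", "transformer_only",
                                            "no_adv", "no_con", "no_cov"),
                             seeds = 0:4) {
  variants <- c(list(full = list(mc = model_config, ad = adapt)),
                stats::setNames(lapply(components, function(cm) {
                  mc <- model_config; ad <- adapt
                  switch(cm,
                         cnn_only = { mc$backbone_mode <- "cnn_only" },
                         transformer_only = {
                           mc$backbone_mode <- "transformer_only"
                           mc$seg_head <- FALSE
                         },
                         no_adv = { ad$lambda_adv <- 0 },
                         no_con = { ad$lambda_con <- 0 },
                         no_cov = { ad$lambda_cov <- 0 },
                         stop("unknown ablation component: ", cm))
                  list(mc = mc, ad = ad)
                }), components))
  run_acc <- matrix(NA_real_, length(variants), length(seeds),
                    dimnames = list(names(variants), NULL))
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    for (si in seq_along(seeds)) {
      fit <- damlm_fit(dataset, v$mc, train_config, v$ad, seed = seeds[si])
      test_tgt <- fit$pools$test$tgt
      run_acc[vi, si] <- if (length(test_tgt))
        .eval_metric(fit, dataset$volumes[test_tgt], "accuracy") else NA_real_
    }
  }
  rows <- lapply(seq_along(variants), function(vi) {
    ci <- stability_ci(run_acc[vi, ])
    p <- if (vi == 1L || length(seeds) < 2L) NA_real_
         else paired_metric_ttest(run_acc[1, ], run_acc[vi, ])$p
    data.frame(configuration = names(variants)[vi], mean_acc = ci$mean,
               sd_acc = ci$sd, ci95 = ci$ci95_halfwidth, p_vs_full = p)
  })
  out <- do.call(rbind, rows)
  attr(out, "runs") <- run_acc
  out
}
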