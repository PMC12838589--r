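# End-to-end optimization: stratified splits, mixed-domain batches,
# augmentation, AdamW with cosine decay, joint batch statistics, total-loss
# assembly, early stopping on a combined validation score, and the `damlm`
# fitted-model interface.

#' Split specification
#'
#' @param ratios Three nonnegative proportions summing to 1 (train/val/test).
#' @param stratify_by Name of the label used for stratification (metadata).
#' @param seed Integer seed for within-class shuffling.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(0.70, 0.15, 0.15), stratify_by = "class",
                       seed = 0L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  structure(list(ratios = as.numeric(ratios), stratify_by = stratify_by,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Stratified train/validation/test split
#'
#' Allocates each class proportionally with largest-remainder rounding, so
#' class proportions are preserved as closely as integer counts allow; the
#' three parts are disjoint and exhaustive, and the assignment is
#' deterministic given the spec's seed.
#'
#' @param labels Vector of class labels, one per sample.
#' @param spec A [split_spec()].
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(labels, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(83L, spec$seed))
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    raw <- n * spec$ratios
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      frac_order <- order(raw - base, decreasing = TRUE)
      base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
    }
    off <- cumsum(c(0, base))
    for (p in 1:3)
      parts[[p]] <- c(parts[[p]], idx[seq_len(base[p]) + off[p]])
  }
  lapply(parts, sort)
}

#' Deterministic mixed-domain batch plan for one epoch
#'
#' Shuffles each domain pool and emits batches holding exactly
#' `batch_size / 2` items from each domain, sampled without replacement
#' within the epoch; every batch therefore contains both domains.
#'
#' @param source_pool,target_pool Integer sample indices per domain.
#' @param batch_size Even batch size.
#' @param seed Integer seed.
#' @return List of batches, each a list with `source` and `target` indices.
#' @export
make_mixed_batches <- function(source_pool, target_pool, batch_size = 16L,
                               seed = 0L) {
  if (batch_size %% 2L != 0L) stop("batch_size must be even")
  if (length(source_pool) == 0L || length(target_pool) == 0L)
    stop("both domain pools must be nonempty")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(97L, seed))
  half <- batch_size %/% 2L
  s <- source_pool[sample.int(length(source_pool))]
  t <- target_pool[sample.int(length(target_pool))]
  nb <- min(length(s), length(t)) %/% half
  if (nb == 0L) stop("domain pools smaller than half a batch")
  lapply(seq_len(nb), function(b) {
    rows <- (b - 1L) * half + seq_len(half)
    list(source = s[rows], target = t[rows])
  })
}

#' Training-time augmentation of one patch
#'
#' Applies, each with independent probability 1/2: elastic deformation,
#' global intensity perturbation within +/-10%, rotation within +/-15
#' degrees about a random axis, and patch dropout (a random cuboid zeroed
#' across channels). Geometric operations co-transform the region and brain
#' masks; with all toggles off the function is the identity.
#'
#' @param X 4-D patch array (x, y, z, channel).
#' @param region_mask,brain_mask Integer label grids matching `X`.
#' @param config List of logical toggles `elastic`, `intensity`, `rotation`,
#'   `dropout` (see [damlm_config()]).
#' @param seed Integer seed.
#' @return List with augmented `X`, `region_mask`, `brain_mask`.
#' @export
augment_patch <- function(X, region_mask, brain_mask,
                          config = list(elastic = TRUE, intensity = TRUE,
                                        rotation = TRUE, dropout = TRUE),
                          seed = 0L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(101L, seed))
  gs <- dim(X)[1:3]
  warp_all <- function(src) {
    for (c in seq_len(dim(X)[4]))
      X[, , , c] <<- array(trilinear_sample(array(X[, , , c], gs), src), dim = gs)
    region_mask <<- array(as.integer(nearest_sample(region_mask, src)), dim = gs)
    brain_mask <<- array(as.integer(nearest_sample(brain_mask, src)), dim = gs)
  }
  if (isTRUE(config$elastic) && stats::runif(1) < 0.5) {
    disp <- .elastic_field(gs, max_disp = 2)
    co <- voxel_grid_coords(gs)
    warp_all(cbind(co[, 1] + as.vector(disp[[1]]), co[, 2] + as.vector(disp[[2]]),
                   co[, 3] + as.vector(disp[[3]])))
  }
  if (isTRUE(config$rotation) && stats::runif(1) < 0.5) {
    ang <- stats::runif(1, -15, 15) * pi / 180
    ax <- sample.int(3L, 1L)
    ca <- cos(ang); sa <- sin(ang)
    R <- diag(3)
    pl <- setdiff(1:3, ax)
    R[pl[1], pl[1]] <- ca; R[pl[1], pl[2]] <- -sa
    R[pl[2], pl[1]] <- sa; R[pl[2], pl[2]] <- ca
    ctr <- (gs - 1) / 2
    co <- voxel_grid_coords(gs)
    src <- sweep(sweep(co, 2, ctr, "-") %*% t(R), 2, ctr, "+")
    warp_all(src)
  }
  if (isTRUE(config$intensity) && stats::runif(1) < 0.5) {
    X <- X * stats::runif(1, 0.9, 1.1)
  }
  if (isTRUE(config$dropout) && stats::runif(1) < 0.5) {
    sz <- pmax(1L, floor(gs * stats::runif(3, 0.1, 0.3)))
    o <- floor(stats::runif(3) * (gs - sz))
    X[o[1] + seq_len(sz[1]), o[2] + seq_len(sz[2]), o[3] + seq_len(sz[3]), ] <- 0
  }
  list(X = X, region_mask = region_mask, brain_mask = brain_mask)
}

#' Cosine learning-rate schedule with floor
#'
#' `eta(t) = eta_min + (eta0 - eta_min) (1 + cos(pi t / T)) / 2` for
#' `t = 0..T`.
#'
#' @param t Step index (0-based).
#' @param T_total Total step count.
#' @param eta0 Initial learning rate.
#' @param eta_min Learning-rate floor.
#' @return Learning rate at step `t`.
#' @export
cosine_lr <- function(t, T_total, eta0 = 3e-4, eta_min = 1e-6) {
  stopifnot(t >= 0, t <= T_total, eta_min <= eta0)
  eta_min + 0.5 * (eta0 - eta_min) * (1 + cos(pi * t / T_total))
}

#' Initialize AdamW optimizer state
#' @param params Flat named list of weight arrays.
#' @return Optimizer state (first/second moments, step counter).
#' @export
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One AdamW update
#'
#' `theta <- theta - eta * m_hat / (sqrt(v_hat) + eps) - eta * wd * theta`
#' with standard bias correction; the decoupled decay term never enters the
#' moment accumulators.
#'
#' @param params Flat named list of weights.
#' @param grads Gradients with matching names/shapes.
#' @param opt State from [adamw_init()].
#' @param lr Learning rate for this step.
#' @param beta1,beta2 Moment decay rates.
#' @param eps Numerical stabilizer.
#' @param weight_decay Decoupled weight-decay factor.
#' @return List with updated `params` and `opt`.
#' @export
adamw_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (k in names(params)) {
    gk <- grads[[k]]
    if (is.null(gk)) gk <- params[[k]] * 0
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * gk
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * gk^2
    mhat <- opt$m[[k]] / bc1
    vhat <- opt$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps) -
      lr * weight_decay * params[[k]]
  }
  list(params = params, opt = opt)
}

#' Joint batch statistics over a mixed-domain batch
#'
#' Single mean and biased variance per channel over the full batch -- never
#' per domain -- as used by the stem's batch-norm layers.
#'
#' @param activations n x C activation matrix.
#' @return List with `mean` and `var` (length-C vectors).
#' @export
joint_batch_stats <- function(activations) {
  mu <- colMeans(activations)
  list(mean = mu, var = colMeans(sweep(activations, 2, mu, "-")^2))
}

#' Total training objective
#'
#' `L_total = L_cls + lambda_seg * L_seg + lambda_DA * L_DA`; with the
#' segmentation head disabled the middle term is absent.
#'
#' @param L_cls,L_seg,L_DA Scalar loss terms.
#' @param lambda_DA,lambda_seg Balancing weights.
#' @return Scalar total loss.
#' @export
total_loss <- function(L_cls, L_seg = 0, L_DA = 0, lambda_DA = 1, lambda_seg = 1) {
  L_cls + lambda_seg * L_seg + lambda_DA * L_DA
}

#' Combined validation score
#'
#' `alpha_val = gamma * alpha_src + (1 - gamma) * alpha_tgt`.
#'
#' @param alpha_src,alpha_tgt Per-domain validation accuracies.
#' @param gamma Source-domain weight in [0, 1].
#' @return Convex combination of the two accuracies.
#' @export
combined_val_score <- function(alpha_src, alpha_tgt, gamma = 0.5) {
  stopifnot(gamma >= 0, gamma <= 1)
  gamma * alpha_src + (1 - gamma) * alpha_tgt
}

#' Training configuration
#'
#' Defaults follow the published training recipe (AdamW, cosine decay with
#' floor, batch 16, mixed half/half domain batches); epoch count and patch
#' size are scaled by the caller for desk-size runs.
#'
#' @param batch_size Even mixed batch size (half per domain).
#' @param epochs Maximum epochs.
#' @param eta0,eta_min Cosine schedule endpoints.
#' @param beta1,beta2 AdamW moment decays.
#' @param weight_decay Decoupled weight decay.
#' @param lambda_DA Weight of the combined adaptation loss.
#' @param lambda_seg Weight of the Dice segmentation loss.
#' @param gamma Source weight in the combined validation score.
#' @param patience Early-stopping patience in epochs.
#' @param patch_shape Training patch shape (scalar or length 3).
#' @param patch_stride Sliding-window stride for patch extraction.
#' @param split_ratios Pair-level train/val/test proportions.
#' @param augment Master augmentation toggle.
#' @param augment_ops Logical toggles for the four augmentation operators.
#' @param bias_correct Apply bias-field correction during preprocessing.
#' @param supervise `"both"` trains the classification (and segmentation)
#'   heads on labels from both domains; `"source"` restricts supervision to
#'   source-domain samples, the cross-domain transfer protocol in which the
#'   target contributes images to the adaptation terms and the joint batch
#'   statistics but no labels.
#' @param grad_clip Optional gradient-norm clip (NULL disables; off by
#'   default).
#' @return Object of class `damlm_config`.
#' @export
damlm_config <- function(batch_size = 16L, epochs = 200L, eta0 = 3e-4,
                         eta_min = 1e-6, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 1e-4, lambda_DA = 1.0,
                         lambda_seg = 1.0, gamma = 0.5, patience = 20L,
                         patch_shape = 32L, patch_stride = 16L,
                         split_ratios = c(0.70, 0.15, 0.15),
                         augment = TRUE,
                         augment_ops = list(elastic = TRUE, intensity = TRUE,
                                            rotation = TRUE, dropout = TRUE),
                         bias_correct = FALSE, grad_clip = NULL,
                         supervise = c("both", "source")) {
  supervise <- match.arg(supervise)
  stopifnot(batch_size %% 2L == 0L, eta_min <= eta0, gamma >= 0, gamma <= 1)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 eta0 = eta0, eta_min = eta_min, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, lambda_DA = lambda_DA,
                 lambda_seg = lambda_seg, gamma = gamma,
                 patience = as.integer(patience),
                 patch_shape = as.integer(rep(patch_shape, length.out = 3)),
                 patch_stride = as.integer(patch_stride),
                 split_ratios = split_ratios, supervise = supervise,
                 augment = isTRUE(augment),
                 augment_ops = augment_ops, bias_correct = isTRUE(bias_correct),
                 grad_clip = grad_clip),
            class = "damlm_config")
}

# preprocess one labeled volume into a training sample: pick the sliding
# patch with the largest tumor overlap (deterministic tie-break: first)
.make_sample <- function(vol, config) {
  pp <- preprocess_volume(vol, bias_correct = config$bias_correct)
  ps <- config$patch_shape
  gs <- dim(pp$X)[1:3]
  if (all(gs == ps)) {
    origin <- c(0L, 0L, 0L)
    X <- pp$X
  } else {
    pg <- patch_grid(gs, ps, config$patch_stride)
    best <- 1L; best_ct <- -1
    for (i in seq_len(nrow(pg$origins))) {
      o <- pg$origins[i, ]
      ct <- sum(pp$region_mask[o[1] + seq_len(ps[1]), o[2] + seq_len(ps[2]),
                               o[3] + seq_len(ps[3])] > 0)
      if (ct > best_ct) { best <- i; best_ct <- ct }
    }
    origin <- pg$origins[best, ]
    o <- origin
    X <- pp$X[o[1] + seq_len(ps[1]), o[2] + seq_len(ps[2]),
              o[3] + seq_len(ps[3]), , drop = FALSE]
  }
  o <- origin
  list(X = X,
       region = pp$region_mask[o[1] + seq_len(ps[1]), o[2] + seq_len(ps[2]),
                               o[3] + seq_len(ps[3])],
       brain = pp$brain_mask[o[1] + seq_len(ps[1]), o[2] + seq_len(ps[2]),
                             o[3] + seq_len(ps[3])],
       class_label = pp$class_label, domain = pp$domain,
       anatomy_seed = pp$anatomy_seed)
}

# flatten a set of samples (list) into batch matrices for the tape
.batch_mats <- function(samples, n_regions) {
  X <- patches_to_mat(lapply(samples, `[[`, "X"))
  region <- unlist(lapply(samples, function(s) as.integer(s$region)))
  list(X = X, region_onehot = one_hot(region, n_regions),
       y = vapply(samples, `[[`, integer(1), "class_label"))
}

#' Fit the domain-adaptive model
#'
#' Trains the hybrid encoder with classification (and optionally Dice
#' segmentation) heads under the trilevel domain-adaptation objective on a
#' paired two-domain dataset. Each step alternates a discriminator update on
#' the binary domain loss with a joint AdamW update of encoder and heads on
#' the total loss; batches hold `batch_size/2` anatomy-paired samples from
#' each domain, batch-norm statistics are computed jointly over the mixed
#' batch, the learning rate follows a cosine decay with floor, and training
#' stops early when the combined validation score fails to improve for
#' `patience` epochs (the best-scoring weights are kept).
#'
#' @param dataset A paired dataset from [build_dataset()] (or a list with
#'   `volumes` and `manifest` in the same layout).
#' @param model_config An [encoder_config()].
#' @param train_config A [damlm_config()].
#' @param adapt An [adaptation_weights()]; set all lambdas to 0 for the
#'   no-adaptation ablation.
#' @param seed Integer seed controlling initialization, splits, batch order
#'   and augmentation.
#' @param verbose Print per-epoch progress.
#' @param .val_score_fn Optional override of the validation score (used to
#'   exercise the early-stopping contract); receives
#'   `(epoch, alpha_src, alpha_tgt)`.
#' @return An object of class `damlm`.
#' @export
damlm_fit <- function(dataset, model_config = encoder_config(),
                      train_config = damlm_config(),
                      adapt = adaptation_weights(), seed = 0L,
                      verbose = FALSE, .val_score_fn = NULL,
                      .disc_seed = NULL) {
  stopifnot(!is.null(dataset$volumes), !is.null(dataset$manifest))
  man <- dataset$manifest
  if (nrow(man) == 0L || !any(man$domain == 0L) || !any(man$domain == 1L))
    stop("dataset must contain volumes from both domains")
  cfg <- train_config
  K <- model_config$n_classes

  samples <- lapply(dataset$volumes, .make_sample, config = cfg)

  # pair-level stratified split so cross-domain positives stay together
  pair_ids <- sort(unique(man$pair_id))
  pair_class <- vapply(pair_ids, function(p) man$class[man$pair_id == p][1], numeric(1))
  sp <- stratified_split(pair_class, split_spec(cfg$split_ratios, seed = seed))
  part_of_pair <- integer(length(pair_ids))
  for (p in 1:3) part_of_pair[sp[[p]]] <- p
  idx_by <- function(part, domain) {
    which(man$pair_id %in% pair_ids[part_of_pair == part] & man$domain == domain)
  }
  pools <- list(train = list(src = idx_by(1, 0L), tgt = idx_by(1, 1L)),
                val = list(src = idx_by(2, 0L), tgt = idx_by(2, 1L)),
                test = list(src = idx_by(3, 0L), tgt = idx_by(3, 1L)))
  if (length(pools$train$src) == 0L || length(pools$train$tgt) == 0L)
    stop("empty training pool in one domain")

  # order training indices by pair id so positions align across domains
  ord_by_pair <- function(ix) ix[order(man$pair_id[ix])]
  train_src <- ord_by_pair(pools$train$src)
  train_tgt <- ord_by_pair(pools$train$tgt)
  n_pairs <- length(train_src)
  half <- min(cfg$batch_size %/% 2L, n_pairs)

  weights <- init_weights(model_config, seed = seed)
  state <- init_bn_state(model_config)
  if (model_config$positional_encoding == "learned" &&
      model_config$backbone_mode != "cnn_only") {
    ds_f <- if (model_config$backbone_mode == "transformer_only")
      2L^length(model_config$strided_blocks)
    else 2L^length(model_config$strided_blocks)
    tok_grid <- cfg$patch_shape %/% ds_f
    weights[["pos.p"]] <- matrix(0, prod(tok_grid), model_config$channels)
  }
  disc <- init_discriminator(model_config$channels,
                             seed = if (is.null(.disc_seed)) seed else .disc_seed)
  opt <- adamw_init(weights)
  dopt <- adamw_init(disc)

  steps_per_epoch <- max(1L, n_pairs %/% half)
  T_total <- cfg$epochs * steps_per_epoch
  seg_on <- isTRUE(model_config$seg_head) &&
    model_config$backbone_mode != "transformer_only" && cfg$lambda_seg > 0

  history <- list()
  best <- list(score = -Inf, weights = weights, state = clone_bn_state(state, model_config),
               disc = disc, epoch = 0L)
  fails <- 0L
  step <- 0L

  eval_acc <- function(w, st, ix) {
    if (length(ix) == 0L) return(NA_real_)
    preds <- .predict_samples(samples[ix], model_config, w, st)
    mean(preds$class == vapply(samples[ix], `[[`, integer(1), "class_label"))
  }

  for (epoch in seq_len(cfg$epochs)) {
    pair_order <- {
      old <- .Random.seed_save()
      set.seed(derive_seed(103L, seed, epoch))
      o <- sample.int(n_pairs)
      .Random.seed_restore(old)
      o
    }
    nb <- n_pairs %/% half
    ep_losses <- c(total = 0, cls = 0, seg = 0, adv = 0, con = 0, cov = 0, disc = 0)
    for (b in seq_len(nb)) {
      sel <- pair_order[(b - 1L) * half + seq_len(half)]
      bidx <- c(train_src[sel], train_tgt[sel])
      bs <- samples[bidx]
      if (cfg$augment) {
        bs <- lapply(seq_along(bs), function(i) {
          a <- augment_patch(bs[[i]]$X, bs[[i]]$region, bs[[i]]$brain,
                             cfg$augment_ops,
                             seed = derive_seed(107L, seed, epoch, b, i))
          s <- bs[[i]]
          s$X <- a$X; s$region <- a$region_mask; s$brain <- a$brain_mask
          s
        })
      }
      bm <- .batch_mats(bs, model_config$n_regions)
      y_d <- c(rep(0, half), rep(1, half))

      P <- wrap_params(weights)
      enc <- fwd_encoder(P, bm$X, model_config, state, training = TRUE,
                         update_stats = TRUE)

      # (a) discriminator step on detached features
      dstep <- discriminator_step(disc, dopt, enc$g$value, y_d,
                                  lr = cosine_lr(step, T_total, cfg$eta0, cfg$eta_min))
      disc <- dstep$disc; dopt <- dstep$opt

      # (b) joint step on the total loss
      logits <- fwd_classifier(P, enc$g)
      probs <- ad_rowsoftmax(logits)
      src_only <- identical(cfg$supervise, "source")
      l_cls <- if (src_only) {
        ad_cross_entropy(ad_rows(probs, seq_len(half)),
                         one_hot(bm$y[seq_len(half)], K))
      } else {
        ad_cross_entropy(probs, one_hot(bm$y, K))
      }
      terms <- list(l_cls); wts <- 1
      l_seg_v <- 0
      if (seg_on) {
        seg <- fwd_decoder(P, enc$tokens, enc$skips, model_config)
        if (src_only) {
          S <- nrow(seg$value) / (2L * half)
          src_rows <- seq_len(S * half)
          l_seg <- ad_dice_loss(ad_rows(seg, src_rows),
                                bm$region_onehot[src_rows, , drop = FALSE])
        } else {
          l_seg <- ad_dice_loss(seg, bm$region_onehot)
        }
        terms <- c(terms, list(l_seg)); wts <- c(wts, cfg$lambda_seg)
        l_seg_v <- as.numeric(l_seg$value)
      }
      l_adv_v <- l_con_v <- l_cov_v <- 0
      if (adapt$lambda_adv > 0) {
        Dc <- wrap_params(disc)
        g_in <- if (adapt$grl) ad_gradscale(enc$g, -1) else enc$g
        p_hat <- fwd_discriminator(Dc, g_in)
        l_adv <- ad_confusion(p_hat)
        w_adv <- cfg$lambda_DA * adapt$lambda_adv * (if (adapt$grl) -1 else 1)
        terms <- c(terms, list(l_adv)); wts <- c(wts, w_adv)
        l_adv_v <- as.numeric(l_adv$value)
      }
      if (adapt$lambda_con > 0 && half >= 2L) {
        z <- ad_l2norm_rows(enc$g)
        l_con <- ad_infonce(z, half, adapt$temperature)
        terms <- c(terms, list(l_con)); wts <- c(wts, cfg$lambda_DA * adapt$lambda_con)
        l_con_v <- as.numeric(l_con$value)
      }
      if (adapt$lambda_cov > 0 && half >= 2L) {
        l_cov <- ad_cov_loss(ad_rows(enc$g, seq_len(half)),
                             ad_rows(enc$g, half + seq_len(half)))
        terms <- c(terms, list(l_cov)); wts <- c(wts, cfg$lambda_DA * adapt$lambda_cov)
        l_cov_v <- as.numeric(l_cov$value)
      }
      l_total <- ad_wsum(terms, wts)
      ad_backward(l_total)
      grads <- lapply(P, function(n) n$grad)
      if (!is.null(cfg$grad_clip)) {
        nrm <- sqrt(sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g^2), numeric(1))))
        if (nrm > cfg$grad_clip)
          grads <- lapply(grads, function(g) if (is.null(g)) g else g * (cfg$grad_clip / nrm))
      }
      upd <- adamw_step(weights, grads, opt,
                        lr = cosine_lr(step, T_total, cfg$eta0, cfg$eta_min),
                        beta1 = cfg$beta1, beta2 = cfg$beta2,
                        weight_decay = cfg$weight_decay)
      weights <- upd$params; opt <- upd$opt
      step <- step + 1L
      ep_losses <- ep_losses + c(as.numeric(l_total$value), as.numeric(l_cls$value),
                                 l_seg_v, l_adv_v, l_con_v, l_cov_v, dstep$loss)
    }
    ep_losses <- ep_losses / nb
    a_src <- eval_acc(weights, state, pools$val$src)
    a_tgt <- eval_acc(weights, state, pools$val$tgt)
    a_val <- if (!is.null(.val_score_fn)) .val_score_fn(epoch, a_src, a_tgt)
             else combined_val_score(a_src, a_tgt, cfg$gamma)
    history[[epoch]] <- data.frame(
      epoch = epoch, loss_total = ep_losses[["total"]], loss_cls = ep_losses[["cls"]],
      loss_seg = ep_losses[["seg"]], loss_adv = ep_losses[["adv"]],
      loss_con = ep_losses[["con"]], loss_cov = ep_losses[["cov"]],
      loss_disc = ep_losses[["disc"]],
      lr = cosine_lr(step - 1L, T_total, cfg$eta0, cfg$eta_min),
      alpha_src = a_src, alpha_tgt = a_tgt, alpha_val = a_val)
    if (verbose)
      message(sprintf("epoch %3d  L=%.4f  a_src=%.3f  a_tgt=%.3f  a_val=%.3f",
                      epoch, ep_losses[["total"]], a_src, a_tgt, a_val))
    if (!is.na(a_val) && a_val > best$score + 1e-12) {
      best <- list(score = a_val, weights = weights,
                   state = clone_bn_state(state, model_config), disc = disc,
                   epoch = epoch)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= cfg$patience) break
    }
  }

  fit <- structure(list(
    weights = best$weights, state = best$state, disc = best$disc,
    final_weights = weights, final_state = state,
    model_config = model_config, train_config = cfg, adapt = adapt,
    history = do.call(rbind, history), best_epoch = best$epoch,
    best_score = best$score, seed = seed,
    pools = pools, n_classes = K), class = "damlm")
  fit
}

# internal: batched eval-mode prediction over a list of samples
.predict_samples <- function(samples, config, weights, state, batch = 16L) {
  n <- length(samples)
  probs <- matrix(NA_real_, n, config$n_classes)
  emb <- matrix(NA_real_, n, config$channels)
  P <- wrap_params(weights)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    X <- patches_to_mat(lapply(samples[i:j], `[[`, "X"))
    enc <- fwd_encoder(P, X, config, state, training = FALSE, update_stats = FALSE)
    logits <- fwd_classifier(P, enc$g)
    pr <- ad_rowsoftmax(logits)$value
    probs[i:j, ] <- pr
    emb[i:j, ] <- enc$g$value
    i <- j + 1L
  }
  list(prob = probs, class = max.col(probs, ties.method = "first") - 1L,
       embedding = emb)
}

# ---- S3 methods ---------------------------------------------------------

#' @export
print.damlm <- function(x, ...) {
  mc <- x$model_config
  cat("Domain-adaptive hybrid 3D CNN-transformer model\n")
  cat(sprintf("  backbone: %s  (C=%d, L_c=%d, L_t=%d, heads=%d)\n",
              mc$backbone_mode, mc$channels, mc$conv_depth,
              mc$transformer_depth, mc$attention_heads))
  cat(sprintf("  heads: %d-class classifier%s\n", mc$n_classes,
              if (mc$seg_head) sprintf(" + %d-region segmentation decoder", mc$n_regions) else ""))
  cat(sprintf("  adaptation: lambda_adv=%.3g lambda_con=%.3g lambda_cov=%.3g (tau=%.3g)\n",
              x$adapt$lambda_adv, x$adapt$lambda_con, x$adapt$lambda_cov,
              x$adapt$temperature))
  cat(sprintf("  trained %d epochs (best epoch %d, combined val score %.3f)\n",
              nrow(x$history), x$best_epoch, x$best_score))
  invisible(x)
}

#' @export
summary.damlm <- function(object, ...) {
  h <- object$history
  out <- list(
    n_parameters = sum(vapply(object$weights, length, numeric(1))),
    epochs_run = nrow(h), best_epoch = object$best_epoch,
    best_val_score = object$best_score,
    final_losses = h[nrow(h), c("loss_total", "loss_cls", "loss_seg",
                                "loss_adv", "loss_con", "loss_cov", "loss_disc")],
    val_accuracy = h[nrow(h), c("alpha_src", "alpha_tgt", "alpha_val")])
  class(out) <- "summary.damlm"
  out
}

#' @export
print.summary.damlm <- function(x, ...) {
  cat(sprintf("damlm fit: %d trainable parameters, %d epochs (best %d)\n",
              x$n_parameters, x$epochs_run, x$best_epoch))
  cat("final epoch losses:\n"); print(round(x$final_losses, 4), row.names = FALSE)
  cat("validation accuracy:\n"); print(round(x$val_accuracy, 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.damlm <- function(object, ...) object$weights

#' Predict from a fitted damlm model
#'
#' @param object A fitted `damlm` object.
#' @param newdata A `phantom_dataset`, list of `labeled_volume`s, or a single
#'   `labeled_volume`.
#' @param type `"class"` (default), `"prob"`, or `"embedding"` (pooled
#'   features g).
#' @param ... Unused.
#' @return Predicted labels, probability matrix, or embedding matrix.
#' @export
predict.damlm <- function(object, newdata, type = c("class", "prob", "embedding"), ...) {
  type <- match.arg(type)
  vols <- if (inherits(newdata, "labeled_volume")) list(newdata)
          else if (!is.null(newdata$volumes)) newdata$volumes
          else newdata
  samples <- lapply(vols, .make_sample, config = object$train_config)
  pr <- .predict_samples(samples, object$model_config, object$weights, object$state)
  switch(type, class = pr$class, prob = pr$prob, embedding = pr$embedding)
}

#' @export
plot.damlm <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(h$epoch, h$loss_total, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training losses", ...)
  graphics::lines(h$epoch, h$loss_cls, lty = 2)
  graphics::legend("topright", c("total", "classification"), lty = 1:2, bty = "n")
  graphics::plot(h$epoch, h$alpha_val, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", main = "validation")
  graphics::lines(h$epoch, h$alpha_src, lty = 2)
  graphics::lines(h$epoch, h$alpha_tgt, lty = 3)
  graphics::legend("bottomright", c("combined", "source", "target"),
                   lty = 1:3, bty = "n")
  invisible(x)
}

#' Save / load model weights
#'
#' Single-file checkpoint: a JSON header line (configuration, array names,
#' shapes, seed) followed by the raw little-endian doubles of every array.
#' The round-trip is bit-stable.
#'
#' @param fit A `damlm` object (or a bare weight list for `weights_only`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "damlm"))
  arrays <- c(fit$weights, stats::setNames(fit$disc, paste0("disc.", names(fit$disc))))
  bn <- list()
  for (i in seq_len(fit$model_config$conv_depth)) {
    key <- sprintf("bn%d", i)
    if (!is.null(fit$state[[key]])) {
      bn[[paste0(key, ".mean")]] <- fit$state[[key]]$mean
      bn[[paste0(key, ".var")]] <- fit$state[[key]]$var
    }
  }
  arrays <- c(arrays, bn)
  hdr <- list(names = names(arrays),
              dims = lapply(arrays, function(a) if (is.null(dim(a))) length(a) else dim(a)),
              model_config = unclass(fit$model_config),
              train_config = unclass(fit$train_config),
              adapt = unclass(fit$adapt), n_classes = fit$n_classes,
              seed = fit$seed)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hjson <- jsonlite::toJSON(hdr, auto_unbox = TRUE)
  writeBin(charToRaw(paste0(hjson, "\n")), con)
  for (a in arrays) writeBin(as.numeric(a), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  chars <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L || b == charToRaw("\n")) break
    chars <- c(chars, b)
  }
  hdr <- jsonlite::fromJSON(rawToChar(chars), simplifyVector = TRUE)
  arrays <- list()
  for (i in seq_along(hdr$names)) {
    d <- unlist(hdr$dims[[i]])
    v <- readBin(con, "numeric", prod(d), size = 8, endian = "little")
    arrays[[hdr$names[i]]] <- if (length(d) > 1L) array(v, dim = d) else v
  }
  list(arrays = arrays, model_config = hdr$model_config,
       train_config = hdr$train_config, adapt = hdr$adapt,
       n_classes = hdr$n_classes, seed = hdr$seed)
}

#' Rebuild a usable model from a checkpoint file
#'
#' Restores the weights, discriminator, batch-norm state and configurations
#' saved by [save_checkpoint()] into a `damlm` object that supports
#' [predict.damlm()] and the evaluation harnesses (training history is not
#' part of the checkpoint).
#'
#' @param path Checkpoint file.
#' @return A `damlm` object.
#' @export
restore_checkpoint <- function(path) {
  ck <- load_checkpoint(path)
  mc <- ck$model_config
  mc$strided_blocks <- as.integer(mc$strided_blocks)
  class(mc) <- "encoder_config"
  tc <- ck$train_config
  tc$patch_shape <- as.integer(tc$patch_shape)
  class(tc) <- "damlm_config"
  ad <- ck$adapt
  class(ad) <- "adaptation_weights"
  arr <- ck$arrays
  disc_nm <- grep("^disc\\.", names(arr), value = TRUE)
  bn_nm <- grep("^bn[0-9]+\\.", names(arr), value = TRUE)
  weights <- arr[setdiff(names(arr), c(disc_nm, bn_nm))]
  disc <- stats::setNames(arr[disc_nm], sub("^disc\\.", "", disc_nm))
  state <- init_bn_state(mc)
  for (i in seq_len(mc$conv_depth)) {
    key <- sprintf("bn%d", i)
    if (!is.null(arr[[paste0(key, ".mean")]])) {
      state[[key]]$mean <- arr[[paste0(key, ".mean")]]
      state[[key]]$var <- arr[[paste0(key, ".var")]]
    }
  }
  structure(list(weights = weights, state = state, disc = disc,
                 model_config = mc, train_config = tc, adapt = ad,
                 history = NULL, best_epoch = NA_integer_,
                 best_score = NA_real_, seed = ck$seed,
                 pools = NULL, n_classes = as.integer(ck$n_classes)),
            class = "damlm")
}
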