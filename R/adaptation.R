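# Trilevel domain-adaptation objective: adversarial feature alignment via a
# domain discriminator with an explicit confusion loss (gradient reversal
# available behind a flag), temperature-scaled cross-domain contrastive
# regularization over anatomy-paired embeddings, and covariance (second-
# order) alignment of domain feature statistics.

#' Adaptation loss weights
#'
#' @param lambda_adv Adversarial confusion weight (default 0.5).
#' @param lambda_con Contrastive weight (default 1.0).
#' @param lambda_cov Covariance-alignment weight (default 0.1).
#' @param temperature Contrastive similarity temperature (> 0, default 0.1).
#' @param grl Use the gradient-reversal formulation instead of the explicit
#'   confusion loss (the two produce identical encoder updates for the
#'   symmetric target; see the methods vignette).
#' @return Object of class `adaptation_weights`.
#' @export
adaptation_weights <- function(lambda_adv = 0.5, lambda_con = 1.0,
                               lambda_cov = 0.1, temperature = 0.1,
                               grl = FALSE) {
  stopifnot(lambda_adv >= 0, lambda_con >= 0, lambda_cov >= 0, temperature > 0)
  structure(list(lambda_adv = lambda_adv, lambda_con = lambda_con,
                 lambda_cov = lambda_cov, temperature = temperature,
                 grl = isTRUE(grl)),
            class = "adaptation_weights")
}

#' Initialize domain discriminator weights
#'
#' Two-layer perceptron (ReLU hidden, sigmoid output) of hidden width C/2.
#'
#' @param C Input feature dimension.
#' @param seed Integer seed.
#' @param hidden Hidden width (default `max(2, C/2)`).
#' @return Named list of weight arrays.
#' @export
init_discriminator <- function(C, seed = 0L, hidden = max(2L, C %/% 2L)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(71L, seed))
  list(w1 = kw(C, hidden), b1 = rep(0, hidden),
       w2 = kw(hidden, 1L), b2 = 0)
}

# tape forward: g node (B, C) -> probability node (B, 1)
fwd_discriminator <- function(D, g) {
  h <- ad_relu(ad_addbias(ad_matmul(g, D[["w1"]]), D[["b1"]]))
  ad_sigmoid(ad_addbias(ad_matmul(h, D[["w2"]]), D[["b2"]]))
}

#' Domain discriminator forward pass
#'
#' @param g Pooled feature vector (length C) or B x C matrix.
#' @param weights Discriminator weights from [init_discriminator()].
#' @return Domain probability in (0, 1) (vector for matrix input).
#' @export
discriminator_forward <- function(g, weights) {
  gm <- if (is.matrix(g)) g else matrix(g, nrow = 1)
  p <- fwd_discriminator(wrap_params(weights), ad_leaf(gm))$value
  if (is.matrix(g)) as.numeric(p) else as.numeric(p)[1]
}

#' Discriminator binary cross-entropy
#'
#' `L_disc = -[y log(p) + (1 - y) log(1 - p)]`, epsilon-clamped; mean over
#' samples for vector input.
#'
#' @param p_hat Predicted domain probabilities in (0, 1).
#' @param y_d True domain labels in \{0, 1\}.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(p_hat, y_d, eps = 1e-12) {
  p <- pmin(pmax(p_hat, eps), 1 - eps)
  mean(-(y_d * log(p) + (1 - y_d) * log(1 - p)))
}

#' Adversarial confusion loss
#'
#' `L_adv = -(1/2)[log(p) + log(1 - p)]`, minimized (at log 2) when the
#' discriminator is maximally uncertain, p = 1/2. Mean over samples.
#'
#' @param p_hat Predicted domain probabilities.
#' @return Scalar loss (>= log 2).
#' @export
adversarial_confusion_loss <- function(p_hat, eps = 1e-12) {
  p <- pmin(pmax(p_hat, eps), 1 - eps)
  mean(-0.5 * (log(p) + log(1 - p)))
}

# tape versions of the two BCE-style losses on a probability node (B, 1)
ad_bce <- function(p, y, eps = 1e-12) {
  pv <- pmin(pmax(p$value, eps), 1 - eps)
  B <- length(pv)
  v <- mean(-(y * log(pv) + (1 - y) * log(1 - pv)))
  ad_node(v, list(p), function(g) {
    list(matrix(g * (-(y / pv) + (1 - y) / (1 - pv)) / B, ncol = 1))
  })
}

ad_confusion <- function(p, eps = 1e-12) {
  pv <- pmin(pmax(p$value, eps), 1 - eps)
  B <- length(pv)
  v <- mean(-0.5 * (log(pv) + log(1 - pv)))
  ad_node(v, list(p), function(g) {
    list(matrix(g * (-0.5 / pv + 0.5 / (1 - pv)) / B, ncol = 1))
  })
}

#' Temperature-scaled cosine similarity
#'
#' `s_ij = (z_i . z_j) / temperature` after defensive L2 normalization.
#'
#' @param z_i,z_j Feature vectors.
#' @param temperature Positive temperature.
#' @return Scalar similarity in [-1/temperature, 1/temperature].
#' @export
similarity <- function(z_i, z_j, temperature = 0.1) {
  stopifnot(temperature > 0)
  ni <- sqrt(sum(z_i^2)); nj <- sqrt(sum(z_j^2))
  if (ni < .Machine$double.eps || nj < .Machine$double.eps) return(0)
  sum(z_i * z_j) / (ni * nj) / temperature
}

#' Cross-domain contrastive (InfoNCE) loss for one anchor
#'
#' `L = -log exp(s(anchor, positive)) / (exp(s(anchor, positive)) +
#' sum_n exp(s(anchor, negative_n)))`, computed in log-sum-exp form.
#'
#' @param anchor Anchor embedding.
#' @param positive Cross-domain positive embedding (same anatomy).
#' @param negatives List (or matrix rows) of negative embeddings (>= 1).
#' @param temperature Similarity temperature.
#' @return Scalar loss (>= 0).
#' @export
contrastive_loss <- function(anchor, positive, negatives, temperature = 0.1) {
  if (is.matrix(negatives)) negatives <- asplit(negatives, 1)
  if (length(negatives) < 1L) stop("contrastive loss requires at least one negative")
  sp <- similarity(anchor, positive, temperature)
  sn <- vapply(negatives, function(n) similarity(anchor, n, temperature), numeric(1))
  all_s <- c(sp, sn)
  m <- max(all_s)
  -(sp - (m + log(sum(exp(all_s - m)))))
}

# tape version over a paired batch: z (2m, C) row-normalized embeddings,
# rows 1..m are domain-0, rows m+1..2m are domain-1, pair i <-> m+i.
# Anchors run over both directions; negatives for anchor i are all
# cross-domain rows except its positive.
ad_infonce <- function(z, m, temperature) {
  zv <- z$value
  n <- 2L * m
  S <- tcrossprod(zv) / temperature
  loss <- 0
  A <- matrix(0, n, n)  # d loss / d S
  for (i in seq_len(n)) {
    pos <- if (i <= m) i + m else i - m
    cand <- if (i <= m) (m + 1L):n else 1L:m   # cross-domain candidates
    s <- S[i, cand]
    mx <- max(s)
    w <- exp(s - mx); w <- w / sum(w)
    loss <- loss + (-(S[i, pos] - (mx + log(sum(exp(s - mx))))))
    A[i, cand] <- A[i, cand] + w
    A[i, pos] <- A[i, pos] - 1
  }
  loss <- loss / n
  A <- A / n
  ad_node(loss, list(z), function(g) {
    dz <- (A %*% zv + crossprod(A, zv)) / temperature
    list(g * dz)
  })
}

#' Covariance alignment loss
#'
#' Squared Frobenius distance between the unbiased feature covariance
#' matrices of the two domains.
#'
#' @param features_src n_src x C feature matrix (domain 0).
#' @param features_tgt n_tgt x C feature matrix (domain 1).
#' @return Scalar `||Sigma_src - Sigma_tgt||_F^2`.
#' @export
covariance_loss <- function(features_src, features_tgt) {
  if (nrow(features_src) < 2L || nrow(features_tgt) < 2L)
    stop("covariance loss requires at least 2 samples per domain")
  d <- stats::cov(features_src) - stats::cov(features_tgt)
  sum(d^2)
}

# tape version: fS, fT nodes (nS x C), (nT x C)
ad_cov_loss <- function(fS, fT) {
  fs <- fS$value; ft <- fT$value
  nS <- nrow(fs); nT <- nrow(ft)
  cs <- scale(fs, center = TRUE, scale = FALSE)
  ct <- scale(ft, center = TRUE, scale = FALSE)
  SS <- crossprod(cs) / (nS - 1)
  ST <- crossprod(ct) / (nT - 1)
  D <- SS - ST
  v <- sum(D^2)
  ad_node(v, list(fS, fT), function(g) {
    gS <- g * 4 / (nS - 1) * (cs %*% D)
    gT <- -g * 4 / (nT - 1) * (ct %*% D)
    # centering: subtract column means of the raw gradients
    gS <- sweep(gS, 2, colMeans(gS), "-")
    gT <- sweep(gT, 2, colMeans(gT), "-")
    list(gS, gT)
  })
}

#' Combine the domain-adaptation loss terms
#'
#' `L_DA = lambda_adv * L_adv + lambda_con * L_con + lambda_cov * L_cov`.
#'
#' @param L_adv,L_con,L_cov Scalar loss terms.
#' @param weights An [adaptation_weights()].
#' @return Scalar combined loss.
#' @export
combine_domain_losses <- function(L_adv, L_con, L_cov, weights = adaptation_weights()) {
  weights$lambda_adv * L_adv + weights$lambda_con * L_con + weights$lambda_cov * L_cov
}

#' One discriminator training step
#'
#' Updates discriminator weights by one AdamW step on the binary
#' cross-entropy of detached pooled features; the encoder receives no
#' gradient from this step (two-player update routing).
#'
#' @param disc Discriminator weight list.
#' @param opt AdamW state for `disc` (from [adamw_init()]).
#' @param g B x C pooled features (treated as constants).
#' @param y_d Domain labels.
#' @param lr Learning rate.
#' @return List with updated `disc`, `opt` and the step's `loss`.
#' @export
discriminator_step <- function(disc, opt, g, y_d, lr) {
  D <- wrap_params(disc)
  p <- fwd_discriminator(D, ad_leaf(g))
  loss <- ad_bce(p, y_d)
  ad_backward(loss)
  grads <- lapply(D, function(n) if (is.null(n$grad)) n$value * 0 else n$grad)
  st <- adamw_step(disc, grads, opt, lr)
  list(disc = st$params, opt = st$opt, loss = as.numeric(loss$value))
}
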