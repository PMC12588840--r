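#' Training-loss configuration
#'
#' Weights of the composite objective: generalized Dice loss (GDL) plus
#' focal loss (FL), the Kullback-Leibler weight penalty of the variational
#' layers, and the auxiliary binary cross-entropy on the NENR class used by
#' the follow-up branch.
#'
#' @param lambda_gdl,lambda_fl non-negative weights of GDL and FL (at least
#'   one positive).
#' @param gamma_init initial focusing parameter of the focal loss.
#' @param gamma_learnable make gamma trainable (softplus-reparameterized).
#' @param kl_weight non-negative weight of the network KL term. `NULL`
#'   (default) resolves at training time to 1 / (voxels per batch) so the
#'   penalty is on a per-voxel scale.
#' @param nenr_ce_weight non-negative weight of the NENR cross-entropy term.
#' @param class_weight_epsilon guard added inside the squared GDL class
#'   weight denominator so absent classes get a large but finite weight.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(lambda_gdl = 1, lambda_fl = 1, gamma_init = 2,
                        gamma_learnable = TRUE, kl_weight = NULL,
                        nenr_ce_weight = 0, class_weight_epsilon = 1e-5) {
  check_scalar_num(lambda_gdl, "lambda_gdl", min = 0)
  check_scalar_num(lambda_fl, "lambda_fl", min = 0)
  if (lambda_gdl == 0 && lambda_fl == 0) {
    stop_validation("at least one of lambda_gdl, lambda_fl must be > 0",
                    field = "lambda_gdl")
  }
  check_scalar_num(gamma_init, "gamma_init", min = 0)
  if (!is.null(kl_weight)) check_scalar_num(kl_weight, "kl_weight", min = 0)
  check_scalar_num(nenr_ce_weight, "nenr_ce_weight", min = 0)
  check_scalar_num(class_weight_epsilon, "class_weight_epsilon", min = 1e-300)
  structure(list(lambda_gdl = lambda_gdl, lambda_fl = lambda_fl,
                 gamma_init = gamma_init,
                 gamma_learnable = isTRUE(gamma_learnable),
                 kl_weight = kl_weight, nenr_ce_weight = nenr_ce_weight,
                 class_weight_epsilon = class_weight_epsilon),
            class = "loss_config")
}

#' Reference / prediction probability pair
#'
#' Couples a one-hot reference field with a predicted per-voxel class
#' probability map over the same voxels. Inputs may be (C, X, Y, Z) arrays
#' or (C x N) matrices; both must be per-voxel probability simplexes
#' (tolerance 1e-6), the reference additionally one-hot.
#'
#' @param r one-hot reference field.
#' @param p predicted probability field of identical shape.
#' @return An object of class `soft_label_pair` holding (C x N) matrices.
#' @export
soft_label_pair <- function(r, p) {
  to_mat <- function(a) if (is.matrix(a)) a else matrix(a, nrow = dim(a)[1L])
  if (is.null(dim(r)) || is.null(dim(p)) || !identical(dim(r), dim(p))) {
    stop_validation("'r' and 'p' must share an identical shape", field = "p")
  }
  rm <- to_mat(r); pm <- to_mat(p)
  if (any(pm < -1e-6) || any(pm > 1 + 1e-6) ||
      any(abs(colSums(pm) - 1) > 1e-6)) {
    stop_validation("'p' must be a per-voxel probability simplex", field = "p")
  }
  if (!all(rm %in% c(0, 1)) || any(colSums(rm) != 1)) {
    stop_validation("'r' must be one-hot per voxel", field = "r")
  }
  structure(list(r = rm, p = pm, n_voxels = ncol(rm), n_classes = nrow(rm)),
            class = "soft_label_pair")
}

# One-hot encode an integer label array (values 0..n_classes-1) as a
# (n_classes x N) matrix.
one_hot <- function(labels, n_classes = 4L) {
  lab <- as.integer(labels)
  m <- matrix(0, nrow = n_classes, ncol = length(lab))
  m[cbind(lab + 1L, seq_along(lab))] <- 1
  m
}

#' Generalized Dice loss over the foreground classes
#'
#' `1 - 2 * sum_l w_l sum_n r_ln p_ln / sum_l w_l sum_n (r_ln + p_ln)`
#' summed over the three foreground classes (FHR, ER, NENR), with the
#' inverse-squared-volume class weights `w_l = 1 / ((sum_n r_ln)^2 + eps)`
#' that make the loss invariant to the relative class volumes. A class
#' absent from the reference takes the largest present-class weight
#' instead of its (near-infinite) printed weight, so rare-class absence
#' cannot swamp the loss.
#'
#' @param pair a [soft_label_pair()].
#' @param epsilon positive guard inside the squared weight denominator.
#' @return Loss value in \[0, 1\] (up to the epsilon guard).
#' @export
generalized_dice_loss <- function(pair, epsilon = 1e-5) {
  if (!inherits(pair, "soft_label_pair")) {
    stop_validation("'pair' must be a soft_label_pair", field = "pair")
  }
  check_scalar_num(epsilon, "epsilon", min = 1e-300)
  fg <- 2:pair$n_classes
  r <- pair$r[fg, , drop = FALSE]
  p <- pair$p[fg, , drop = FALSE]
  w <- .gdl_weights(rowSums(r), epsilon)
  A <- sum(w * rowSums(r * p))
  B <- sum(w * (rowSums(r) + rowSums(p)))
  1 - 2 * A / B
}

# Inverse-squared-volume class weights. A class absent from the reference
# has infinite printed weight; it is capped at the largest present-class
# weight so that one missing class cannot dominate the loss (epsilon keeps
# the all-absent corner finite).
.gdl_weights <- function(volumes, epsilon) {
  w <- 1 / (volumes^2 + epsilon)
  present <- volumes > 0
  if (any(present) && any(!present)) {
    w[!present] <- max(w[present])
  }
  w
}

# dGDL/dp as a (C x N) matrix (zero on the background row).
gdl_grad <- function(pair, epsilon = 1e-5) {
  fg <- 2:pair$n_classes
  r <- pair$r[fg, , drop = FALSE]
  p <- pair$p[fg, , drop = FALSE]
  w <- .gdl_weights(rowSums(r), epsilon)
  A <- sum(w * rowSums(r * p))
  B <- sum(w * (rowSums(r) + rowSums(p)))
  g <- matrix(0, nrow = pair$n_classes, ncol = pair$n_voxels)
  g[fg, ] <- -2 * (w * r * B - A * w) / B^2
  g
}

#' Focal loss
#'
#' Mean over voxels of `-(1 - p_t)^gamma * ln(p_t)` where `p_t` is the
#' predicted probability of the true class (floored at 1e-7 before the
#' log). With `gamma = 0` this is the mean cross-entropy; larger `gamma`
#' down-weights well-classified voxels.
#'
#' @param pair a [soft_label_pair()].
#' @param gamma non-negative focusing parameter.
#' @return Non-negative loss value.
#' @export
focal_loss <- function(pair, gamma) {
  if (!inherits(pair, "soft_label_pair")) {
    stop_validation("'pair' must be a soft_label_pair", field = "pair")
  }
  check_scalar_num(gamma, "gamma", min = 0)
  pt <- pmax(colSums(pair$r * pair$p), 1e-7)
  mean(-(1 - pt)^gamma * log(pt))
}

# dFL/dp (nonzero only on the true-class entries) and dFL/dgamma.
fl_grad <- function(pair, gamma) {
  pt <- pmax(colSums(pair$r * pair$p), 1e-7)
  om <- pmax(1 - pt, 1e-7)
  n <- pair$n_voxels
  gt <- (gamma * om^(gamma - 1) * log(pt) - om^gamma / pt) / n
  dgamma <- mean(-om^gamma * log(om) * log(pt))
  list(dp = pair$r * rep(gt, each = pair$n_classes), dgamma = dgamma)
}

#' Weighted generalized Dice focal loss
#'
#' `lambda_gdl * GDL + lambda_fl * FL`.
#'
#' @param pair a [soft_label_pair()].
#' @param config a [loss_config()].
#' @param gamma focusing parameter used for the FL component (defaults to
#'   the config's `gamma_init`).
#' @return The weighted sum.
#' @export
generalized_dice_focal_loss <- function(pair, config = loss_config(),
                                        gamma = config$gamma_init) {
  v <- 0
  if (config$lambda_gdl > 0) {
    v <- v + config$lambda_gdl *
      generalized_dice_loss(pair, config$class_weight_epsilon)
  }
  if (config$lambda_fl > 0) {
    v <- v + config$lambda_fl * focal_loss(pair, gamma)
  }
  v
}

#' Discrete Kullback-Leibler divergence KL(P || Q)
#'
#' `sum_x P(x) * ln(P(x) / Q(x))` in nats; non-negative, zero iff P = Q.
#'
#' @param P,Q probability vectors on the same support.
#' @return KL divergence in nats.
#' @export
kl_divergence_discrete <- function(P, Q) {
  if (length(P) != length(Q) || any(P < -1e-12) || any(Q < -1e-12) ||
      abs(sum(P) - 1) > 1e-9 || abs(sum(Q) - 1) > 1e-9) {
    stop_validation("'P' and 'Q' must be probability vectors of equal length",
                    field = "P")
  }
  act <- P > 0
  if (any(act & Q <= 0)) {
    stop_validation("KL(P||Q) undefined: Q is zero where P is positive",
                    field = "Q")
  }
  sum(P[act] * log(P[act] / Q[act]))
}

# Mean binary cross-entropy of the NENR-vs-rest probability map.
nenr_cross_entropy <- function(pair) {
  y <- pair$r[4L, ]
  pn <- pmin(pmax(pair$p[4L, ], 1e-7), 1 - 1e-7)
  mean(-(y * log(pn) + (1 - y) * log(1 - pn)))
}

nenr_ce_grad <- function(pair) {
  y <- pair$r[4L, ]
  pn <- pmin(pmax(pair$p[4L, ], 1e-7), 1 - 1e-7)
  g <- matrix(0, nrow = pair$n_classes, ncol = pair$n_voxels)
  g[4L, ] <- (-y / pn + (1 - y) / (1 - pn)) / pair$n_voxels
  g
}

#' Total training loss
#'
#' `generalized_dice_focal_loss + kl_weight * network_kl +
#' nenr_ce_weight * nenr_ce`. The NENR cross-entropy is the mean binary
#' cross-entropy of the NENR-vs-rest map and is enabled (weight > 0) only
#' for follow-up training.
#'
#' @param pair a [soft_label_pair()].
#' @param network_kl non-negative network KL (nats).
#' @param config a [loss_config()]; a `NULL` `kl_weight` counts the KL at
#'   weight 1 / n_voxels.
#' @param gamma focusing parameter for the FL component.
#' @param nenr_ce precomputed NENR cross-entropy (defaults to computing it
#'   from `pair`).
#' @return The total loss (non-negative for non-negative weights).
#' @export
total_loss <- function(pair, network_kl = 0, config = loss_config(),
                       gamma = config$gamma_init,
                       nenr_ce = nenr_cross_entropy(pair)) {
  check_scalar_num(network_kl, "network_kl", min = 0)
  kw <- config$kl_weight %||% (1 / pair$n_voxels)
  generalized_dice_focal_loss(pair, config, gamma) + kw * network_kl +
    config$nenr_ce_weight * nenr_ce
}

# Gradient of the segmentation part of the total loss w.r.t. the logits of
# a softmax output (KL gradients are handled at the layer level). Returns
# the loss components, dlogits as (C x N), and dgamma.
seg_loss_grad <- function(pair, config, gamma) {
  g <- matrix(0, nrow = pair$n_classes, ncol = pair$n_voxels)
  gdl <- fl <- nce <- 0
  dgamma <- 0
  if (config$lambda_gdl > 0) {
    gdl <- generalized_dice_loss(pair, config$class_weight_epsilon)
    g <- g + config$lambda_gdl * gdl_grad(pair, config$class_weight_epsilon)
  }
  if (config$lambda_fl > 0) {
    fl <- focal_loss(pair, gamma)
    fg <- fl_grad(pair, gamma)
    g <- g + config$lambda_fl * fg$dp
    dgamma <- config$lambda_fl * fg$dgamma
  }
  if (config$nenr_ce_weight > 0) {
    nce <- nenr_cross_entropy(pair)
    g <- g + config$nenr_ce_weight * nenr_ce_grad(pair)
  }
  # chain through softmax: dz = p * (g - sum_l g_l p_l)
  inner <- colSums(g * pair$p)
  dz <- pair$p * sweep(g, 2L, inner, "-")
  list(gdl = gdl, fl = fl, nenr_ce = nce, dlogits = dz, dgamma = dgamma)
}
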