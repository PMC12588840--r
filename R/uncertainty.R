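#' Posterior sample set from stochastic forward passes
#'
#' Stores T per-voxel class-probability fields together with their
#' per-voxel, per-class mean and (population) variance.
#'
#' @param samples numeric array dim c(T, 4, X, Y, Z); each pass is a
#'   per-voxel probability simplex over (background, FHR, ER, NENR).
#' @return An object of class `posterior_sample_set` with fields `samples`,
#'   `mean`, `variance`, `T`.
#' @export
posterior_sample_set <- function(samples) {
  d <- dim(samples)
  if (length(d) != 5L || d[2L] != 4L) {
    stop_validation("'samples' must have dim (T, 4, X, Y, Z)",
                    field = "samples")
  }
  if (d[1L] < 1L) stop_validation("need at least one sample", field = "samples")
  M <- matrix(samples, nrow = d[1L])
  mu <- colMeans(M)
  va <- colMeans(M * M) - mu * mu
  structure(list(samples = samples,
                 mean = array(mu, dim = d[-1L]),
                 variance = array(pmax(va, 0), dim = d[-1L]),
                 T = d[1L]),
            class = "posterior_sample_set")
}

#' Draw T stochastic segmentations of a volume
#'
#' Runs T stochastic forward passes (Flipout weight perturbations or MC
#' dropout) with distinct RNG sub-states, converts logits to per-voxel
#' class probabilities, and summarizes them as a [posterior_sample_set()].
#' Seed-deterministic: the same seed and T give a bit-identical set.
#'
#' @param net a `glioseg_network` in variational or mc_dropout mode.
#' @param vol a [multimodal_volume()] (or a bare (4, X, Y, Z) array).
#' @param T_samples number of stochastic passes (>= 2).
#' @param seed integer seed.
#' @return A [posterior_sample_set()].
#' @export
sample_predictions <- function(net, vol, T_samples = 20L, seed = 1L) {
  if (!inherits(net, "glioseg_network") && !inherits(net, "glioseg_fused")) {
    stop_validation("'net' must be a glioseg_network or glioseg_fused model",
                    field = "net")
  }
  if (model_mode(net) == "deterministic") {
    stop_validation(
      "posterior sampling requires a variational or mc_dropout network (variance is undefined for a deterministic one)",
      field = "decoder_mode")
  }
  if (T_samples < 2L) stop_validation("'T_samples' must be >= 2", field = "T_samples")
  x <- if (inherits(vol, "multimodal_volume")) vol$data else vol
  d <- dim(x)
  n_cls <- if (inherits(net, "glioseg_fused")) nrow(net$cls$W) else net$config$n_classes
  samples <- array(0, dim = c(T_samples, n_cls, d[2:4]))
  with_seed(seed, {
    for (t in seq_len(T_samples)) {
      fw <- model_forward(net, x, stochastic = TRUE)
      samples[t, , , , ] <- channel_softmax(fw$logits)
    }
  })
  posterior_sample_set(samples)
}

#' Background-derived relabeling threshold
#'
#' `threshold = mu_B - lambda * sigma_B`, using the background class's
#' posterior mean and standard deviation (`sigma_B` is the s.d. under the
#' default scale; the variance may be substituted for sensitivity
#' analysis).
#'
#' @param mu_B background posterior mean(s).
#' @param sigma_B background posterior scale(s), >= 0.
#' @param lambda_ non-negative threshold weight (0.1 in the reference
#'   tuning).
#' @return The threshold(s), vectorized over voxels.
#' @export
compute_threshold <- function(mu_B, sigma_B, lambda_ = 0.1) {
  check_scalar_num(lambda_, "lambda_", min = 0)
  if (any(sigma_B < 0)) stop_validation("'sigma_B' must be >= 0", field = "sigma_B")
  mu_B - lambda_ * sigma_B
}

#' Relabeling configuration
#'
#' @param lambda_ non-negative threshold weight (default 0.1).
#' @param n_samples stochastic passes T for full inference (default 1000;
#'   reduce for desk-scale runs).
#' @param threshold_scale "std" (default, per the printed rule) or
#'   "variance" for sensitivity analysis.
#' @param threshold_scope "per_voxel" (each voxel's own background
#'   statistics) or "per_case" (statistics pooled over all
#'   background-predicted voxels of the case).
#' @return An object of class `relabel_config`.
#' @export
relabel_config <- function(lambda_ = 0.1, n_samples = 1000L,
                           threshold_scale = c("std", "variance"),
                           threshold_scope = c("per_voxel", "per_case")) {
  check_scalar_num(lambda_, "lambda_", min = 0)
  check_scalar_num(n_samples, "n_samples", min = 1)
  structure(list(lambda_ = lambda_, n_samples = as.integer(n_samples),
                 threshold_scale = match.arg(threshold_scale),
                 threshold_scope = match.arg(threshold_scope)),
            class = "relabel_config")
}

#' Uncertainty-guided relabeling of background voxels
#'
#' Implements the five-step misclassification-correction rule. Only voxels
#' currently labeled background are eligible. For each, a threshold
#' `mu_B - lambda * sigma_B` is computed from the background posterior;
#' foreground classes whose posterior mean exceeds the threshold are
#' candidates. No candidate leaves the voxel unchanged; a single candidate
#' claims it; among multiple candidates the one with the lowest posterior
#' variance wins (exact ties go to the lowest class index and are flagged).
#'
#' @param samples a [posterior_sample_set()].
#' @param initial a [label_map()] (normally the argmax of the posterior
#'   mean).
#' @param config a [relabel_config()].
#' @return list with `labels` (the corrected [label_map()]) and `audit`
#'   (branch counts and settings).
#' @export
relabel_background_voxels <- function(samples, initial,
                                      config = relabel_config()) {
  if (!inherits(samples, "posterior_sample_set")) {
    stop_validation("'samples' must be a posterior_sample_set", field = "samples")
  }
  if (!inherits(initial, "label_map")) initial <- label_map(initial)
  dvol <- dim(samples$mean)[-1L]
  if (!identical(dim(initial$labels), dvol)) {
    stop_validation("label map shape does not match the sample set",
                    field = "initial")
  }
  mu <- matrix(samples$mean, nrow = 4L)
  va <- matrix(samples$variance, nrow = 4L)
  lab <- as.integer(initial$labels)
  elig <- which(lab == 0L)
  audit <- list(eligible = length(elig), unchanged = 0L,
                single_candidate = 0L, multi_candidate = 0L, ties = 0L,
                lambda = config$lambda_, scope = config$threshold_scope,
                scale = config$threshold_scale, T = samples$T)
  if (length(elig)) {
    if (config$threshold_scope == "per_case") {
      muB <- mean(mu[1L, elig])
      scl <- if (config$threshold_scale == "std") {
        sqrt(mean(va[1L, elig]))
      } else {
        mean(va[1L, elig])
      }
      thr <- rep(muB - config$lambda_ * scl, length(elig))
    } else {
      scl <- if (config$threshold_scale == "std") sqrt(va[1L, elig]) else va[1L, elig]
      thr <- mu[1L, elig] - config$lambda_ * scl
    }
    mf <- mu[2:4, elig, drop = FALSE]
    vf <- va[2:4, elig, drop = FALSE]
    cand <- mf > rep(thr, each = 3L)
    ncand <- colSums(cand)
    audit$unchanged <- sum(ncand == 0L)
    audit$single_candidate <- sum(ncand == 1L)
    audit$multi_candidate <- sum(ncand >= 2L)
    sel <- ncand > 0L
    if (any(sel)) {
      vmask <- vf
      vmask[!cand] <- Inf
      pick <- max.col(t(-vmask[, sel, drop = FALSE]), ties.method = "first")
      multi <- which(sel)[ncand[sel] >= 2L]
      if (length(multi)) {
        vm <- vmask[, multi, drop = FALSE]
        audit$ties <- sum(apply(vm, 2L, function(v) {
          sum(v == min(v)) > 1L
        }))
      }
      lab[elig[sel]] <- pick
    }
  }
  out <- array(lab, dim = dvol)
  list(labels = label_map(out), audit = audit)
}

#' Per-voxel uncertainty map
#'
#' `predictive_variance` is the posterior variance of the predicted
#' (argmax-of-mean) class's probability; `predictive_entropy` is the
#' entropy of the mean simplex normalized by ln(4) to \[0,1\].
#'
#' @param samples a [posterior_sample_set()].
#' @param kind "predictive_variance" or "predictive_entropy".
#' @return A 3D numeric array.
#' @export
uncertainty_map <- function(samples,
                            kind = c("predictive_entropy",
                                     "predictive_variance")) {
  kind <- match.arg(kind)
  if (!inherits(samples, "posterior_sample_set")) {
    stop_validation("'samples' must be a posterior_sample_set", field = "samples")
  }
  dvol <- dim(samples$mean)[-1L]
  mu <- matrix(samples$mean, nrow = 4L)
  if (kind == "predictive_variance") {
    pred <- max.col(t(mu), ties.method = "first")
    va <- matrix(samples$variance, nrow = 4L)
    array(va[cbind(pred, seq_len(ncol(va)))], dim = dvol)
  } else {
    mus <- pmax(mu, 1e-12)
    array(-colSums(mus * log(mus)) / log(4), dim = dvol)
  }
}

# Argmax-of-mean initial labeling of a posterior sample set (ties broken
# by lowest class index).
initial_labels <- function(samples) {
  label_map(channel_argmax(samples$mean))
}
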