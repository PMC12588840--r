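#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param weight_decay L2 weight decay added to gradients (default 1e-5).
#' @param batch_size cases per optimizer step (default 8).
#' @param epochs training epochs.
#' @param split (train, validation, test) fractions summing to 1.
#' @param k_folds folds for [crossvalidate()] (default 5).
#' @param seed integer seed governing splits, initialization and sampling.
#' @param freeze_pretrained keep the pretrained branch fixed during fused
#'   follow-up training (default TRUE); FALSE fine-tunes it as well.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 1e-5,
                         batch_size = 8L, epochs = 100L,
                         split = c(0.8, 0.1, 0.1), k_folds = 5L, seed = 1L,
                         freeze_pretrained = TRUE) {
  check_scalar_num(learning_rate, "learning_rate", min = 1e-12)
  check_scalar_num(weight_decay, "weight_decay", min = 0)
  check_scalar_num(batch_size, "batch_size", min = 1)
  check_scalar_num(epochs, "epochs", min = 1)
  if (length(split) != 3L || any(split < 0) || abs(sum(split) - 1) > 1e-9) {
    stop_validation("'split' must be 3 non-negative fractions summing to 1",
                    field = "split")
  }
  check_scalar_num(k_folds, "k_folds", min = 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), split = split,
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 freeze_pretrained = isTRUE(freeze_pretrained)),
            class = "train_config")
}

#' Generate a corpus of phantom cases
#'
#' One phantom per case, all sharing the template spec but with distinct
#' seeds derived from `seed`. `preoperative = TRUE` emulates a
#' preoperative-style corpus: necrotic cores are common and there is no
#' resection cavity.
#'
#' @param n_cases number of cases.
#' @param spec a [phantom_spec()] template.
#' @param seed integer corpus seed.
#' @param preoperative emulate preoperative data (NENR prevalence 0.9,
#'   no cavity).
#' @return list of cases, each a list(case_id, volume, labels).
#' @export
phantom_corpus <- function(n_cases, spec = phantom_spec(), seed = 1L,
                           preoperative = FALSE) {
  lapply(seq_len(n_cases), function(i) {
    s <- spec
    s$seed <- as.integer((seed * 10007L + i) %% .Machine$integer.max)
    if (preoperative) {
      s$nenr_prevalence <- 0.9
      s$cavity <- FALSE
    }
    ph <- generate_phantom(s)
    list(case_id = sprintf("case_%04d", i), volume = ph$volume,
         labels = ph$labels)
  })
}

# ---- optimizer ----------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = 0 * p, v = 0 * p),
         how = "list", classes = "ANY")
}

adam_step <- function(params, grads, state, step, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      skip = character()) {
  for (ly in names(params)) {
    if (ly %in% skip) next
    g_ly <- grads[[ly]]
    if (is.null(g_ly)) next
    for (nm in names(params[[ly]])) {
      g <- g_ly[[nm]]
      if (is.null(g)) next
      p <- params[[ly]][[nm]]
      if (wd > 0) g <- g + wd * p
      st <- state[[ly]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^step)
      vhat <- st$v / (1 - beta2^step)
      params[[ly]][[nm]] <- p - lr * mhat / (sqrt(vhat) + eps)
      state[[ly]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

# ---- generic model forward ---------------------------------------------

model_forward <- function(model, x, stochastic = TRUE) {
  if (inherits(model, "glioseg_fused")) {
    f1 <- net_forward(model$pretrained, x, stochastic = stochastic)
    f2 <- net_forward(model$scratch, x, stochastic = stochastic)
    fused <- fuse_embeddings(f1$features, f2$features, mode = "sum")
    lm <- model$cls$W %*% matrix(fused, nrow = dim(fused)[1L]) + model$cls$b
    list(logits = array(lm, dim = c(nrow(model$cls$W), dim(fused)[2:4])))
  } else {
    net_forward(model, x, stochastic = stochastic)
  }
}

model_mode <- function(model) {
  if (inherits(model, "glioseg_fused")) model$scratch$config$decoder_mode
  else model$config$decoder_mode
}

# ---- core fitting loop --------------------------------------------------

# Split a corpus into train/val/test case indices, seed-deterministically.
split_cases <- function(n, split, seed) {
  with_seed(seed, {
    idx <- sample.int(n)
    n_tr <- round(split[1] * n)
    n_va <- round(split[2] * n)
    list(train = idx[seq_len(n_tr)],
         val = idx[n_tr + seq_len(max(n_va, 0))],
         test = idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  })
}

case_pair <- function(case, n_classes = 4L) {
  soft_label_pair_fast(one_hot(case$labels$labels, n_classes), NULL)
}

# internal: skip the simplex re-validation on trusted softmax output
soft_label_pair_fast <- function(rm, pm) {
  structure(list(r = rm, p = pm, n_voxels = ncol(rm), n_classes = nrow(rm)),
            class = "soft_label_pair")
}

# Train one network (or the scratch branch + fused head) by Adam on the
# composite objective. Returns best-validation parameters and the per-step
# training log.
fit_network <- function(net, train_cases, val_cases, tcfg,
                        lcfg = loss_config(), log_path = NULL) {
  nvox_case <- prod(dim(train_cases[[1]]$volume$data)[-1L])
  kl_w <- lcfg$kl_weight %||% (1 / (tcfg$batch_size * nvox_case))
  variational <- net$config$decoder_mode == "variational"
  gamma_raw <- inv_softplus(max(lcfg$gamma_init, 1e-6))
  gstate <- list(m = 0, v = 0)
  state <- adam_init(net$params)
  onehots <- lapply(train_cases, function(ca) one_hot(ca$labels$labels))
  step <- 0L
  log <- list()
  best <- list(val = Inf, params = net$params, gamma_raw = gamma_raw,
               epoch = 0L)
  with_seed(tcfg$seed, {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample(seq_along(train_cases))
      batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
      for (bt in batches) {
        gamma <- if (lcfg$gamma_learnable) softplus(gamma_raw) else lcfg$gamma_init
        gsum <- NULL
        dgam <- 0
        comp <- c(gdl = 0, fl = 0, kl = 0, nenr_ce = 0)
        for (ci in bt) {
          ca <- train_cases[[ci]]
          fw <- net_forward(net, ca$volume$data, stochastic = TRUE,
                            want_cache = TRUE)
          p <- channel_softmax(fw$logits)
          pair <- soft_label_pair_fast(onehots[[ci]],
                                       matrix(p, nrow = dim(p)[1L]))
          sg <- seg_loss_grad(pair, lcfg, gamma)
          dlog <- array(sg$dlogits, dim = dim(fw$logits)) / length(bt)
          gr <- net_backward(net, fw$cache, dlog,
                             kl_weight = if (variational) kl_w / length(bt) else 0)
          gsum <- if (is.null(gsum)) gr else accumulate_grads(gsum, gr)
          dgam <- dgam + sg$dgamma / length(bt)
          comp <- comp + c(sg$gdl, sg$fl,
                           if (variational) fw$kl else 0, sg$nenr_ce) / length(bt)
        }
        step <- step + 1L
        upd <- adam_step(net$params, gsum, state, step,
                         tcfg$learning_rate, tcfg$weight_decay)
        net$params <- upd$params
        state <- upd$state
        if (lcfg$gamma_learnable) {
          g <- dgam * stats::plogis(gamma_raw)
          gstate$m <- 0.9 * gstate$m + 0.1 * g
          gstate$v <- 0.999 * gstate$v + 0.001 * g * g
          gamma_raw <- gamma_raw - tcfg$learning_rate *
            (gstate$m / (1 - 0.9^step)) /
            (sqrt(gstate$v / (1 - 0.999^step)) + 1e-8)
        }
        total <- lcfg$lambda_gdl * comp[["gdl"]] +
          lcfg$lambda_fl * comp[["fl"]] + kl_w * comp[["kl"]] +
          lcfg$nenr_ce_weight * comp[["nenr_ce"]]
        log[[length(log) + 1L]] <- data.frame(
          step = step, epoch = ep, gdl = comp[["gdl"]], fl = comp[["fl"]],
          kl = comp[["kl"]], nenr_ce = comp[["nenr_ce"]], total = total,
          gamma = if (lcfg$gamma_learnable) softplus(gamma_raw) else lcfg$gamma_init)
      }
      vl <- validation_loss(net, val_cases, lcfg, kl_w,
                            if (lcfg$gamma_learnable) softplus(gamma_raw) else lcfg$gamma_init)
      if (vl < best$val) {
        best <- list(val = vl, params = net$params, gamma_raw = gamma_raw,
                     epoch = ep)
      }
    }
  })
  net$params <- best$params
  history <- do.call(rbind, log)
  if (!is.null(log_path)) utils::write.csv(history, log_path, row.names = FALSE)
  list(net = net, gamma_raw = best$gamma_raw, history = history,
       best_val_loss = best$val, best_epoch = best$epoch)
}

accumulate_grads <- function(a, b) {
  for (ly in names(b)) {
    for (nm in names(b[[ly]])) {
      a[[ly]][[nm]] <- a[[ly]][[nm]] + b[[ly]][[nm]]
    }
  }
  a
}

# Mean-weight (deterministic) validation loss including the KL penalty.
validation_loss <- function(net, val_cases, lcfg, kl_w, gamma) {
  if (!length(val_cases)) return(NA_real_)
  variational <- net$config$decoder_mode == "variational"
  vals <- vapply(val_cases, function(ca) {
    fw <- net_forward(net, ca$volume$data, stochastic = FALSE)
    p <- channel_softmax(fw$logits)
    pair <- soft_label_pair_fast(one_hot(ca$labels$labels),
                                 matrix(p, nrow = dim(p)[1L]))
    v <- generalized_dice_focal_loss(pair, lcfg, gamma)
    if (lcfg$nenr_ce_weight > 0) {
      v <- v + lcfg$nenr_ce_weight * nenr_cross_entropy(pair)
    }
    if (variational) v <- v + kl_w * fw$kl
    v
  }, 0)
  mean(vals)
}

# ---- checkpoints --------------------------------------------------------

new_checkpoint <- function(model, gamma_raw, history, tcfg, lcfg, seed,
                           best_val_loss = NA_real_, best_epoch = NA_integer_) {
  structure(list(model = model, gamma_raw = gamma_raw, history = history,
                 train_config = tcfg, loss_config = lcfg, seed = seed,
                 best_val_loss = best_val_loss, best_epoch = best_epoch,
                 rng_kind = RNGkind()),
            class = "glioseg_checkpoint")
}

#' Save / load a training checkpoint
#'
#' Checkpoints hold the model (config + all parameters), the learnable
#' focusing parameter, the training history, configs and RNG metadata —
#' enough to re-execute a run deterministically on one machine.
#'
#' @param checkpoint a `glioseg_checkpoint`.
#' @param path file path (.rds).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "glioseg_checkpoint")) {
    stop_validation("file does not contain a glioseg checkpoint", field = "path")
  }
  ck
}

# Order-insensitive digest of a parameter list (for freeze audits).
param_checksum <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(params[order(names(params))], f, version = 2)
  unname(tools::md5sum(f))
}

# ---- training entry points ---------------------------------------------

#' Pretrain a segmentation network
#'
#' Trains a network on a (preoperative-style) labeled corpus with the
#' generalized Dice focal loss plus, for variational decoders, the KL
#' penalty. The parameters achieving the lowest validation loss are kept.
#'
#' @param cases list of cases (each list(case_id, volume, labels)).
#' @param config a [train_config()].
#' @param net_config a [network_config()].
#' @param loss a [loss_config()].
#' @param log_path optional CSV path for the per-step loss log.
#' @return A `glioseg_checkpoint`.
#' @export
pretrain <- function(cases, config = train_config(),
                     net_config = network_config(), loss = loss_config(),
                     log_path = NULL) {
  sp <- split_cases(length(cases), config$split, config$seed)
  if (!length(sp$val)) {
    stop_validation("validation split is empty", field = "split")
  }
  net <- build_network(net_config, seed = config$seed)
  fit <- fit_network(net, cases[sp$train], cases[sp$val], config, loss,
                     log_path = log_path)
  ck <- new_checkpoint(fit$net, fit$gamma_raw, fit$history, config, loss,
                       config$seed, fit$best_val_loss, fit$best_epoch)
  ck$split <- sp
  ck
}

#' Fine-tune a fused dual-branch model on follow-up cases
#'
#' Builds the transfer-learning head: the pretrained branch (frozen by
#' default), a scratch branch trained from random initialization, and a
#' fused classification layer applied to the element-wise sum of the two
#' branches' final decoder features. The scratch branch is optimized with
#' the total loss including the auxiliary NENR cross-entropy.
#'
#' @param cases follow-up cases.
#' @param pretrained a `glioseg_checkpoint` from [pretrain()].
#' @param config a [train_config()]; `freeze_pretrained` controls whether
#'   the pretrained branch receives updates.
#' @param loss a [loss_config()]; its `nenr_ce_weight` should be positive
#'   for follow-up training.
#' @param log_path optional CSV loss log.
#' @return A `glioseg_checkpoint` whose `model` is a `glioseg_fused`.
#' @export
finetune_fused <- function(cases, pretrained, config = train_config(),
                           loss = loss_config(nenr_ce_weight = 0.5),
                           log_path = NULL) {
  if (!inherits(pretrained, "glioseg_checkpoint") ||
      !inherits(pretrained$model, "glioseg_network")) {
    stop_validation("'pretrained' must be a network checkpoint",
                    field = "pretrained")
  }
  pre_net <- pretrained$model
  sp <- split_cases(length(cases), config$split, config$seed)
  if (!length(sp$val)) stop_validation("validation split is empty", field = "split")
  scratch <- build_network(pre_net$config, seed = config$seed + 101L)
  if (!identical(pre_net$config$encoder_channels,
                 scratch$config$encoder_channels)) {
    stop_validation("channel schedules of the two branches are incompatible",
                    field = "encoder_channels")
  }
  ncl <- pre_net$config$n_classes
  prior <- c(1 - 0.03 * (ncl - 1L), rep(0.03, ncl - 1L))
  cls <- with_seed(config$seed + 202L, list(
    W = he_init(ncl, pre_net$config$encoder_channels[1L]) / 10,
    b = log(prior)))
  model <- structure(list(pretrained = pre_net, scratch = scratch, cls = cls,
                          freeze_pretrained = config$freeze_pretrained),
                     class = "glioseg_fused")
  fit <- fit_fused(model, cases[sp$train], cases[sp$val], config, loss,
                   log_path = log_path)
  ck <- new_checkpoint(fit$model, fit$gamma_raw, fit$history, config, loss,
                       config$seed, fit$best_val_loss, fit$best_epoch)
  ck$split <- sp
  ck$pretrained_checksum <- param_checksum(pre_net$params)
  # branches excluded from gradient updates during this run
  ck$freeze_manifest <- if (config$freeze_pretrained) "pretrained" else character(0)
  ck
}

fit_fused <- function(model, train_cases, val_cases, tcfg, lcfg,
                      log_path = NULL) {
  nvox_case <- prod(dim(train_cases[[1]]$volume$data)[-1L])
  kl_w <- lcfg$kl_weight %||% (1 / (tcfg$batch_size * nvox_case))
  variational <- model$scratch$config$decoder_mode == "variational"
  gamma_raw <- inv_softplus(max(lcfg$gamma_init, 1e-6))
  gstate <- list(m = 0, v = 0)
  s_state <- adam_init(model$scratch$params)
  p_state <- if (!model$freeze_pretrained) adam_init(model$pretrained$params)
  c_state <- adam_init(list(cls = model$cls))$cls
  onehots <- lapply(train_cases, function(ca) one_hot(ca$labels$labels))
  ncls <- nrow(model$cls$W)
  step <- 0L
  log <- list()
  best <- list(val = Inf, model = model, gamma_raw = gamma_raw, epoch = 0L)
  with_seed(tcfg$seed + 1L, {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample(seq_along(train_cases))
      batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
      for (bt in batches) {
        gamma <- if (lcfg$gamma_learnable) softplus(gamma_raw) else lcfg$gamma_init
        gs <- gp <- NULL
        gcls <- list(W = 0 * model$cls$W, b = 0 * model$cls$b)
        dgam <- 0
        comp <- c(gdl = 0, fl = 0, kl = 0, nenr_ce = 0)
        for (ci in bt) {
          ca <- train_cases[[ci]]
          f1 <- net_forward(model$pretrained, ca$volume$data,
                            stochastic = TRUE,
                            want_cache = !model$freeze_pretrained)
          f2 <- net_forward(model$scratch, ca$volume$data, stochastic = TRUE,
                            want_cache = TRUE)
          fused <- f1$features + f2$features
          fm <- matrix(fused, nrow = dim(fused)[1L])
          lm <- model$cls$W %*% fm + model$cls$b
          p <- channel_softmax(array(lm, dim = c(ncls, dim(fused)[2:4])))
          pair <- soft_label_pair_fast(onehots[[ci]],
                                       matrix(p, nrow = ncls))
          sg <- seg_loss_grad(pair, lcfg, gamma)
          dlm <- sg$dlogits / length(bt)
          gcls$W <- gcls$W + tcrossprod(dlm, fm)
          gcls$b <- gcls$b + rowSums(dlm)
          dfused <- array(crossprod(model$cls$W, dlm), dim = dim(fused))
          zlog <- array(0, dim = c(ncls, dim(fused)[2:4]))
          grs <- net_backward(model$scratch, f2$cache, zlog,
                              kl_weight = if (variational) kl_w / length(bt) else 0,
                              dfeatures_extra = dfused)
          gs <- if (is.null(gs)) grs else accumulate_grads(gs, grs)
          if (!model$freeze_pretrained) {
            grp <- net_backward(model$pretrained, f1$cache, zlog,
                                kl_weight = 0, dfeatures_extra = dfused)
            gp <- if (is.null(gp)) grp else accumulate_grads(gp, grp)
          }
          dgam <- dgam + sg$dgamma / length(bt)
          comp <- comp + c(sg$gdl, sg$fl,
                           if (variational) f2$kl else 0,
                           sg$nenr_ce) / length(bt)
        }
        step <- step + 1L
        upd <- adam_step(model$scratch$params, gs, s_state, step,
                         tcfg$learning_rate, tcfg$weight_decay, skip = "cls")
        model$scratch$params <- upd$params
        s_state <- upd$state
        if (!model$freeze_pretrained) {
          updp <- adam_step(model$pretrained$params, gp, p_state, step,
                            tcfg$learning_rate, tcfg$weight_decay,
                            skip = "cls")
          model$pretrained$params <- updp$params
          p_state <- updp$state
        }
        updc <- adam_step(list(cls = model$cls), list(cls = gcls),
                          list(cls = c_state), step, tcfg$learning_rate,
                          tcfg$weight_decay)
        model$cls <- updc$params$cls
        c_state <- updc$state$cls
        if (lcfg$gamma_learnable) {
          g <- dgam * stats::plogis(gamma_raw)
          gstate$m <- 0.9 * gstate$m + 0.1 * g
          gstate$v <- 0.999 * gstate$v + 0.001 * g * g
          gamma_raw <- gamma_raw - tcfg$learning_rate *
            (gstate$m / (1 - 0.9^step)) /
            (sqrt(gstate$v / (1 - 0.999^step)) + 1e-8)
        }
        total <- lcfg$lambda_gdl * comp[["gdl"]] +
          lcfg$lambda_fl * comp[["fl"]] + kl_w * comp[["kl"]] +
          lcfg$nenr_ce_weight * comp[["nenr_ce"]]
        log[[length(log) + 1L]] <- data.frame(
          step = step, epoch = ep, gdl = comp[["gdl"]], fl = comp[["fl"]],
          kl = comp[["kl"]], nenr_ce = comp[["nenr_ce"]], total = total,
          gamma = if (lcfg$gamma_learnable) softplus(gamma_raw) else lcfg$gamma_init)
      }
      vl <- fused_validation_loss(model, val_cases, lcfg, kl_w,
                                  if (lcfg$gamma_learnable) softplus(gamma_raw) else lcfg$gamma_init)
      if (vl < best$val) {
        best <- list(val = vl, model = model, gamma_raw = gamma_raw,
                     epoch = ep)
      }
    }
  })
  history <- do.call(rbind, log)
  if (!is.null(log_path)) utils::write.csv(history, log_path, row.names = FALSE)
  list(model = best$model, gamma_raw = best$gamma_raw, history = history,
       best_val_loss = best$val, best_epoch = best$epoch)
}

fused_validation_loss <- function(model, val_cases, lcfg, kl_w, gamma) {
  if (!length(val_cases)) return(NA_real_)
  variational <- model$scratch$config$decoder_mode == "variational"
  vals <- vapply(val_cases, function(ca) {
    fw <- model_forward(model, ca$volume$data, stochastic = FALSE)
    p <- channel_softmax(fw$logits)
    pair <- soft_label_pair_fast(one_hot(ca$labels$labels),
                                 matrix(p, nrow = dim(p)[1L]))
    v <- generalized_dice_focal_loss(pair, lcfg, gamma)
    if (lcfg$nenr_ce_weight > 0) {
      v <- v + lcfg$nenr_ce_weight * nenr_cross_entropy(pair)
    }
    if (variational) v <- v + kl_w * network_kl(model$scratch)
    v
  }, 0)
  mean(vals)
}

# ---- inference ----------------------------------------------------------

pad_to_multiple <- function(x, div) {
  d <- dim(x)
  target <- ceiling(d[2:4] / div) * div
  if (all(target == d[2:4])) return(list(x = x, orig = d[2:4]))
  out <- array(0, dim = c(d[1L], target))
  out[, seq_len(d[2L]), seq_len(d[3L]), seq_len(d[4L])] <- x
  list(x = out, orig = d[2:4])
}

#' Full uncertainty-aware inference for one case
#'
#' Runs T stochastic forward passes, labels each voxel by the argmax of
#' the posterior mean, applies the uncertainty-guided background
#' relabeling (unless `relabel` is NULL), and returns the final labels
#' with uncertainty maps. Inputs whose dimensions are not divisible by the
#' pooling depth are zero-padded and the outputs cropped back.
#'
#' @param model a `glioseg_network`, `glioseg_fused`, or checkpoint.
#' @param vol a [multimodal_volume()].
#' @param T_samples stochastic passes (ignored for deterministic models).
#' @param relabel a [relabel_config()] or NULL to disable relabeling.
#' @param seed integer seed for the stochastic passes.
#' @return list with `labels` ([label_map()]), `samples`
#'   ([posterior_sample_set()] or NULL), `entropy`, `variance` maps,
#'   `initial_labels` and the relabel `audit`.
#' @export
predict_case <- function(model, vol, T_samples = 20L,
                         relabel = relabel_config(), seed = 1L) {
  if (inherits(model, "glioseg_checkpoint")) model <- model$model
  x <- if (inherits(vol, "multimodal_volume")) vol$data else vol
  S <- if (inherits(model, "glioseg_fused")) model$scratch$n_stages else model$n_stages
  pd <- pad_to_multiple(x, 2^(S - 1L))
  o <- pd$orig
  if (model_mode(model) == "deterministic") {
    fw <- model_forward(model, pd$x, stochastic = FALSE)
    p <- channel_softmax(fw$logits)
    lab <- channel_argmax(p)[seq_len(o[1]), seq_len(o[2]), seq_len(o[3]),
                             drop = FALSE]
    return(list(labels = label_map(array(lab, dim = o)), samples = NULL,
                entropy = NULL, variance = NULL,
                initial_labels = label_map(array(lab, dim = o)),
                audit = NULL))
  }
  ss <- sample_predictions(model, pd$x, T_samples = T_samples, seed = seed)
  if (!all(o == dim(ss$mean)[-1L])) {
    cropped <- ss$samples[, , seq_len(o[1]), seq_len(o[2]), seq_len(o[3]),
                          drop = FALSE]
    ss <- posterior_sample_set(cropped)
  }
  init <- initial_labels(ss)
  audit <- NULL
  final <- init
  if (!is.null(relabel)) {
    rl <- relabel_background_voxels(ss, init, relabel)
    final <- rl$labels
    audit <- rl$audit
  }
  list(labels = final, samples = ss,
       entropy = uncertainty_map(ss, "predictive_entropy"),
       variance = uncertainty_map(ss, "predictive_variance"),
       initial_labels = init, audit = audit)
}

#' Tune the relabeling weight on validation cases
#'
#' Samples each validation case once, applies the relabeling rule for
#' every candidate lambda on the same posterior samples, and returns the
#' lambda maximizing mean foreground Dice (ties to the smallest lambda).
#'
#' @param val_cases validation cases with ground truth.
#' @param model a stochastic model or checkpoint.
#' @param grid candidate lambda values.
#' @param T_samples stochastic passes per case.
#' @param seed integer seed.
#' @return list with `best_lambda` and the per-lambda `table`.
#' @export
tune_lambda <- function(val_cases, model, grid = c(0, 0.05, 0.1, 0.2, 0.5),
                        T_samples = 20L, seed = 1L) {
  if (!length(grid)) stop_validation("'grid' must be nonempty", field = "grid")
  if (inherits(model, "glioseg_checkpoint")) model <- model$model
  preds <- lapply(seq_along(val_cases), function(i) {
    predict_case(model, val_cases[[i]]$volume, T_samples = T_samples,
                 relabel = NULL, seed = seed + i)
  })
  scores <- vapply(grid, function(lam) {
    ds <- vapply(seq_along(val_cases), function(i) {
      rl <- relabel_background_voxels(preds[[i]]$samples,
                                      preds[[i]]$initial_labels,
                                      relabel_config(lambda_ = lam))
      mean(vapply(1:3, function(k) {
        as.numeric(dice(rl$labels, val_cases[[i]]$labels, k))
      }, 0))
    }, 0)
    mean(ds)
  }, 0)
  best <- grid[which.max(scores)]  # which.max takes the first (smallest) tie
  list(best_lambda = best,
       table = data.frame(lambda = grid, mean_foreground_dsc = scores))
}

# ---- evaluation ---------------------------------------------------------

#' Evaluate a model on labeled cases
#'
#' Produces the full metrics report: per-case, per-class overlap metrics
#' (DSC, JI, HD), pooled voxel-wise calibration metrics (ECE, UCE,
#' per-class Brier, NLL), the reliability and risk-coverage tables and the
#' error-detection AUROC. Voxels are pooled over cases and subsampled to
#' at most `max_voxels` (seeded) to bound memory.
#'
#' @param model a stochastic model or checkpoint.
#' @param cases labeled cases.
#' @param T_samples stochastic passes per case.
#' @param relabel a [relabel_config()] or NULL.
#' @param bins calibration bins (default 15).
#' @param seed integer seed.
#' @param max_voxels calibration subsample cap.
#' @return An object of class `metrics_report`.
#' @export
evaluate_cases <- function(model, cases, T_samples = 20L,
                           relabel = relabel_config(), bins = 15L, seed = 1L,
                           max_voxels = 1e6) {
  if (inherits(model, "glioseg_checkpoint")) model <- model$model
  per_case <- list()
  conf <- corr <- unc <- ptrue <- NULL
  pclass <- vector("list", 4L)
  oclass <- vector("list", 4L)
  audits <- list()
  for (i in seq_along(cases)) {
    ca <- cases[[i]]
    pr <- predict_case(model, ca$volume, T_samples = T_samples,
                       relabel = relabel, seed = seed + i)
    audits[[i]] <- pr$audit
    for (k in 1:3) {
      per_case[[length(per_case) + 1L]] <- data.frame(
        case_id = ca$case_id %||% as.character(i),
        class = c("FHR", "ER", "NENR")[k],
        dsc = as.numeric(dice(pr$labels, ca$labels, k)),
        ji = as.numeric(jaccard(pr$labels, ca$labels, k)),
        hd = as.numeric(hausdorff(pr$labels, ca$labels, k,
                                  ca$volume$spacing_mm)))
    }
    mu <- matrix(pr$samples$mean, nrow = 4L)
    lab <- as.integer(pr$labels$labels)
    ref <- as.integer(ca$labels$labels)
    conf <- c(conf, pmax(mu[1L, ], mu[2L, ], mu[3L, ], mu[4L, ]))
    corr <- c(corr, as.numeric(lab == ref))
    unc <- c(unc, as.numeric(pr$entropy))
    ptrue <- c(ptrue, mu[cbind(ref + 1L, seq_len(ncol(mu)))])
    for (k in 1:4) {
      pclass[[k]] <- c(pclass[[k]], mu[k, ])
      oclass[[k]] <- c(oclass[[k]], as.numeric(ref == k - 1L))
    }
  }
  keep <- with_seed(seed, {
    if (length(conf) > max_voxels) sample.int(length(conf), max_voxels)
    else seq_along(conf)
  })
  ci <- calibration_input(conf[keep], corr[keep], M = bins)
  ui <- calibration_input(unc[keep], corr[keep], M = bins)
  cls_names <- c("background", "FHR", "ER", "NENR")
  brier_by_class <- vapply(1:4, function(k) {
    brier(pclass[[k]][keep], oclass[[k]][keep])
  }, 0)
  names(brier_by_class) <- cls_names
  per_case <- do.call(rbind, per_case)
  summary <- stats::aggregate(cbind(dsc, ji) ~ class, per_case, mean)
  structure(list(
    per_case = per_case,
    summary = summary,
    ece = ece(ci), uce = uce(ui),
    brier_by_class = brier_by_class,
    nll = nll(ptrue[keep]),
    reliability = reliability_curve(ci),
    risk_coverage = risk_coverage_curve(conf[keep], corr[keep]),
    error_auroc = tryCatch(error_detection_roc(unc[keep], corr[keep])$auroc,
                           error = function(e) NA_real_),
    relabel_audits = audits,
    n_cases = length(cases), T_samples = T_samples, bins = bins),
    class = "metrics_report")
}

#' K-fold cross-validation
#'
#' Case-level disjoint folds: every case appears in exactly one test fold;
#' each fold trains on the remaining cases (with an inner validation
#' split) and is evaluated out-of-fold. Returns per-fold reports plus a
#' pooled out-of-fold per-case table.
#'
#' @param cases labeled cases (length >= k_folds).
#' @param config a [train_config()].
#' @param net_config a [network_config()].
#' @param loss a [loss_config()].
#' @param T_samples stochastic passes at evaluation.
#' @param relabel a [relabel_config()] or NULL.
#' @return list with `folds` (per-fold reports), `fold_assignment`,
#'   `pooled` (out-of-fold per-case table) and `pooled_mean_dsc`.
#' @export
crossvalidate <- function(cases, config = train_config(),
                          net_config = network_config(),
                          loss = loss_config(), T_samples = 10L,
                          relabel = relabel_config()) {
  k <- config$k_folds
  n <- length(cases)
  if (k < 2L || n < k) {
    stop_validation("need k_folds >= 2 and at least k_folds cases",
                    field = "k_folds")
  }
  fold_of <- with_seed(config$seed,
                       sample(rep(seq_len(k), length.out = n)))
  folds <- vector("list", k)
  pooled <- list()
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    trainval <- cases[which(fold_of != f)]
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    cfg_f$split <- c(0.875, 0.125, 0)  # inner split; test fold held out
    ck <- pretrain(trainval, cfg_f, net_config, loss)
    rep_f <- evaluate_cases(ck$model, cases[test_idx], T_samples = T_samples,
                            relabel = relabel, seed = cfg_f$seed)
    rep_f$test_case_ids <- vapply(cases[test_idx],
                                  function(ca) ca$case_id %||% "", "")
    folds[[f]] <- rep_f
    pooled[[f]] <- rep_f$per_case
  }
  pooled <- do.call(rbind, pooled)
  list(folds = folds, fold_assignment = fold_of, pooled = pooled,
       pooled_mean_dsc = mean(pooled$dsc))
}

# ---- run manifests ------------------------------------------------------

#' Write a run manifest
#'
#' Records everything needed to re-execute a run deterministically: the
#' operation name, its JSON-serializable arguments, the seed, package
#' version and output checksums. [replay_run()] re-executes the operation
#' from the manifest and returns its result.
#'
#' @param operation name of an exported glioseg function.
#' @param args named list of its arguments (JSON-serializable).
#' @param seed integer seed the run used.
#' @param outputs optional named list/vector of output file checksums.
#' @param path JSON file to write.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(operation, args, seed, outputs = NULL, path) {
  manifest <- list(operation = operation, args = args, seed = seed,
                   outputs = outputs,
                   package = "glioseg",
                   version = as.character(utils::packageVersion("glioseg")),
                   rng_kind = RNGkind())
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}

#' @rdname write_manifest
#' @param manifest_path path to a manifest JSON.
#' @export
replay_run <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  fn <- get(m$operation, envir = asNamespace("glioseg"))
  do.call(fn, m$args)
}

#' Simulate and write a phantom case corpus
#'
#' Generates `n_cases` phantoms and writes each as NIfTI files (one per
#' channel plus a label file) under `out_dir`, with a run manifest.
#'
#' @param n_cases number of cases.
#' @param out_dir output directory (created if needed).
#' @param seed corpus seed.
#' @param spec_args named list of [phantom_spec()] overrides.
#' @return Invisibly, the list of written `case_record`s.
#' @export
simulate_cases <- function(n_cases, out_dir, seed = 1L, spec_args = list()) {
  spec <- do.call(phantom_spec, spec_args)
  cases <- phantom_corpus(n_cases, spec, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(cases, function(ca) {
    write_case(ca$volume, ca$labels, file.path(out_dir, ca$case_id))
  })
  files <- unlist(lapply(recs, function(r) c(unlist(r$channel_paths),
                                             r$label_path)))
  write_manifest("simulate_cases",
                 list(n_cases = n_cases, out_dir = out_dir, seed = seed,
                      spec_args = spec_args),
                 seed = seed,
                 outputs = as.list(tools::md5sum(files)),
                 path = file.path(out_dir, "manifest.json"))
  invisible(recs)
}

#' Desk-scale (tiny) preset
#'
#' The configuration used by the end-to-end phantom experiments: 40
#' default phantoms at 32^3 voxels, a reduced channel schedule c(12, 16),
#' 20 epochs at batch 8 (Adam lr 0.001, weight decay 1e-5), T = 20
#' stochastic passes at inference, and the desk-scale posterior
#' initialization (variance 1e-3; see the methods vignette for why the
#' full-scale initialization cannot anneal within a tiny run).
#'
#' @param seed integer seed for the corpus and training.
#' @return list with `n_cases`, `phantom`, `net_config`, `train_config`,
#'   `loss`, `T_samples`, `relabel`.
#' @export
tiny_preset <- function(seed = 1L) {
  list(n_cases = 40L,
       phantom = phantom_spec(),
       net_config = network_config(encoder_channels = c(12L, 16L),
                                   posterior_init_variance = 1e-3),
       train_config = train_config(epochs = 20L, batch_size = 8L,
                                   seed = seed),
       loss = loss_config(lambda_gdl = 0.2, lambda_fl = 1),
       T_samples = 20L,
       relabel = relabel_config(lambda_ = 0.1, n_samples = 20L))
}
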