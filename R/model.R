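#' Network architecture configuration
#'
#' Describes the 3D encoder-decoder: per-stage encoder channels (the last
#' entry is the bottleneck width), kernel geometry, and the decoder flavour.
#' The decoder mirrors the encoder in spatial resolution; equal-resolution
#' stages are paired by concatenating skip connections. In `variational`
#' mode every decoder convolution is a Flipout variational layer with a
#' N(0,1) weight prior and posterior scale initialized so the mapped
#' variance equals `posterior_init_variance`; `mc_dropout` instead keeps
#' deterministic weights and applies inference-time dropout after each
#' decoder block.
#'
#' The default channel schedule expands by a factor of four per stage and
#' terminates at a 128-channel bottleneck so that two branches can be fused
#' without projection layers; the literal schedule `c(4, 8, 16, 32)` is
#' accepted as well.
#'
#' @param in_channels input modalities (4: T1, T1+Gd, T2, FLAIR).
#' @param n_classes output classes (4: background, FHR, ER, NENR).
#' @param encoder_channels positive integers, one per encoder stage.
#' @param conv_kernel,conv_stride,conv_dilation convolution geometry
#'   (only 3/1/1 is implemented, matching the reference architecture).
#' @param pool_kernel max-pool kernel (only 2 is implemented).
#' @param convs_per_block convolutions per encoder/decoder stage (default
#'   1; classic full-scale U-Nets use 2 — at short optimization horizons
#'   the shallower block trains faster).
#' @param standardize_input z-score each input channel over the volume
#'   before the first convolution (default TRUE).
#' @param decoder_mode one of "variational", "deterministic", "mc_dropout".
#' @param dropout_rate dropout probability in \[0,1) (mc_dropout mode only).
#' @param prior_mean,prior_variance Gaussian weight prior of the
#'   variational layers.
#' @param posterior_init_mean,posterior_init_variance initialization of the
#'   variational posterior (trainable thereafter).
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_channels = 4L, n_classes = 4L,
                           encoder_channels = c(8L, 32L, 128L),
                           conv_kernel = 3L, conv_stride = 1L,
                           conv_dilation = 1L, pool_kernel = 2L,
                           convs_per_block = 1L, standardize_input = TRUE,
                           decoder_mode = c("variational", "deterministic",
                                            "mc_dropout"),
                           dropout_rate = 0.2,
                           prior_mean = 0, prior_variance = 1,
                           posterior_init_mean = 0,
                           posterior_init_variance = 3) {
  decoder_mode <- match.arg(decoder_mode)
  check_scalar_num(in_channels, "in_channels", min = 1)
  check_scalar_num(n_classes, "n_classes", min = 2)
  if (length(encoder_channels) < 2L || any(encoder_channels < 1)) {
    stop_validation("'encoder_channels' must list >= 2 positive stage widths",
                    field = "encoder_channels")
  }
  if (conv_kernel != 3L || conv_stride != 1L || conv_dilation != 1L) {
    stop_validation("only conv kernel 3, stride 1, dilation 1 is implemented",
                    field = "conv_kernel")
  }
  if (pool_kernel != 2L) {
    stop_validation("only pool kernel 2 is implemented", field = "pool_kernel")
  }
  check_scalar_num(convs_per_block, "convs_per_block", min = 1, max = 3)
  check_scalar_num(dropout_rate, "dropout_rate", min = 0, max = 1 - 1e-9)
  check_scalar_num(prior_variance, "prior_variance", min = 1e-12)
  check_scalar_num(posterior_init_variance, "posterior_init_variance",
                   min = 1e-12)
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 encoder_channels = as.integer(encoder_channels),
                 conv_kernel = 3L, conv_stride = 1L, conv_dilation = 1L,
                 pool_kernel = 2L, convs_per_block = as.integer(convs_per_block),
                 standardize_input = isTRUE(standardize_input),
                 decoder_mode = decoder_mode,
                 dropout_rate = dropout_rate,
                 prior_mean = prior_mean, prior_variance = prior_variance,
                 posterior_init_mean = posterior_init_mean,
                 posterior_init_variance = posterior_init_variance),
            class = "network_config")
}

he_init <- function(cout, fanin_cols) {
  matrix(stats::rnorm(cout * fanin_cols, sd = sqrt(2 / fanin_cols)),
         nrow = cout)
}

#' Build a seeded 3D encoder-decoder segmentation network
#'
#' Encoder stages are deterministic 3x3x3 convolutions (instance norm +
#' ReLU) separated by 2x2x2 max pools; the decoder mirrors them with
#' transposed-convolution upsampling, skip concatenation and one
#' convolution per stage. In `variational` mode the decoder convolutions
#' are Flipout layers; the final classification layer is a deterministic
#' 1x1x1 convolution producing `n_classes` logit maps. Parameter
#' initialization is fully determined by `seed`.
#'
#' @param config a [network_config()].
#' @param seed integer seed for parameter initialization.
#' @return An object of class `glioseg_network`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  if (!inherits(config, "network_config")) {
    stop_validation("'config' must be a network_config", field = "config")
  }
  ch <- config$encoder_channels
  S <- length(ch)
  make_var <- function(cout, fan) {
    rho0 <- inv_softplus(sqrt(config$posterior_init_variance))
    list(W_mu = he_init(cout, fan) + config$posterior_init_mean,
         W_rho = matrix(rho0, nrow = cout, ncol = fan))
  }
  K <- config$convs_per_block
  with_seed(seed, {
    params <- list()
    cprev <- config$in_channels
    for (i in seq_len(S)) {
      cin_u <- cprev
      for (u in seq_len(K)) {
        params[[paste0("enc_conv", i, letters[u])]] <-
          list(W = he_init(ch[i], cin_u * 27L))
        cin_u <- ch[i]
      }
      cprev <- ch[i]
    }
    for (i in rev(seq_len(S - 1L))) {
      cin <- ch[i + 1L]; cout <- ch[i]
      params[[paste0("dec_up", i)]] <- list(
        W = array(stats::rnorm(cout * cin * 8L, sd = sqrt(2 / (cin * 8L))),
                  dim = c(cout, cin, 8L)))
      cin_u <- 2L * ch[i]
      for (u in seq_len(K)) {
        nm <- paste0("dec_conv", i, letters[u])
        params[[nm]] <- if (config$decoder_mode == "variational") {
          make_var(ch[i], cin_u * 27L)
        } else {
          list(W = he_init(ch[i], cin_u * 27L))
        }
        cin_u <- ch[i]
      }
    }
    # classification bias initialized to log class priors (background
    # dominant): the network starts by predicting background confidently,
    # so the focal term focuses its gradient on lesion voxels from the
    # first step instead of spending the early steps learning the
    # background prior
    prior <- c(1 - 0.03 * (config$n_classes - 1L),
               rep(0.03, config$n_classes - 1L))
    params$cls <- list(W = he_init(config$n_classes, ch[1L]) / 10,
                       b = log(prior))
    structure(list(config = config, params = params, n_stages = S),
              class = "glioseg_network")
  })
}

# Forward pass over one (C_in, X, Y, Z) volume. `stochastic` activates the
# Flipout perturbations / MC dropout; `want_cache` retains what backward
# needs. Returns logits, final decoder features, KL sum, and the cache.
net_forward <- function(net, x, stochastic = TRUE, want_cache = FALSE) {
  cfg <- net$config
  S <- net$n_stages
  d <- dim(x)
  if (d[1L] != cfg$in_channels) {
    stop_validation(sprintf("input has %d channels, network expects %d",
                            d[1L], cfg$in_channels), field = "input")
  }
  div <- 2^(S - 1L)
  if (any(d[2:4] %% div != 0)) {
    stop_validation(sprintf(
      "spatial dims %s must be divisible by %d for %d pooling stages",
      paste(d[2:4], collapse = "x"), div, S - 1L), field = "input")
  }
  if (cfg$standardize_input) {
    m <- matrix(x, nrow = d[1L])
    mu <- rowMeans(m)
    s <- sqrt(pmax(rowMeans(m * m) - mu * mu, 0)) + 1e-8
    x <- array((m - mu) / s, dim = d)
  }
  K <- cfg$convs_per_block %||% 1L
  cache <- list()
  enc_feats <- vector("list", S)
  h <- x
  # conv + instance norm + ReLU, optionally variational
  unit_fw <- function(h, name, variational) {
    p <- net$params[[name]]
    if (variational) {
      fo <- flipout_fw(h, p$W_mu, p$W_rho, stochastic = stochastic)
      cv <- list(y = fo$y)
    } else {
      cv <- conv3_fw(h, p$W)
      fo <- NULL
    }
    ino <- instnorm_fw(cv$y)
    rl <- relu_fw(ino$y)
    list(y = rl$y, cache = list(fo = fo, cv = cv, ino = ino, rl = rl))
  }
  for (i in seq_len(S)) {
    units <- vector("list", K)
    for (u in seq_len(K)) {
      uu <- unit_fw(h, paste0("enc_conv", i, letters[u]), FALSE)
      h <- uu$y
      units[[u]] <- uu$cache
    }
    enc_feats[[i]] <- h
    if (want_cache) cache[[paste0("enc", i)]] <- list(units = units)
    if (i < S) {
      mp <- maxpool_fw(h)
      h <- mp$y
      if (want_cache) cache[[paste0("pool", i)]] <- mp
    }
  }
  variational <- cfg$decoder_mode == "variational"
  kl <- 0
  for (i in rev(seq_len(S - 1L))) {
    up <- upconv_fw(h, net$params[[paste0("dec_up", i)]]$W)
    skip <- enc_feats[[i]]
    hcat <- array(0, dim = c(2L * dim(skip)[1L], dim(skip)[2:4]))
    hcat[seq_len(dim(skip)[1L]), , , ] <- skip
    hcat[dim(skip)[1L] + seq_len(dim(skip)[1L]), , , ] <- up$y
    h <- hcat
    units <- vector("list", K)
    for (u in seq_len(K)) {
      nm <- paste0("dec_conv", i, letters[u])
      uu <- unit_fw(h, nm, variational)
      h <- uu$y
      units[[u]] <- uu$cache
      if (variational) {
        p <- net$params[[nm]]
        kl <- kl + gaussian_kl(p$W_mu, p$W_rho, cfg$prior_mean,
                               cfg$prior_variance)
      }
    }
    dp <- NULL
    if (cfg$decoder_mode == "mc_dropout" && stochastic) {
      dp <- dropout_fw(h, cfg$dropout_rate)
      h <- dp$y
    }
    if (want_cache) {
      cache[[paste0("dec", i)]] <- list(up = up, units = units,
                                        dp = dp, skip_ch = dim(skip)[1L])
    }
  }
  features <- h
  Wc <- net$params$cls$W
  logits_m <- Wc %*% matrix(h, nrow = dim(h)[1L]) + net$params$cls$b
  logits <- array(logits_m, dim = c(cfg$n_classes, dim(h)[2:4]))
  if (want_cache) cache$features <- features
  list(logits = logits, features = features,
       kl = if (cfg$decoder_mode == "variational") kl else NA_real_,
       cache = if (want_cache) cache else NULL)
}

# Backward pass matching net_forward(want_cache = TRUE). `dlogits` is the
# loss gradient w.r.t. the logits; `kl_weight` adds the KL gradient of the
# variational layers. Returns a grads list parallel to net$params.
net_backward <- function(net, cache, dlogits, kl_weight = 0,
                         dfeatures_extra = NULL) {
  cfg <- net$config
  S <- net$n_stages
  grads <- list()
  h <- cache$features
  hm <- matrix(h, nrow = dim(h)[1L])
  dlm <- matrix(dlogits, nrow = cfg$n_classes)
  grads$cls <- list(W = tcrossprod(dlm, hm), b = rowSums(dlm))
  dh <- array(crossprod(net$params$cls$W, dlm), dim = dim(h))
  if (!is.null(dfeatures_extra)) dh <- dh + dfeatures_extra
  unit_bw <- function(dh, name, uc, variational) {
    dh <- relu_bw(uc$rl, dh)
    dh <- instnorm_bw(uc$ino, dh)
    p <- net$params[[name]]
    if (variational) {
      bw <- flipout_bw(p$W_mu, p$W_rho, uc$fo$cache, dh)
      g <- list(W_mu = bw$dW_mu, W_rho = bw$dW_rho)
      if (kl_weight > 0) {
        kg <- gaussian_kl_grad(p$W_mu, p$W_rho, cfg$prior_mean,
                               cfg$prior_variance)
        g$W_mu <- g$W_mu + kl_weight * kg$dW_mu
        g$W_rho <- g$W_rho + kl_weight * kg$dW_rho
      }
    } else {
      bw <- conv3_bw(p$W, uc$cv, dh)
      g <- list(W = bw$dW)
    }
    grads[[name]] <<- g
    bw$dX
  }
  variational <- cfg$decoder_mode == "variational"
  K <- cfg$convs_per_block %||% 1L
  for (i in seq_len(S - 1L)) {
    cc <- cache[[paste0("dec", i)]]
    if (!is.null(cc$dp)) dh <- dropout_bw(cc$dp, dh)
    for (u in rev(seq_len(K))) {
      dh <- unit_bw(dh, paste0("dec_conv", i, letters[u]), cc$units[[u]],
                    variational)
    }
    dcat <- dh
    cs <- cc$skip_ch
    dskip <- dcat[seq_len(cs), , , , drop = FALSE]
    dup <- dcat[cs + seq_len(cs), , , , drop = FALSE]
    ub <- upconv_bw(net$params[[paste0("dec_up", i)]]$W, cc$up, dup)
    grads[[paste0("dec_up", i)]] <- list(W = ub$dW)
    # gradient flowing into the encoder feature at this resolution: the
    # skip path now, plus the pooled path accumulated below
    cache[[paste0("enc", i)]]$dskip <- dskip
    dh <- ub$dX
  }
  # dh currently sits at the bottleneck input (= pooled enc S-1 output)
  for (i in rev(seq_len(S))) {
    cc <- cache[[paste0("enc", i)]]
    if (i == S) {
      dfeat <- dh
    } else {
      dfeat <- maxpool_bw(cache[[paste0("pool", i)]], dh) + cc$dskip
    }
    for (u in rev(seq_len(K))) {
      dfeat <- unit_bw(dfeat, paste0("enc_conv", i, letters[u]),
                       cc$units[[u]], FALSE)
    }
    dh <- dfeat
  }
  grads
}

#' Total Kullback-Leibler divergence of a variational network
#'
#' Sum of the closed-form Gaussian KL between every variational layer's
#' weight posterior and its prior. Non-negative; zero exactly when every
#' posterior equals its prior.
#'
#' @param net a network built with `decoder_mode = "variational"`.
#' @return A single non-negative number (nats).
#' @export
network_kl <- function(net) {
  if (!inherits(net, "glioseg_network") ||
      net$config$decoder_mode != "variational") {
    stop_validation("network KL is defined only for variational networks",
                    field = "decoder_mode")
  }
  kl <- 0
  for (nm in grep("^dec_conv", names(net$params), value = TRUE)) {
    p <- net$params[[nm]]
    kl <- kl + gaussian_kl(p$W_mu, p$W_rho, net$config$prior_mean,
                           net$config$prior_variance)
  }
  kl
}

#' Parameters of a single variational (Flipout) convolution layer
#'
#' @param weight_mean (C_out x C_in*k^3) matrix of posterior weight means.
#' @param weight_scale_raw matrix of the same shape; the posterior scale is
#'   `softplus(weight_scale_raw)`. Defaults to the value whose mapped
#'   variance equals `posterior_init_variance`.
#' @param prior_mean,prior_variance Gaussian prior on each weight.
#' @param posterior_init_mean,posterior_init_variance posterior
#'   initialization used when `weight_scale_raw` is NULL.
#' @param in_channels number of input channels of the layer.
#' @return An object of class `variational_conv_params`.
#' @export
variational_conv_params <- function(weight_mean, weight_scale_raw = NULL,
                                    prior_mean = 0, prior_variance = 1,
                                    posterior_init_mean = 0,
                                    posterior_init_variance = 3,
                                    in_channels) {
  if (!is.matrix(weight_mean)) {
    stop_validation("'weight_mean' must be a (C_out x C_in*27) matrix",
                    field = "weight_mean")
  }
  if (is.null(weight_scale_raw)) {
    weight_scale_raw <- matrix(inv_softplus(sqrt(posterior_init_variance)),
                               nrow = nrow(weight_mean),
                               ncol = ncol(weight_mean))
  }
  if (!identical(dim(weight_mean), dim(weight_scale_raw))) {
    stop_validation("mean and raw-scale shapes differ", field = "weight_scale_raw")
  }
  if (ncol(weight_mean) %% (27L * in_channels) != 0 &&
      ncol(weight_mean) != in_channels * 27L) {
    stop_validation("'weight_mean' columns must equal in_channels*27",
                    field = "weight_mean")
  }
  check_scalar_num(prior_variance, "prior_variance", min = 1e-300)
  structure(list(weight_mean = weight_mean,
                 weight_scale_raw = weight_scale_raw,
                 prior_mean = prior_mean, prior_variance = prior_variance,
                 in_channels = as.integer(in_channels)),
            class = "variational_conv_params")
}

#' One stochastic forward pass through a variational convolution
#'
#' Convolves with the posterior mean weights and adds a sign-modulated
#' sampled perturbation (Flipout); the perturbation has zero expectation,
#' so over many passes the sample-mean output converges to the mean-weight
#' convolution. Also returns the layer's closed-form KL contribution.
#'
#' @param input feature array dim c(C_in, X, Y, Z).
#' @param params a [variational_conv_params()].
#' @param seed integer seed for the perturbation and sign samples.
#' @param stochastic set FALSE for the mean-weight (deterministic) pass.
#' @return list with `output` (C_out, X, Y, Z) and `kl_contribution`.
#' @export
variational_conv_forward <- function(input, params, seed = 1L,
                                     stochastic = TRUE) {
  if (!inherits(params, "variational_conv_params")) {
    stop_validation("'params' must be variational_conv_params",
                    field = "params")
  }
  if (length(dim(input)) != 4L || dim(input)[1L] != params$in_channels) {
    stop_validation("'input' must be (C_in, X, Y, Z)", field = "input")
  }
  out <- with_seed(seed,
                   flipout_fw(input, params$weight_mean,
                              params$weight_scale_raw,
                              stochastic = stochastic))
  list(output = out$y,
       kl_contribution = gaussian_kl(params$weight_mean,
                                     params$weight_scale_raw,
                                     params$prior_mean,
                                     params$prior_variance))
}

#' Fuse the feature embeddings of two branches
#'
#' The transfer-learning head combines the frozen pretrained branch with
#' the scratch follow-up branch. `sum` adds the two feature tensors
#' element-wise (no projection layer is needed because both branches share
#' the channel schedule); `concat` stacks them along the channel axis.
#'
#' @param pretrained_features,followup_features feature arrays
#'   (C, X, Y, Z) with identical shape.
#' @param mode "sum" or "concat".
#' @return The fused feature array (C or 2C channels).
#' @export
fuse_embeddings <- function(pretrained_features, followup_features,
                            mode = c("sum", "concat")) {
  mode <- match.arg(mode)
  da <- dim(pretrained_features); db <- dim(followup_features)
  if (!identical(da, db)) {
    stop_validation(sprintf("cannot fuse shapes (%s) and (%s)",
                            paste(da, collapse = "x"),
                            paste(db, collapse = "x")), field = "shape")
  }
  if (mode == "sum") {
    pretrained_features + followup_features
  } else {
    out <- array(0, dim = c(2L * da[1L], da[2:4]))
    out[seq_len(da[1L]), , , ] <- pretrained_features
    out[da[1L] + seq_len(da[1L]), , , ] <- followup_features
    out
  }
}
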