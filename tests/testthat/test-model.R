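# Network construction, variational convolution behavior, KL accounting,
# and embedding fusion.

small_cfg <- function(mode = "variational", ...) {
  network_config(encoder_channels = c(4L, 8L), decoder_mode = mode, ...)
}

test_that("the network maps (4, X, Y, Z) volumes to 4-class logits of the same shape", {
  net <- build_network(small_cfg(), seed = 1)
  for (dims in list(c(8, 8, 8), c(16, 8, 8), c(8, 16, 24))) {
    x <- array(rnorm(prod(c(4, dims))), dim = c(4, dims))
    fw <- glioseg:::net_forward(net, x, stochastic = TRUE)
    expect_equal(dim(fw$logits), c(4, dims))
  }
  # indivisible spatial dims are rejected
  xbad <- array(0, dim = c(4, 7, 8, 8))
  expect_error(glioseg:::net_forward(net, xbad),
               class = "glioseg_validation_error")
})

test_that("deterministic decoders repeat; variational decoders vary; seeds reproduce", {
  x <- array(rnorm(4 * 8^3), dim = c(4, 8, 8, 8))
  det <- build_network(small_cfg("deterministic"), seed = 3)
  f1 <- glioseg:::net_forward(det, x, stochastic = TRUE)
  f2 <- glioseg:::net_forward(det, x, stochastic = TRUE)
  expect_identical(f1$logits, f2$logits)
  var_net <- build_network(small_cfg(), seed = 3)
  g1 <- glioseg:::with_seed(11, glioseg:::net_forward(var_net, x, TRUE))
  g2 <- glioseg:::with_seed(12, glioseg:::net_forward(var_net, x, TRUE))
  expect_false(identical(g1$logits, g2$logits))
  g3 <- glioseg:::with_seed(11, glioseg:::net_forward(var_net, x, TRUE))
  expect_identical(g1$logits, g3$logits)
  # parameter initialization is seed-deterministic
  expect_identical(build_network(small_cfg(), seed = 5)$params,
                   build_network(small_cfg(), seed = 5)$params)
})

test_that("the variational convolution degenerates to the mean convolution", {
  set.seed(4)
  W_mu <- matrix(rnorm(2 * 2 * 27), nrow = 2)
  x <- array(rnorm(2 * 6^3), dim = c(2, 6, 6, 6))
  # the mean-weight (deterministic) pass is exactly the plain convolution
  p <- variational_conv_params(W_mu, in_channels = 2L)
  outd <- variational_conv_forward(x, p, seed = 1, stochastic = FALSE)
  plain <- glioseg:::conv3_fw(x, W_mu)$y
  expect_identical(outd$output, plain)
  # a vanishing posterior scale reproduces it in the stochastic path too
  p0 <- variational_conv_params(W_mu, matrix(-50, 2, 54), in_channels = 2L)
  outs <- variational_conv_forward(x, p0, seed = 1, stochastic = TRUE)
  expect_equal(outs$output, plain, tolerance = 1e-12)
})

test_that("layer KL matches the closed form, quadrature, and is zero at the prior", {
  # posterior == prior: N(0,1) against N(0,1)
  W_mu <- matrix(0, 1, 27)
  raw1 <- matrix(glioseg:::inv_softplus(1), 1, 27)
  p_eq <- variational_conv_params(W_mu, raw1, in_channels = 1L)
  x <- array(rnorm(27), dim = c(1, 3, 3, 3))
  expect_equal(variational_conv_forward(x, p_eq)$kl_contribution, 0,
               tolerance = 1e-12)
  # single weight, posterior N(0, 3), prior N(0, 1): 0.5*(3 - 1 + ln(1/3))
  kl1 <- glioseg:::gaussian_kl(matrix(0, 1, 1),
                               matrix(glioseg:::inv_softplus(sqrt(3)), 1, 1))
  expect_equal(kl1, 0.5 * (3 - 1 + log(1 / 3)), tolerance = 1e-9)
  # numerical quadrature of integral q log(q/p)
  q <- function(x) dnorm(x, 0, sqrt(3))
  integrand <- function(x) q(x) * (dnorm(x, 0, sqrt(3), log = TRUE) -
                                     dnorm(x, 0, 1, log = TRUE))
  quad <- integrate(integrand, -30, 30, rel.tol = 1e-10)$value
  expect_equal(kl1, quad, tolerance = 1e-6)
})

test_that("network KL sums the per-layer closed forms and detects the prior", {
  net <- build_network(network_config(encoder_channels = c(4L, 8L, 16L)),
                       seed = 2)
  kl <- network_kl(net)
  manual <- 0
  for (nm in grep("^dec_conv", names(net$params), value = TRUE)) {
    p <- net$params[[nm]]
    manual <- manual + glioseg:::gaussian_kl(p$W_mu, p$W_rho, 0, 1)
  }
  expect_equal(kl, manual, tolerance = 1e-10)
  expect_gt(kl, 0)  # posterior variance init (3) differs from prior (1)
  # set every posterior exactly to the prior
  for (nm in grep("^dec_conv", names(net$params), value = TRUE)) {
    net$params[[nm]]$W_mu[] <- 0
    net$params[[nm]]$W_rho[] <- glioseg:::inv_softplus(1)
  }
  expect_equal(network_kl(net), 0, tolerance = 1e-12)
  net$params$dec_conv1a$W_rho[1] <- glioseg:::inv_softplus(2)
  expect_gt(network_kl(net), 0)
  det <- build_network(small_cfg("deterministic"), seed = 1)
  expect_error(network_kl(det), class = "glioseg_validation_error")
})

test_that("Monte-Carlo sample means converge to the mean-weight pass", {
  set.seed(6)
  W_mu <- matrix(rnorm(108, sd = 0.3), nrow = 2)
  raw <- matrix(glioseg:::inv_softplus(0.15), 2, 54)
  p <- variational_conv_params(W_mu, raw, in_channels = 2L)
  x <- array(rnorm(2 * 5^3), dim = c(2, 5, 5, 5))
  ref <- variational_conv_forward(x, p, stochastic = FALSE)$output
  n <- 10000
  probe <- c(1L, 64L, 200L)  # fixed output voxels
  draws <- matrix(0, n, length(probe))
  glioseg:::with_seed(99, {
    for (t in seq_len(n)) {
      out <- glioseg:::flipout_fw(x, p$weight_mean, p$weight_scale_raw)$y
      draws[t, ] <- out[probe]
    }
  })
  for (j in seq_along(probe)) {
    se <- sd(draws[, j]) / sqrt(n)
    expect_lt(abs(mean(draws[, j]) - ref[probe[j]]), 3 * se + 1e-12)
  }
})

test_that("sample-mean drift to the mean-weight pass shrinks as T grows", {
  net <- build_network(small_cfg(), seed = 8)
  x <- array(rnorm(4 * 8^3), dim = c(4, 8, 8, 8))
  ref <- glioseg:::channel_softmax(
    glioseg:::net_forward(net, x, stochastic = FALSE)$logits)
  drift <- sapply(c(10L, 100L, 1000L), function(T) {
    ss <- sample_predictions(net, x, T_samples = T, seed = 5)
    mean(abs(ss$mean - ref))
  })
  expect_lt(drift[3], drift[1])
})

test_that("embedding fusion follows the sum/concat contracts", {
  a <- array(rnorm(8 * 4^3), dim = c(8, 4, 4, 4))
  zero <- array(0, dim = dim(a))
  expect_identical(fuse_embeddings(a, zero, "sum"), a)
  expect_equal(fuse_embeddings(a, a, "sum"), 2 * a)
  cc <- fuse_embeddings(a, a, "concat")
  expect_equal(dim(cc), c(16, 4, 4, 4))
  expect_identical(cc[1:8, , , ], a)
  b <- array(0, dim = c(8, 4, 4, 2))
  err <- tryCatch(fuse_embeddings(a, b), condition = identity)
  expect_s3_class(err, "glioseg_validation_error")
  expect_match(conditionMessage(err), "8x4x4x2")
})

test_that("configuration validation rejects unsupported geometry", {
  expect_error(network_config(conv_kernel = 5), class = "glioseg_validation_error")
  expect_error(network_config(pool_kernel = 3), class = "glioseg_validation_error")
  expect_error(network_config(encoder_channels = 8L),
               class = "glioseg_validation_error")
  expect_error(network_config(dropout_rate = 1), class = "glioseg_validation_error")
})

test_that("mc_dropout decoders are stochastic at inference", {
  net <- build_network(small_cfg("mc_dropout", dropout_rate = 0.3), seed = 9)
  x <- array(rnorm(4 * 8^3), dim = c(4, 8, 8, 8))
  f1 <- glioseg:::with_seed(1, glioseg:::net_forward(net, x, TRUE))
  f2 <- glioseg:::with_seed(2, glioseg:::net_forward(net, x, TRUE))
  expect_false(identical(f1$logits, f2$logits))
  ss <- sample_predictions(net, x, T_samples = 5, seed = 3)
  expect_gt(max(ss$variance), 0)
})
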