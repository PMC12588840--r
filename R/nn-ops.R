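# Layer primitives for the volumetric encoder-decoder, each with an explicit
# forward cache and a matching backward. Feature tensors are channel-first
# arrays dim = c(C, X, Y, Z); convolution weights are (C_out x C_in*k^3)
# matrices whose column order matches cpp_vol2col (channel fastest, then
# kernel offset).

conv3_fw <- function(x, W) {
  d <- dim(x)
  col <- cpp_vol2col(as.numeric(x), d[1L], d[2L], d[3L], d[4L], 3L)
  y <- W %*% col
  list(y = array(y, dim = c(nrow(W), d[2:4])), col = col, dims_in = d)
}

conv3_bw <- function(W, cache, dY) {
  dYm <- matrix(dY, nrow = nrow(W))
  dW <- tcrossprod(dYm, cache$col)
  d <- cache$dims_in
  dX <- cpp_col2vol(crossprod(W, dYm), d[1L], d[2L], d[3L], d[4L], 3L)
  list(dW = dW, dX = array(dX, dim = d))
}

# Flipout variational convolution: shared Gaussian weight perturbation
# decorrelated across forward passes by rank-one channel sign flips.
# Returns the perturbed response plus everything backward needs; the
# closed-form Gaussian KL against the layer prior is computed separately.
flipout_fw <- function(x, W_mu, W_rho, stochastic = TRUE) {
  d <- dim(x)
  cin <- d[1L]
  col <- cpp_vol2col(as.numeric(x), cin, d[2L], d[3L], d[4L], 3L)
  cache <- list(col = col, dims_in = d, stochastic = stochastic)
  if (stochastic) {
    sigma <- softplus(W_rho)
    eps <- matrix(stats::rnorm(length(W_mu)), nrow = nrow(W_mu))
    s_in <- sample(c(-1, 1), cin, replace = TRUE)
    s_out <- sample(c(-1, 1), nrow(W_mu), replace = TRUE)
    # for a single example the sign-modulated perturbation path collapses
    # to one convolution with the effective weights
    #   W_eff = W_mu + diag(s_out) (sigma*eps) diag(s_in per column block)
    souter <- s_out %o% rep(s_in, times = ncol(W_mu) / cin)
    W_eff <- W_mu + (sigma * eps) * souter
    y <- W_eff %*% col
    cache$eps <- eps
    cache$souter <- souter
    cache$W_eff <- W_eff
  } else {
    y <- W_mu %*% col
  }
  list(y = array(y, dim = c(nrow(W_mu), d[2:4])), cache = cache)
}

flipout_bw <- function(W_mu, W_rho, cache, dY) {
  dYm <- matrix(dY, nrow = nrow(W_mu))
  dW_mu <- tcrossprod(dYm, cache$col)
  d <- cache$dims_in
  if (cache$stochastic) {
    dW_rho <- dW_mu * cache$souter * cache$eps * stats::plogis(W_rho)
    dcol <- crossprod(cache$W_eff, dYm)
  } else {
    dW_rho <- 0 * W_rho
    dcol <- crossprod(W_mu, dYm)
  }
  dX <- cpp_col2vol(dcol, d[1L], d[2L], d[3L], d[4L], 3L)
  list(dW_mu = dW_mu, dW_rho = dW_rho, dX = array(dX, dim = d))
}

# KL(q || p) summed over a layer's weights, q = N(mu, softplus(rho)^2).
gaussian_kl <- function(W_mu, W_rho, prior_mean = 0, prior_variance = 1) {
  s2 <- softplus(W_rho)^2
  sum(0.5 * (s2 / prior_variance + (W_mu - prior_mean)^2 / prior_variance -
               1 + log(prior_variance) - log(s2)))
}

gaussian_kl_grad <- function(W_mu, W_rho, prior_mean = 0, prior_variance = 1) {
  sigma <- softplus(W_rho)
  list(dW_mu = (W_mu - prior_mean) / prior_variance,
       dW_rho = (sigma / prior_variance - 1 / sigma) * stats::plogis(W_rho))
}

instnorm_fw <- function(x, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1L])
  mu <- rowMeans(m)
  v <- rowMeans(m * m) - mu * mu
  s <- sqrt(pmax(v, 0) + eps)
  xhat <- (m - mu) / s
  list(y = array(xhat, dim = d), xhat = xhat, s = s, dims = d)
}

instnorm_bw <- function(cache, dY) {
  dm <- matrix(dY, nrow = cache$dims[1L])
  xhat <- cache$xhat
  dX <- (dm - rowMeans(dm) - xhat * rowMeans(dm * xhat)) / cache$s
  array(dX, dim = cache$dims)
}

relu_fw <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

relu_bw <- function(cache, dY) dY * cache$mask

maxpool_fw <- function(x) {
  d <- dim(x)
  X2 <- d[2L] %/% 2L; Y2 <- d[3L] %/% 2L; Z2 <- d[4L] %/% 2L
  lin <- array(seq_len(prod(d)), dim = d)
  n <- d[1L] * X2 * Y2 * Z2
  M <- matrix(0, nrow = 8L, ncol = n)
  I <- matrix(0L, nrow = 8L, ncol = n)
  o <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    o <- o + 1L
    sx <- seq(1L + dx, d[2L], by = 2L)
    sy <- seq(1L + dy, d[3L], by = 2L)
    sz <- seq(1L + dz, d[4L], by = 2L)
    M[o, ] <- x[, sx, sy, sz]
    I[o, ] <- lin[, sx, sy, sz]
  }
  slot <- max.col(t(M), ties.method = "first")
  pick <- cbind(slot, seq_len(n))
  list(y = array(M[pick], dim = c(d[1L], X2, Y2, Z2)),
       argmax = I[pick], dims_in = d)
}

maxpool_bw <- function(cache, dY) {
  dX <- array(0, dim = cache$dims_in)
  dX[cache$argmax] <- as.numeric(dY)
  dX
}

# Transposed convolution, kernel 2 stride 2 (each output voxel receives
# exactly one kernel tap). Weights: array dim c(C_out, C_in, 8).
upconv_fw <- function(x, W) {
  d <- dim(x)
  cin <- d[1L]; cout <- dim(W)[1L]
  Xm <- matrix(x, nrow = cin)
  y <- array(0, dim = c(cout, 2L * d[2L], 2L * d[3L], 2L * d[4L]))
  o <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    o <- o + 1L
    yo <- W[, , o, drop = FALSE]
    dim(yo) <- c(cout, cin)
    y[, seq(1L + dx, 2L * d[2L], 2L), seq(1L + dy, 2L * d[3L], 2L),
      seq(1L + dz, 2L * d[4L], 2L)] <- yo %*% Xm
  }
  list(y = y, Xm = Xm, dims_in = d)
}

upconv_bw <- function(W, cache, dY) {
  d <- cache$dims_in
  cin <- d[1L]; cout <- dim(W)[1L]
  dW <- array(0, dim = dim(W))
  dXm <- matrix(0, nrow = cin, ncol = ncol(cache$Xm))
  o <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    o <- o + 1L
    dYo <- dY[, seq(1L + dx, 2L * d[2L], 2L), seq(1L + dy, 2L * d[3L], 2L),
              seq(1L + dz, 2L * d[4L], 2L)]
    dYo <- matrix(dYo, nrow = cout)
    dW[, , o] <- tcrossprod(dYo, cache$Xm)
    Wo <- W[, , o, drop = FALSE]
    dim(Wo) <- c(cout, cin)
    dXm <- dXm + crossprod(Wo, dYo)
  }
  list(dW = dW, dX = array(dXm, dim = d))
}

dropout_fw <- function(x, rate) {
  mask <- array(stats::rbinom(length(x), 1L, 1 - rate), dim = dim(x)) /
    (1 - rate)
  list(y = x * mask, mask = mask)
}

dropout_bw <- function(cache, dY) dY * cache$mask
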