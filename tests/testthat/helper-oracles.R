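# Independent oracles used by the tests. These are deliberately naive,
# straight-line implementations kept separate from the package's own code
# paths.

# 26-connectivity dilation of a logical 3D mask by one voxel.
dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out | mask[xs, ys, zs]
  }
  out
}

# Number of 26-connected components of a logical 3D mask (flood fill).
n_components26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  comp <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      ai <- arrayInd(v, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        nx <- ai[1] + dx; ny <- ai[2] + dy; nz <- ai[3] + dz
        if (nx < 1 || ny < 1 || nz < 1 || nx > d[1] || ny > d[2] || nz > d[3]) next
        li <- nx + d[1] * ((ny - 1L) + d[2] * (nz - 1L))
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- comp
          queue <- c(queue, li)
        }
      }
    }
  }
  comp
}

# Brute-force symmetric Hausdorff distance over coordinate matrices.
hausdorff_bruteforce <- function(A, B, spacing = c(1, 1, 1)) {
  As <- sweep(A, 2L, spacing, "*")
  Bs <- sweep(B, 2L, spacing, "*")
  dmin_AB <- apply(As, 1L, function(a) {
    min(sqrt(colSums((t(Bs) - a)^2)))
  })
  dmin_BA <- apply(Bs, 1L, function(b) {
    min(sqrt(colSums((t(As) - b)^2)))
  })
  max(max(dmin_AB), max(dmin_BA))
}

# Straight-line reimplementation of the background-relabeling rule
# (threshold from background mean/sd, candidate means above threshold,
# single candidate wins, multiple resolved by lowest variance, exact ties
# to the lowest class index), looping voxel by voxel.
relabel_bruteforce <- function(mu, va, labels, lambda_) {
  out <- labels
  for (v in seq_along(labels)) {
    if (labels[v] != 0L) next
    thr <- mu[1L, v] - lambda_ * sqrt(va[1L, v])
    cand <- which(mu[2:4, v] > thr)
    if (length(cand) == 0L) next
    if (length(cand) == 1L) {
      out[v] <- cand
    } else {
      vars <- va[1L + cand, v]
      out[v] <- cand[which.min(vars)]
    }
  }
  out
}

# Exact two-sided signed-rank p-value by dynamic programming over the null
# distribution of the positive-rank sum (no ties, no zeros).
wilcoxon_exact_p <- function(d) {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  # distribution of V under the null: polynomial product over ranks
  counts <- c(1, rep(0, n * (n + 1) / 2))
  for (r in seq_len(n)) {
    shifted <- c(rep(0, r), counts)[seq_along(counts)]
    counts <- counts + shifted
  }
  probs <- counts / 2^n
  lo <- sum(probs[seq_len(V + 1L)])          # P(V <= v)
  hi <- sum(probs[seq(V + 1L, length(probs))])  # P(V >= v)
  min(1, 2 * min(lo, hi))
}

# Construct a posterior_sample_set with prescribed per-voxel mean and
# variance matrices (4 x N), bypassing the sample-derived constructor; used
# to exercise individual relabeling branches with illustrative statistics.
fake_sample_set <- function(mu, va, dims, T = 10L) {
  structure(list(samples = array(NA_real_, dim = c(T, 4L, dims)),
                 mean = array(mu, dim = c(4L, dims)),
                 variance = array(va, dim = c(4L, dims)), T = T),
            class = "posterior_sample_set")
}

# Random per-voxel simplex sample array (T, 4, dims...) via normalized
# exponentials.
random_sample_array <- function(T, dims, seed) {
  set.seed(seed)
  n <- prod(dims)
  arr <- array(0, dim = c(T, 4L, dims))
  for (t in seq_len(T)) {
    m <- matrix(stats::rexp(4L * n), nrow = 4L)
    m <- sweep(m, 2L, colSums(m), "/")
    arr[t, , , , ] <- array(m, dim = c(4L, dims))
  }
  arr
}

tiny_phantom_cases <- function(n, shape = c(16L, 16L, 16L), seed = 1L, ...) {
  phantom_corpus(n, phantom_spec(shape = shape, ...), seed = seed)
}
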