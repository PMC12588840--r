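# Posterior sampling statistics, the background threshold, the
# relabeling rule (all four branches + oracle equivalence + lambda
# monotonicity) and the uncertainty maps.

test_that("sample-set mean and variance equal direct recomputation", {
  arr <- random_sample_array(7, c(4, 4, 4), seed = 1)
  ss <- posterior_sample_set(arr)
  expect_equal(ss$T, 7L)
  M <- matrix(arr, nrow = 7)
  expect_equal(as.numeric(ss$mean), colMeans(M), tolerance = 1e-12)
  expect_equal(as.numeric(ss$variance),
               colMeans(M^2) - colMeans(M)^2, tolerance = 1e-12)
  expect_true(all(ss$variance >= 0))
})

test_that("the background threshold follows mu_B - lambda * sigma_B", {
  expect_equal(compute_threshold(0.90, 0.20, 0.1), 0.88)
  expect_equal(compute_threshold(0.90, 0.20, 0), 0.90)
  expect_equal(compute_threshold(0.90, 0, 0.1), 0.90)
  expect_equal(compute_threshold(c(0.5, 0.8), c(0.1, 0.2), 0.5),
               c(0.45, 0.70))
  expect_error(compute_threshold(0.9, -0.1), class = "glioseg_validation_error")
  expect_error(relabel_config(lambda_ = -1), class = "glioseg_validation_error")
})

test_that("each relabeling branch behaves per the rule", {
  dims <- c(1L, 1L, 3L)
  # voxel 1: confident background, no candidate -> unchanged
  # voxel 2: mu_B 0.60 sd 0.10 -> thr 0.59; only ER (0.35) ... use means on
  #          the simplex: ER mean clears the threshold alone
  # voxel 3: two candidates above threshold; lower-variance one wins
  mu <- cbind(c(0.97, 0.01, 0.01, 0.01),
              c(0.45, 0.05, 0.46, 0.04),
              c(0.20, 0.39, 0.38, 0.03))
  va <- cbind(c(0.001, 0.001, 0.001, 0.001),
              c(0.01, 0.001, 0.002, 0.001),
              c(0.04, 0.040, 0.010, 0.001))
  ss <- fake_sample_set(mu, va, dims)
  init <- label_map(array(0L, dim = dims))
  res <- relabel_background_voxels(ss, init, relabel_config(lambda_ = 0.1))
  out <- as.integer(res$labels$labels)
  expect_equal(out[1], 0L)                       # no candidate
  # voxel 2: thr = 0.45 - 0.1*0.1 = 0.44; only ER (0.46) exceeds
  expect_equal(out[2], 2L)
  # voxel 3: thr = 0.20 - 0.1*0.2 = 0.18; FHR (0.39) and ER (0.38) exceed;
  # ER has the smaller variance
  expect_equal(out[3], 2L)
  expect_equal(res$audit$eligible, 3L)
  expect_equal(res$audit$unchanged, 1L)
  expect_equal(res$audit$single_candidate, 1L)
  expect_equal(res$audit$multi_candidate, 1L)
})

test_that("foreground-labeled voxels are never touched", {
  arr <- random_sample_array(6, c(5, 5, 5), seed = 2)
  ss <- posterior_sample_set(arr)
  init <- label_map(array(sample(0:3, 125, replace = TRUE), dim = c(5, 5, 5)))
  res <- relabel_background_voxels(ss, init, relabel_config(lambda_ = 5))
  fg <- init$labels != 0L
  expect_identical(res$labels$labels[fg], init$labels[fg])
})

test_that("relabeling agrees with a straight-line brute-force oracle", {
  for (s in 1:4) {
    arr <- random_sample_array(5, c(10, 10, 10), seed = 100 + s)
    ss <- posterior_sample_set(arr)
    init <- glioseg:::initial_labels(ss)
    for (lam in c(0, 0.1, 0.5, 2)) {
      res <- relabel_background_voxels(ss, init, relabel_config(lambda_ = lam))
      bf <- relabel_bruteforce(matrix(ss$mean, nrow = 4),
                               matrix(ss$variance, nrow = 4),
                               as.integer(init$labels), lam)
      expect_identical(as.integer(res$labels$labels), as.integer(bf))
    }
    # all four branches exercised across the sweep
    res2 <- relabel_background_voxels(ss, init, relabel_config(lambda_ = 2))
    expect_gt(res2$audit$multi_candidate, 0)
  }
})

test_that("an exact variance tie goes to the lowest class index and is flagged", {
  dims <- c(1L, 1L, 1L)
  mu <- matrix(c(0.30, 0.36, 0.34, 0.00), ncol = 1)
  va <- matrix(c(0.01, 0.02, 0.02, 0.001), ncol = 1)
  ss <- fake_sample_set(mu, va, dims)
  res <- relabel_background_voxels(ss, label_map(array(0L, dims)),
                                   relabel_config(lambda_ = 0.1))
  expect_equal(as.integer(res$labels$labels), 1L)  # FHR, the lower index
  expect_equal(res$audit$ties, 1L)
})

test_that("the relabeled set grows monotonically with lambda", {
  arr <- random_sample_array(5, c(8, 8, 8), seed = 9)
  ss <- posterior_sample_set(arr)
  init <- glioseg:::initial_labels(ss)
  lams <- c(0, 0.1, 0.3, 1, 3)
  sets <- lapply(lams, function(l) {
    res <- relabel_background_voxels(ss, init, relabel_config(lambda_ = l))
    which(res$labels$labels != init$labels)
  })
  for (i in seq_along(lams)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
})

test_that("per-case scope pools the background statistics", {
  arr <- random_sample_array(5, c(6, 6, 6), seed = 12)
  ss <- posterior_sample_set(arr)
  init <- glioseg:::initial_labels(ss)
  res <- relabel_background_voxels(ss, init,
                                   relabel_config(lambda_ = 0.1,
                                                  threshold_scope = "per_case"))
  mu <- matrix(ss$mean, nrow = 4); va <- matrix(ss$variance, nrow = 4)
  elig <- which(as.integer(init$labels) == 0L)
  thr <- mean(mu[1, elig]) - 0.1 * sqrt(mean(va[1, elig]))
  bf <- as.integer(init$labels)
  for (v in elig) {
    cand <- which(mu[2:4, v] > thr)
    if (length(cand) == 1L) bf[v] <- cand
    if (length(cand) > 1L) bf[v] <- cand[which.min(va[1 + cand, v])]
  }
  expect_identical(as.integer(res$labels$labels), bf)
  expect_equal(res$audit$scope, "per_case")
})

test_that("uncertainty maps match per-voxel recomputation", {
  arr <- random_sample_array(6, c(4, 4, 4), seed = 3)
  ss <- posterior_sample_set(arr)
  ent <- uncertainty_map(ss, "predictive_entropy")
  mu <- matrix(ss$mean, nrow = 4)
  expect_equal(as.numeric(ent), -colSums(mu * log(mu)) / log(4),
               tolerance = 1e-9)
  pv <- uncertainty_map(ss, "predictive_variance")
  va <- matrix(ss$variance, nrow = 4)
  pred <- apply(mu, 2, which.max)
  expect_equal(as.numeric(pv), va[cbind(pred, seq_len(64))], tolerance = 1e-12)
  # degenerate cases
  const <- array(rep(c(0.25, 0.25, 0.25, 0.25), each = 3), c(3, 4, 2, 2, 2))
  ss2 <- posterior_sample_set(const)
  expect_equal(max(abs(uncertainty_map(ss2, "predictive_variance"))), 0)
  expect_equal(as.numeric(uncertainty_map(ss2, "predictive_entropy")),
               rep(1, 8), tolerance = 1e-9)
})
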