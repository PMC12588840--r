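# Overlap, calibration, selective-prediction and paired-test metrics.

rand_labels <- function(dims, seed) {
  set.seed(seed)
  array(sample(0:3, prod(dims), replace = TRUE,
               prob = c(0.7, 0.15, 0.1, 0.05)), dim = dims)
}

test_that("Dice and Jaccard match their formulas and the algebraic identity", {
  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[2:3, 1, 1] <- 1L
  expect_equal(as.numeric(dice(a, b, 1)), 0.5)       # |A|=2,|B|=2,overlap 1
  expect_equal(as.numeric(jaccard(a, b, 1)), 1 / 3)  # 1 / 3 union
  expect_equal(as.numeric(dice(a, a, 1)), 1)
  expect_equal(as.numeric(jaccard(a, a, 1)), 1)
  disj <- array(0L, c(4, 4, 4)); disj[4, 4, 4] <- 1L
  expect_equal(as.numeric(dice(a, disj, 1)), 0)
  # both-empty convention
  expect_equal(as.numeric(dice(a, a, 3)), 1)
  expect_true(attr(dice(a, a, 3), "both_empty"))
  # JI = DSC / (2 - DSC) on random mask pairs
  for (s in 1:100) {
    p <- rand_labels(c(6, 6, 6), s)
    r <- rand_labels(c(6, 6, 6), s + 1000)
    for (k in 1:3) {
      d <- as.numeric(dice(p, r, k))
      j <- as.numeric(jaccard(p, r, k))
      expect_equal(j, d / (2 - d), tolerance = 1e-12)
    }
  }
})

test_that("Hausdorff distance matches brute force and handles empties", {
  a <- array(0L, c(8, 8, 8)); a[1, 1, 1] <- 1L
  b <- array(0L, c(8, 8, 8)); b[4, 5, 1] <- 1L   # offset (3,4,0): 3-4-5
  expect_equal(hausdorff(a, b, 1), 5)
  expect_equal(hausdorff(a, a, 1), 0)
  empty <- array(0L, c(8, 8, 8))
  expect_equal(hausdorff(empty, empty, 1), 0)
  expect_true(is.nan(hausdorff(a, empty, 1)))
  # random point sets vs O(|X||Y|) oracle, with anisotropic spacing
  for (s in 1:10) {
    set.seed(s)
    p <- array(0L, c(10, 10, 10)); p[sample(1000, 20)] <- 1L
    r <- array(0L, c(10, 10, 10)); r[sample(1000, 20)] <- 1L
    sp <- c(1, 1.5, 3)
    expect_equal(hausdorff(p, r, 1, sp),
                 hausdorff_bruteforce(which(p == 1, arr.ind = TRUE),
                                      which(r == 1, arr.ind = TRUE), sp),
                 tolerance = 1e-10)
  }
})

test_that("ECE is zero when calibrated, and matches per-bin recomputation", {
  set.seed(4)
  n <- 20000
  # perfectly calibrated: confidence 0.8, ~80% correct
  ci <- calibration_input(rep(0.8, n), rbinom(n, 1, 0.8))
  expect_lt(ece(ci), 0.01)
  ci2 <- calibration_input(rep(1, n), rbinom(n, 1, 0.5))
  expect_equal(ece(ci2), abs(1 - mean(ci2$correct)), tolerance = 1e-12)
  # random input vs independent recomputation
  sc <- runif(n); co <- rbinom(n, 1, sc)
  ci3 <- calibration_input(sc, co, M = 15)
  bins <- pmin(floor(sc * 15) + 1, 15)
  exp_ece <- sum(sapply(1:15, function(m) {
    sel <- bins == m
    if (!any(sel)) return(0)
    sum(sel) / n * abs(mean(co[sel]) - mean(sc[sel]))
  }))
  expect_equal(ece(ci3), exp_ece, tolerance = 1e-12)
})

test_that("UCE measures the uncertainty/error gap", {
  set.seed(5)
  n <- 20000
  u <- runif(n)
  correct <- rbinom(n, 1, 1 - u)  # error rate equals uncertainty: calibrated
  expect_lt(uce(calibration_input(u, correct)), 0.02)
  # uncertainty all 0 with 30% errors
  ci <- calibration_input(rep(0, n), rbinom(n, 1, 0.7))
  expect_equal(uce(ci), 1 - mean(ci$correct), tolerance = 1e-12)
  # recomputation oracle
  ci3 <- calibration_input(u, correct, M = 10)
  bins <- pmin(floor(u * 10) + 1, 10)
  exp_uce <- sum(sapply(1:10, function(m) {
    sel <- bins == m
    if (!any(sel)) return(0)
    sum(sel) / n * abs((1 - mean(correct[sel])) - mean(u[sel]))
  }))
  expect_equal(uce(ci3), exp_uce, tolerance = 1e-12)
})

test_that("reliability curve is consistent with the ECE it summarizes", {
  set.seed(6)
  n <- 50000
  sc <- runif(n); co <- rbinom(n, 1, sc)
  ci <- calibration_input(sc, co)
  tb <- reliability_curve(ci)
  expect_equal(sum(tb$count), n)
  expect_equal(sum(tb$count / n * abs(tb$accuracy - tb$mean_score)), ece(ci),
               tolerance = 1e-12)
  # calibrated input: occupied bins near the diagonal within binomial error
  big <- tb[tb$count > 500, ]
  se <- sqrt(big$mean_score * (1 - big$mean_score) / big$count)
  expect_true(all(abs(big$accuracy - big$mean_score) < 4 * se + 1 / ci$M))
  one <- calibration_input(rep(0.5, 100), rbinom(100, 1, 0.5))
  expect_equal(nrow(reliability_curve(one)), 1L)
  expect_equal(reliability_curve(one)$count, 100L)
})

test_that("Brier and NLL match direct evaluation", {
  set.seed(7)
  out <- rbinom(500, 1, 0.4)
  expect_equal(brier(as.numeric(out), out), 0)
  expect_equal(brier(rep(0.5, 500), out), 0.25, tolerance = 1e-12)
  p <- runif(500)
  expect_equal(brier(p, out), mean((p - out)^2), tolerance = 1e-12)
  expect_equal(nll(rep(1, 10)), 0)
  expect_equal(nll(rep(0.5, 10)), log(2), tolerance = 1e-12)
  expect_gte(nll(runif(100)), 0)
})

test_that("error-detection ROC: perfect detector, null detector, rank oracle", {
  set.seed(8)
  correct <- rbinom(2000, 1, 0.7)
  perfect <- 1 - correct
  expect_equal(error_detection_roc(perfect, correct)$auroc, 1)
  indep <- runif(20000)
  c2 <- rbinom(20000, 1, 0.6)
  expect_lt(abs(error_detection_roc(indep, c2)$auroc - 0.5), 0.02)
  # AUROC equals the normalized Mann-Whitney U statistic
  u <- runif(500)
  c3 <- rbinom(500, 1, plogis(2 - 4 * u))
  err <- c3 == 0
  rks <- rank(u)
  U <- sum(rks[err]) - sum(err) * (sum(err) + 1) / 2
  expect_equal(error_detection_roc(u, c3)$auroc, U / (sum(err) * sum(!err)),
               tolerance = 1e-10)
  expect_error(error_detection_roc(runif(5), rep(1, 5)),
               class = "glioseg_validation_error")
})

test_that("risk-coverage curve orders risk and ends at the overall error rate", {
  set.seed(9)
  n <- 1000
  correct <- rbinom(n, 1, 0.8)
  # ideal ranking: all errors least confident
  conf <- ifelse(correct == 1, runif(n, 0.5, 1), runif(n, 0, 0.5))
  rc <- risk_coverage_curve(conf, correct)
  acc <- mean(correct)
  expect_true(all(rc$risk[rc$coverage <= acc - 0.01] == 0))
  expect_equal(rc$risk[n], 1 - acc, tolerance = 1e-12)
  # constant confidence keeps risk near-flat at the overall error rate at
  # full coverage
  rc2 <- risk_coverage_curve(rep(0.7, n), correct)
  expect_equal(rc2$risk[n], 1 - acc, tolerance = 1e-12)
})

test_that("paired Wilcoxon matches exact-null enumeration and Bonferroni caps", {
  set.seed(10)
  a <- runif(20, 0.5, 0.9)
  b <- a + 0.1
  res <- paired_wilcoxon(a, b)
  expect_lt(res$p_value, 0.01)
  # distinct all-positive shifts engage the exact path; compare with the
  # enumerated null (all-positive signs put V at the distribution's tip,
  # p = 2 / 2^n)
  b2 <- a + 0.1 + seq_len(20) / 1e4
  res_u <- paired_wilcoxon(a, b2)
  expect_equal(res_u$p_value, wilcoxon_exact_p(b2 - a), tolerance = 1e-12)
  expect_equal(res_u$p_value, 2 / 2^20, tolerance = 1e-15)
  # a mixed-sign paired sample against the enumeration oracle
  d <- c(0.21, -0.13, 0.34, 0.05, -0.41, 0.27, 0.18, -0.02, 0.09, 0.3)
  res2 <- paired_wilcoxon(a[1:10], a[1:10] + d)
  expect_equal(res2$p_value, wilcoxon_exact_p(d), tolerance = 1e-12)
  expect_error(paired_wilcoxon(a, a), class = "glioseg_validation_error")
  expect_equal(paired_wilcoxon(a, b, n_comparisons = 3)$p_adjusted,
               min(1, res$p_value * 3))
  res3 <- paired_wilcoxon(a[1:8], a[1:8] + rep(c(0.2, -0.01), 4),
                          n_comparisons = 50)
  expect_lte(res3$p_adjusted, 1)
})
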