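# Composite objective: generalized Dice loss, focal loss, KL divergence,
# and the assembled total loss.

make_pair <- function(r, p) soft_label_pair(r, p)

test_that("generalized Dice loss hits its perfect- and zero-overlap limits", {
  set.seed(1)
  lab <- c(rep(0, 10), rep(1, 5), rep(2, 3), rep(3, 2))
  r <- glioseg:::one_hot(lab)
  expect_lt(generalized_dice_loss(make_pair(r, r)), 1e-4)
  # probability 1 on a wrong class everywhere
  wrong <- glioseg:::one_hot((lab + 1) %% 4)
  expect_equal(generalized_dice_loss(make_pair(r, wrong)), 1, tolerance = 1e-6)
})

test_that("generalized Dice loss matches term-by-term evaluation on a hand example", {
  # 2 voxels, one-hot over 4 classes (background + 3 foreground)
  r <- matrix(c(0, 1, 0, 0,
                0, 0, 1, 0), nrow = 4)
  p <- matrix(c(0.1, 0.6, 0.2, 0.1,
                0.2, 0.1, 0.5, 0.2), nrow = 4)
  eps <- 1e-5
  w <- 1 / (c(1, 1) + eps)               # class volumes: FHR 1, ER 1
  w <- c(w, max(w))                      # absent NENR capped at max present
  num <- w[1] * 0.6 + w[2] * 0.5 + w[3] * 0
  den <- w[1] * (1 + 0.7) + w[2] * (1 + 0.7) + w[3] * (0 + 0.3)
  expect_equal(generalized_dice_loss(make_pair(r, p), eps), 1 - 2 * num / den,
               tolerance = 1e-12)
})

test_that("GDL is invariant to voxel order and to relative class volumes at optimum", {
  set.seed(7)
  lab <- sample(0:3, 200, replace = TRUE)
  r <- glioseg:::one_hot(lab)
  p <- matrix(rexp(4 * 200), nrow = 4)
  p <- sweep(p, 2, colSums(p), "/")
  v1 <- generalized_dice_loss(make_pair(r, p))
  perm <- sample(200)
  v2 <- generalized_dice_loss(make_pair(r[, perm], p[, perm]))
  expect_equal(v1, v2, tolerance = 1e-12)
  # perfect predictions give ~0 regardless of class volumes
  for (sizes in list(c(50, 5, 1), c(3, 90, 7), c(1, 1, 200))) {
    lab <- rep(c(1, 2, 3, 0), c(sizes, 30))
    r <- glioseg:::one_hot(lab)
    expect_lt(generalized_dice_loss(make_pair(r, r)), 1e-3)
  }
})

test_that("focal loss reduces to cross-entropy at gamma 0 and matches the printed formula", {
  set.seed(2)
  lab <- sample(0:3, 50, replace = TRUE)
  r <- glioseg:::one_hot(lab)
  p <- matrix(rexp(200), nrow = 4)
  p <- sweep(p, 2, colSums(p), "/")
  pair <- make_pair(r, p)
  pt <- colSums(r * p)
  expect_equal(focal_loss(pair, 0), mean(-log(pt)), tolerance = 1e-10)
  # single voxel, p_t = 0.5, gamma = 2
  r1 <- matrix(c(0, 1, 0, 0), nrow = 4)
  p1 <- matrix(c(0.3, 0.5, 0.1, 0.1), nrow = 4)
  expect_equal(focal_loss(make_pair(r1, p1), 2), -0.25 * log(0.5),
               tolerance = 1e-12)
  # perfect prediction
  expect_equal(focal_loss(make_pair(r1, r1), 2), 0, tolerance = 1e-6)
})

test_that("focal loss decreases as the true-class probability increases", {
  r <- matrix(c(0, 1, 0, 0), nrow = 4)
  pts <- seq(0.1, 0.9, by = 0.1)
  vals <- sapply(pts, function(pt) {
    p <- matrix(c((1 - pt) / 3, pt, (1 - pt) / 3, (1 - pt) / 3), nrow = 4)
    focal_loss(make_pair(r, p), 2)
  })
  expect_true(all(diff(vals) < 0))
})

test_that("the weighted sum assembles exactly from its components", {
  set.seed(3)
  lab <- sample(0:3, 64, replace = TRUE)
  r <- glioseg:::one_hot(lab)
  p <- matrix(rexp(4 * 64), nrow = 4)
  p <- sweep(p, 2, colSums(p), "/")
  pair <- make_pair(r, p)
  g <- generalized_dice_loss(pair)
  f <- focal_loss(pair, 2)
  expect_equal(generalized_dice_focal_loss(pair, loss_config(lambda_fl = 0),
                                           gamma = 2), g)
  expect_equal(generalized_dice_focal_loss(pair, loss_config(lambda_gdl = 0),
                                           gamma = 2), f)
  expect_equal(generalized_dice_focal_loss(pair, loss_config(), gamma = 2),
               g + f, tolerance = 1e-12)
  # full total with KL and NENR terms
  nce <- glioseg:::nenr_cross_entropy(pair)
  cfg <- loss_config(kl_weight = 0.25, nenr_ce_weight = 0.5)
  expect_equal(total_loss(pair, network_kl = 2, config = cfg, gamma = 2),
               g + f + 0.25 * 2 + 0.5 * nce, tolerance = 1e-12)
  cfg0 <- loss_config(kl_weight = 0, nenr_ce_weight = 0)
  expect_equal(total_loss(pair, network_kl = 5, config = cfg0, gamma = 2),
               g + f, tolerance = 1e-12)
})

test_that("a perfect prediction with posterior at prior scores ~zero total loss", {
  lab <- c(rep(0, 5), 1, 1, 2, 3, 3)
  r <- glioseg:::one_hot(lab)
  pair <- make_pair(r, r)
  v <- total_loss(pair, network_kl = 0,
                  config = loss_config(kl_weight = 1, nenr_ce_weight = 1),
                  gamma = 2)
  expect_lt(v, 1e-3)
})

test_that("discrete KL matches direct evaluation, is asymmetric and validates", {
  expect_equal(kl_divergence_discrete(c(0.25, 0.75), c(0.25, 0.75)), 0)
  v <- kl_divergence_discrete(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(v, 0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(v, kl_divergence_discrete(c(0.25, 0.75),
                                                          c(0.5, 0.5)))))
  expect_gt(v, 0)
  expect_error(kl_divergence_discrete(c(0.5, 0.5), c(1, 0)),
               class = "glioseg_validation_error")
  expect_error(kl_divergence_discrete(c(0.5, 0.5), c(0.5, 0.4)),
               class = "glioseg_validation_error")
})

test_that("loss configuration and pair validation reject bad input", {
  expect_error(loss_config(lambda_gdl = 0, lambda_fl = 0),
               class = "glioseg_validation_error")
  expect_error(focal_loss(make_pair(glioseg:::one_hot(0:3),
                                    glioseg:::one_hot(0:3)), gamma = -1),
               class = "glioseg_validation_error")
  bad_p <- matrix(c(0.9, 0.9, 0.1, 0.1), nrow = 4, ncol = 4)
  expect_error(soft_label_pair(glioseg:::one_hot(0:3), bad_p),
               class = "glioseg_validation_error")
})

test_that("analytic loss gradients match finite differences", {
  set.seed(11)
  lab <- sample(0:3, 30, replace = TRUE)
  r <- glioseg:::one_hot(lab)
  p <- matrix(rexp(120), nrow = 4)
  p <- sweep(p, 2, colSums(p), "/")
  pair <- glioseg:::soft_label_pair_fast(r, p)
  checks <- list(
    gdl = list(f = function(pp) generalized_dice_loss(
      glioseg:::soft_label_pair_fast(r, pp)),
      g = glioseg:::gdl_grad(pair)),
    fl = list(f = function(pp) focal_loss(
      glioseg:::soft_label_pair_fast(r, pp), 1.7),
      g = glioseg:::fl_grad(pair, 1.7)$dp),
    nce = list(f = function(pp) glioseg:::nenr_cross_entropy(
      glioseg:::soft_label_pair_fast(r, pp)),
      g = glioseg:::nenr_ce_grad(pair)))
  for (nm in names(checks)) {
    ck <- checks[[nm]]
    idx <- sample(length(p), 12)
    for (i in idx) {
      eps <- 1e-6
      p2 <- p; p2[i] <- p2[i] + eps
      p3 <- p; p3[i] <- p3[i] - eps
      fd <- (ck$f(p2) - ck$f(p3)) / (2 * eps)
      expect_equal(ck$g[i], fd, tolerance = 1e-4,
                   label = sprintf("%s grad at %d", nm, i))
    }
  }
})
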