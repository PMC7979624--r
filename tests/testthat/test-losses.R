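test_that("perfect one-hot prediction gives zero XCE, Dice, and combined loss", {
  set.seed(21)
  lab <- array(sample(0:5, 4 * 4 * 4, TRUE), c(4, 4, 4))
  p <- one_hot_field(lab)
  expect_equal(xce_loss(p, lab), 0)
  expect_equal(generalized_dice_loss(p, lab), 0, tolerance = 1e-12)
  expect_equal(combined_loss(p, lab), 0, tolerance = 1e-12)
})

test_that("uniform prediction over 6 classes gives XCE = ln 6", {
  lab <- array(sample(0:5, 27, TRUE), c(3, 3, 3))
  p <- array(1 / 6, c(3, 3, 3, 6))
  expect_equal(xce_loss(p, lab), log(6), tolerance = 1e-12)
})

test_that("XCE counts only non-ignored voxels (hand case: 5 kept at p=0.5)", {
  # 10 voxels, 5 ignored; every kept voxel assigns probability 0.5 to its
  # true class -> -(1/5) * 5 * log(0.5) = ln 2
  lab <- array(c(rep(1L, 5), rep(255L, 5)), c(10, 1, 1))
  p <- array(1 / 6, c(10, 1, 1, 6))
  p[1:5, 1, 1, ] <- rep(c(0.1, 0.5, 0.1, 0.1, 0.1, 0.1), each = 5)
  expect_equal(xce_loss(p, lab), log(2), tolerance = 1e-12)
})

test_that("all-ignored supervision warns and returns 0", {
  lab <- array(255L, c(2, 2, 2))
  p <- array(1 / 6, c(2, 2, 2, 6))
  expect_warning(v <- xce_loss(p, lab), "ignored")
  expect_equal(v, 0)
})

test_that("generalized Dice matches a 4-voxel hand computation (C = 3)", {
  # voxels n = 1..4, classes 0 (background), 1, 2; voxel 4 ignored.
  # labels: 1, 1, 2, (255); probabilities per voxel (rows n, cols class):
  P <- rbind(c(0.2, 0.7, 0.1),
             c(0.5, 0.3, 0.2),
             c(0.1, 0.3, 0.6),
             c(1.0, 0.0, 0.0))
  lab <- array(c(1L, 1L, 2L, 255L), c(4, 1, 1))
  probs <- array(P, c(4, 1, 1, 3))
  eps <- 1e-5
  # independent direct evaluation over the 3 kept voxels:
  # class 1: num = 2*(0.7 + 0.3) + eps; den = (0.7+0.3+0.3) + 2 + eps
  # class 2: num = 2*0.6 + eps;         den = (0.1+0.2+0.6) + 1 + eps
  t1 <- (2 * (0.7 + 0.3) + eps) / ((0.7 + 0.3 + 0.3) + 2 + eps)
  t2 <- (2 * 0.6 + eps) / ((0.1 + 0.2 + 0.6) + 1 + eps)
  expected <- 1 - (t1 + t2) / 2
  got <- generalized_dice_loss(probs, lab, loss_config(epsilon = eps))
  expect_equal(got, expected, tolerance = 1e-12)
  # combined loss is the weighted sum of the two components
  expect_equal(combined_loss(probs, lab),
               0.5 * xce_loss(probs, lab) + 0.5 * got, tolerance = 1e-12)
})

test_that("fully disjoint foreground prediction drives the Dice loss to 1", {
  # truth cycles through all five foreground classes; the prediction puts
  # all mass on the "next" class, so every foreground overlap is empty
  lab_v <- rep(1:5, length.out = 60)
  lab <- array(as.integer(lab_v), c(60, 1, 1))
  p <- matrix(0, 60, 6)
  p[cbind(1:60, (lab_v %% 5) + 2L)] <- 1
  probs <- array(p, c(60, 1, 1, 6))
  l5 <- generalized_dice_loss(probs, lab, loss_config(epsilon = 1e-5))
  expect_gt(l5, 1 - 1e-4)
  expect_true(l5 <= 1)

  # a foreground class absent from both truth and prediction contributes
  # eps/eps = 1 (no penalty): with truth all class 1 and prediction all
  # class 2, classes 3..5 are absent -> loss = 1 - 3/5 + O(eps)
  lab1 <- array(1L, c(4, 4, 4))
  p1 <- array(0, c(4, 4, 4, 6)); p1[, , , 3] <- 1
  expect_equal(generalized_dice_loss(p1, lab1, loss_config(epsilon = 1e-5)),
               1 - 3 / 5, tolerance = 1e-3)
})

test_that("epsilon only perturbs the Dice loss at its own scale", {
  set.seed(22)
  lab <- array(sample(0:5, 512, TRUE), c(8, 8, 8))
  p <- array(runif(512 * 6), c(8, 8, 8, 6))
  p <- p / array(rep(apply(p, 1:3, sum), 6), dim(p))
  l1 <- generalized_dice_loss(p, lab, loss_config(epsilon = 1))
  l2 <- generalized_dice_loss(p, lab, loss_config(epsilon = 1e-5))
  l3 <- generalized_dice_loss(p, lab, loss_config(epsilon = 1e-9))
  expect_lt(abs(l2 - l3), 1e-4)       # converged as eps -> 0
  expect_lt(abs(l1 - l3), 0.05)       # eps = 1 already close on 512 voxels
  expect_true(l2 >= 0 && l2 <= 1)
})

test_that("ignored voxels contribute exactly zero loss gradient", {
  set.seed(23)
  lab <- array(sample(c(0:5, 255L), 64, TRUE), c(4, 4, 4))
  p <- array(runif(64 * 6), c(4, 4, 4, 6))
  p <- p / array(rep(apply(p, 1:3, sum), 6), dim(p))
  g <- bodycomp:::combined_loss_grad(p, lab, loss_config())
  ign <- which(lab == 255L)
  gm <- bodycomp:::channel_mat(g)
  expect_true(all(gm[ign, ] == 0))
  # and perturbing an ignored voxel's probabilities leaves the loss unchanged
  l0 <- combined_loss(p, lab)
  p2 <- p
  pm <- bodycomp:::channel_mat(p2)
  pm[ign[1], ] <- rev(pm[ign[1], ])
  p2 <- array(pm, dim(p))
  expect_equal(combined_loss(p2, lab), l0, tolerance = 1e-12)
})

test_that("losses are permutation-invariant over voxels", {
  set.seed(24)
  lab_v <- sample(c(0:5, 255L), 60, TRUE)
  p_m <- matrix(runif(60 * 6), 60)
  p_m <- p_m / rowSums(p_m)
  perm <- sample(60)
  as_field <- function(lv, pm) list(
    lab = array(lv, c(60, 1, 1)), p = array(pm, c(60, 1, 1, 6)))
  a <- as_field(lab_v, p_m)
  b <- as_field(lab_v[perm], p_m[perm, ])
  expect_equal(xce_loss(a$p, a$lab), xce_loss(b$p, b$lab))
  expect_equal(generalized_dice_loss(a$p, a$lab),
               generalized_dice_loss(b$p, b$lab))
})

test_that("dice_score: identity, disjoint, hand count, symmetry, empties", {
  a <- array(0L, c(2, 4, 4)); a[1, 1, 1:2] <- 1L
  expect_equal(dice_score(a, a, 1L), 1)
  b <- array(0L, c(2, 4, 4)); b[2, 1, 1:2] <- 1L
  expect_equal(dice_score(a, b, 1L), 0)
  # P = 2 voxels, T = 4 voxels, overlap 2 -> 2*2 / (2+4)
  t4 <- array(0L, c(2, 4, 4)); t4[1, 1, 1:4] <- 1L
  expect_equal(dice_score(a, t4, 1L), 2 * 2 / (2 + 4))
  expect_equal(dice_score(t4, a, 1L), dice_score(a, t4, 1L))
  # both empty -> 1; unknown code -> error
  expect_equal(dice_score(a, b, 5L), 1)
  expect_error(dice_score(a, b, 9L), "unknown")
  # ignored voxels are excluded in either map
  t5 <- t4; t5[1, 1, 3:4] <- 255L
  expect_equal(dice_score(a, t5, 1L), 1)
})

test_that("ICC(2,1) matches an aov-based ANOVA oracle and penalizes bias", {
  a <- c(10, 12, 14, 20, 25, 31)
  b <- c(11, 13, 13, 22, 26, 33)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- anova(stats::lm(y ~ subj + rater, df))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2; n <- 6
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(icc(a, b), oracle, tolerance = 1e-12)

  expect_equal(icc(a, a), 1)
  expect_lt(icc(a, a + 5), 1)           # absolute agreement penalizes shift
  expect_error(icc(rep(3, 5), rep(3, 5)), "zero variance")
  expect_error(icc(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman statistics are exact for a known shift", {
  a <- c(1, 2, 3, 4); b <- a - 2
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa_lo, 2)
  expect_equal(ba$loa_hi, 2)
})
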