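test_that("cross-entropy matches hand evaluation and its fixed points", {
  # single pixel, b = 1, a = 0.5 -> -ln(0.5)
  expect_equal(cross_entropy(matrix(0.5), matrix(1)), 0.6931472, tolerance = 1e-6)
  # perfect confident prediction: loss at the clipping floor
  expect_lt(cross_entropy(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 1e-6)
  set.seed(31)
  pr <- rand_prob_pair()
  # brute-force elementwise oracle
  a <- pmin(pmax(pr$pred, 1e-7), 1 - 1e-7)
  manual <- 0
  for (i in seq_along(a))
    manual <- manual - (pr$gt[i] * log(a[i]) + (1 - pr$gt[i]) * log(1 - a[i]))
  expect_equal(cross_entropy(pr$pred, pr$gt), manual / length(a), tolerance = 1e-12)
  expect_error(cross_entropy(matrix(0.5, 2, 2), matrix(1, 3, 3)), "differ")
})

test_that("focal loss reduces to cross-entropy at alpha=1, gamma=0 and matches brute force", {
  set.seed(32)
  for (i in 1:10) {
    pr <- rand_prob_pair()
    expect_lt(abs(focal(pr$pred, pr$gt, alpha = 1, gamma = 0) -
                    cross_entropy(pr$pred, pr$gt)), 1e-9)
    # gamma down-weights: modulating factors are <= 1
    expect_lte(focal(pr$pred, pr$gt, alpha = 1, gamma = 2),
               focal(pr$pred, pr$gt, alpha = 1, gamma = 0))
  }
  pr <- rand_prob_pair()
  a <- pmin(pmax(pr$pred, 1e-7), 1 - 1e-7)
  b <- pr$gt
  manual <- mean(-(1 * (1 - a)^2 * b * log(a) + a^2 * (1 - b) * log(1 - a)))
  expect_equal(focal(pr$pred, pr$gt, 1, 2), manual, tolerance = 1e-12)
  expect_lt(focal(array(c(1, 0), c(1, 1, 2, 1)), array(c(1, 0), c(1, 1, 2, 1))), 1e-6)
  expect_error(focal(pr$pred, pr$gt, alpha = 0), "alpha")
  expect_error(focal(pr$pred, pr$gt, gamma = -1), "gamma")
})

test_that("dice loss matches set arithmetic and complements the dice score", {
  m <- matrix(0, 4, 4); m[1:2, 1:2] <- 1
  expect_lt(dice_loss(m, m), 1e-6)
  disj <- matrix(0, 4, 4); disj[3:4, 3:4] <- 1
  expect_equal(dice_loss(m, disj), 1, tolerance = 1e-6)
  # |A| = |B| = 4 with overlap 2 -> 1 - 2*2/8 = 0.5
  half <- matrix(0, 4, 4); half[2:3, 1:2] <- 1
  expect_equal(dice_loss(m, half), 0.5, tolerance = 1e-6)
  set.seed(33)
  for (i in 1:20) {
    a <- rand_mask(8, 8) * 1
    b <- rand_mask(8, 8) * 1
    expect_equal(dice_loss(a, b) + dice_score(a, b), 1, tolerance = 1e-5)
  }
})

test_that("combined losses are weighted sums of their terms", {
  set.seed(34)
  pr <- rand_prob_pair()
  expect_identical(combined_loss(pr$pred, pr$gt, loss_config("cross_entropy")),
                   cross_entropy(pr$pred, pr$gt))
  both <- combined_loss(pr$pred, pr$gt, loss_config("dice+ce"))
  expect_lt(abs(both - (dice_loss(pr$pred, pr$gt) + cross_entropy(pr$pred, pr$gt))),
            1e-9)
  all3 <- combined_loss(pr$pred, pr$gt, loss_config("dice+focal+ce"))
  expect_lt(abs(all3 - (dice_loss(pr$pred, pr$gt) +
                          focal(pr$pred, pr$gt, 1, 2) +
                          cross_entropy(pr$pred, pr$gt))), 1e-9)
  w <- combined_loss(pr$pred, pr$gt, loss_config("dice+ce", weights = c(0.5, 2)))
  expect_lt(abs(w - (0.5 * dice_loss(pr$pred, pr$gt) +
                       2 * cross_entropy(pr$pred, pr$gt))), 1e-9)
  expect_error(loss_config("dice+ce", weights = c(0, 0)), "not all zero")
  expect_error(loss_config("hinge"), "arg")
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(35)
  pr <- rand_prob_pair(c(4, 4, 3, 1))
  for (kind in c("cross_entropy", "focal", "dice", "dice+focal+ce")) {
    cfg <- loss_config(kind)
    g <- combined_loss_grad_for_test(pr$pred, pr$gt, cfg)
    for (trial in 1:5) {
      i <- sample(length(pr$pred), 1)
      eps <- 1e-6
      up <- pr$pred; up[i] <- up[i] + eps
      dn <- pr$pred; dn[i] <- dn[i] - eps
      num <- (combined_loss(up, pr$gt, cfg) - combined_loss(dn, pr$gt, cfg)) / (2 * eps)
      expect_lt(abs(num - g[i]), 1e-5 * max(1, abs(num)), label = kind)
    }
  }
})
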