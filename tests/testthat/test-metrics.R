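test_that("dice score follows set arithmetic and the empty-mask conventions", {
  m <- rand_mask(10, 10)
  expect_equal(dice_score(m, m), 1)
  a <- matrix(FALSE, 6, 6); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 6, 6); b[5:6, 5:6] <- TRUE
  expect_equal(dice_score(a, b), 0)
  # |A| = |B| = 4, overlap 2
  c2 <- matrix(FALSE, 6, 6); c2[2:3, 1:2] <- TRUE
  expect_equal(dice_score(a, c2), 0.5)
  empty <- matrix(FALSE, 6, 6)
  expect_equal(dice_score(empty, empty), 1)
  expect_equal(dice_score(a, empty), 0)
  # symmetric in its arguments
  set.seed(41)
  x <- rand_mask(12, 12); y <- rand_mask(12, 12)
  expect_equal(dice_score(x, y), dice_score(y, x))
})

test_that("RAVD is the signed percent volume difference", {
  a <- matrix(FALSE, 10, 10); a[1:5, 1:4] <- TRUE      # 20 px
  expect_equal(ravd(a, a), 0)
  b <- matrix(FALSE, 10, 10); b[1:6, 1:4] <- TRUE      # 24 px
  expect_equal(ravd(a, b), 20)
  expect_equal(ravd(a, matrix(FALSE, 10, 10)), -100)
  expect_error(ravd(matrix(FALSE, 4, 4), a[1:4, 1:4]), "empty")
  # not symmetric
  expect_false(isTRUE(all.equal(ravd(a, b), ravd(b, a))))
})

test_that("Hausdorff distance: hand cases, directed asymmetry, spacing awareness", {
  m <- rand_mask(12, 12)
  expect_equal(hausdorff(m, m, mode = "directed"), 0)
  a <- matrix(FALSE, 5, 6); a[1, 1] <- TRUE
  b <- matrix(FALSE, 5, 6); b[4, 5] <- TRUE
  expect_equal(hausdorff(a, b), 5)                      # 3-4-5 triangle
  expect_equal(hausdorff(a, b, spacing = c(2, 2)), 10)  # mm scaling
  # directed vs symmetric on nested masks
  big <- matrix(FALSE, 20, 20); big[5:16, 5:16] <- TRUE
  small <- matrix(FALSE, 20, 20); small[10:11, 10:11] <- TRUE
  expect_false(isTRUE(all.equal(hausdorff(big, small), hausdorff(small, big))))
  expect_equal(hausdorff(big, small, mode = "symmetric"),
               max(hausdorff(big, small), hausdorff(small, big)))
  expect_error(hausdorff(matrix(FALSE, 3, 3), a[1:3, 1:3]), "empty")
})

test_that("Hausdorff and MSD match the brute-force all-pairs oracle", {
  set.seed(42)
  for (i in 1:25) {
    nr <- sample(8:32, 1); nc <- sample(8:32, 1)
    A <- rand_mask(nr, nc, p = 0.25, min_pixels = 3)
    B <- rand_mask(nr, nc, p = 0.25, min_pixels = 3)
    sp <- c(runif(1, 0.3, 3), runif(1, 0.3, 3))
    o <- brute_distances(A, B, sp)
    expect_lt(abs(hausdorff(A, B, sp) - o$hd_ab), 1e-9)
    expect_lt(abs(hausdorff(A, B, sp, mode = "symmetric") - o$hd_sym), 1e-9)
    msd <- mean_surface_distance(A, B, sp)
    expect_lt(abs(msd - o$msd), 1e-9)
    expect_lte(msd, hausdorff(A, B, sp, mode = "symmetric") + 1e-12)
  }
})

test_that("3-d distances respect anisotropic slice spacing", {
  A <- array(FALSE, c(4, 8, 8)); A[2, 4, 4] <- TRUE
  B <- array(FALSE, c(4, 8, 8)); B[3, 4, 4] <- TRUE
  expect_equal(hausdorff(A, B, spacing = c(3.6, 0.5, 0.5)), 3.6)
  expect_equal(mean_surface_distance(A, B, spacing = c(3.6, 0.5, 0.5)), 3.6)
})

test_that("sensitivity and specificity come straight from the confusion counts", {
  # TP = 8, FN = 2, TN = 85, FP = 5 -> Sen 0.8, Spc 0.9444
  gt <- matrix(FALSE, 10, 10); gt[1, 1:10] <- TRUE
  pred <- matrix(FALSE, 10, 10); pred[1, 1:8] <- TRUE; pred[2, 1:5] <- TRUE
  ss <- sensitivity_specificity(gt, pred)
  expect_equal(unname(ss["sensitivity"]), 0.8)
  expect_equal(unname(ss["specificity"]), 85 / 90, tolerance = 1e-6)
  expect_equal(unname(sensitivity_specificity(gt, gt)), c(1, 1))
  allpos <- matrix(TRUE, 10, 10)
  ss2 <- sensitivity_specificity(gt, allpos)
  expect_equal(unname(ss2), c(1, 0))
  expect_error(sensitivity_specificity(matrix(FALSE, 2, 2), matrix(TRUE, 2, 2)),
               "undefined")
})

test_that("regional scoring splits the prostate range 25/50/25 from the apex", {
  lab <- array(0L, c(24, 10, 10))
  lab[3:22, 4:7, 4:7] <- 2L                    # 20 prostate slices
  gt <- LabelVolume(lab, c(3.6, 0.5, 0.5))
  r <- regional_dice(gt, gt)
  expect_equal(unname(r), c(1, 1, 1))
  # prediction correct only in the mid block: slices 3..22 split 5/10/5
  pred <- lab
  pred[3:7, , ] <- 0L                          # apex block wrong (empty)
  pred[18:22, , ] <- 0L                        # base block wrong
  r2 <- regional_dice(gt, LabelVolume(pred, c(3.6, 0.5, 0.5)))
  expect_equal(unname(r2), c(0, 1, 0))
  few <- array(0L, c(5, 4, 4)); few[2, 2, 2] <- 1L
  expect_error(regional_dice(LabelVolume(few, c(1, 1, 1)),
                             LabelVolume(few, c(1, 1, 1))), ">= 4")
})

test_that("cohort summaries aggregate as in the results tables", {
  base <- data.frame(ravd = 0, hausdorff = 1, msd = 0.5,
                     sensitivity = 0.9, specificity = 0.99)
  s1 <- summarize_cohort(cbind(data.frame(dice = c(0.9, 0.9, 0.9)), base))
  expect_equal(s1$MDS, 90)
  expect_equal(s1$StD, 0)
  expect_equal(s1$CI95, 0)
  s2 <- summarize_cohort(cbind(data.frame(dice = c(0.8, 1.0)), base[c(1, 1), ]))
  expect_equal(s2$MDS, 90)
  expect_equal(s2$MeDS, 90)
  # CI95 against the textbook normal-approximation formula on simulated cases
  set.seed(43)
  dice <- pmin(pmax(rnorm(100, 0.9, 0.05), 0), 1)
  s3 <- summarize_cohort(cbind(data.frame(dice = dice),
                               base[rep(1, 100), ]))
  expect_equal(s3$CI95, 100 * 1.96 * sd(dice) / 10, tolerance = 1e-12)
  expect_equal(s3$MRAVD, 0)
  expect_true(all(c("MDS", "CI95", "StD", "MeDS", "MRAVD", "MHD", "MSD",
                    "Sen", "Spc") %in% names(s3)))
  expect_error(summarize_cohort(data.frame()), "non-empty")
})

test_that("paired t-test matches the t-distribution and handles degeneracies", {
  a <- c(0.91, 0.88, 0.93, 0.9, 0.87, 0.92, 0.89, 0.94, 0.9, 0.91)
  b <- c(0.9, 0.87, 0.91, 0.91, 0.86, 0.9, 0.88, 0.92, 0.89, 0.9)
  p <- paired_ttest(a, b)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(p, 2 * pt(-abs(tstat), df = length(d) - 1), tolerance = 1e-12)
  expect_equal(paired_ttest(a, a), 1)
  expect_equal(paired_ttest(a, a - 0.1), 0)    # constant nonzero difference
  expect_error(paired_ttest(a, b[1:5]), "equal length")
})
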