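# ICC, Bland-Altman, Lin decomposition, staged workflow, power, outliers

test_that("ICC(2,1) is exactly 1 for identical raters and matches the aov oracle", {
  m <- matrix(rep(c(3, 7, 1, 9, 4, 6), 4), ncol = 4)
  r <- iccAbsoluteAgreement(m)
  expect_identical(r$icc, 1)
  expect_identical(c(r$ciLow, r$ciHigh), c(1, 1))

  set.seed(101)
  for (k in 1:10) {
    x <- matrix(rnorm(24, sd = 2), 6, 4) + rnorm(6, sd = 3)
    expect_equal(iccAbsoluteAgreement(x)$icc, oracleIcc21(x), tolerance = 1e-9)
  }

  # exhaustive-flavoured small-instance check: random 5 x 3 integer matrices
  # with entries in {0, 1, 2} against the independent ANOVA oracle
  set.seed(102)
  tried <- 0
  while (tried < 200) {
    x <- matrix(sample(0:2, 15, replace = TRUE), 5, 3)
    if (var(rowMeans(x)) == 0) next
    ours <- tryCatch(iccAbsoluteAgreement(x)$icc, error = function(e) NA)
    if (is.na(ours)) next
    expect_equal(ours, oracleIcc21(x), tolerance = 1e-9)
    tried <- tried + 1
  }
})

test_that("a constant rater shift strictly lowers absolute-agreement ICC", {
  set.seed(103)
  x <- matrix(rnorm(20), 5, 4) + (1:5) * 2
  base <- iccAbsoluteAgreement(x)$icc
  shifted <- x
  shifted[, 2] <- shifted[, 2] + 3
  expect_lt(iccAbsoluteAgreement(shifted)$icc, base)
})

test_that("ICC failure modes are reported as failures, not zeros", {
  flat <- matrix(5, 4, 3) + rep(c(0, 0.1, -0.1), each = 4)  # no case variance
  expect_error(iccAbsoluteAgreement(flat), "undefined")
  expect_error(iccAbsoluteAgreement(matrix(1:4, 2, 2)[, 1, drop = FALSE]),
               "at least 2")
  withNA <- matrix(rnorm(12), 4, 3)
  withNA[2, 2] <- NA
  expect_error(iccAbsoluteAgreement(withNA), "missing")
})

test_that("blandAltman computes bias and symmetric 1.96-SD limits", {
  a <- c(1, 3, 5, 7)
  expect_equal(blandAltman(a, a), list(bias = 0, loaLow = 0, loaHigh = 0))
  r <- blandAltman(a, a + 2)
  expect_equal(r$bias, -2)
  expect_equal(r$loaLow, -2)
  expect_equal(r$loaHigh, -2)
  set.seed(104)
  for (k in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    ba <- blandAltman(x, y)
    expect_equal(ba$loaHigh - ba$bias, ba$bias - ba$loaLow, tolerance = 1e-12)
    expect_equal(ba$loaHigh - ba$loaLow, 2 * 1.96 * sd(x - y), tolerance = 1e-12)
  }
  expect_error(blandAltman(1:4, 1:5), "length")
})

test_that("linCCC matches the closed form and its decomposition sums to 100", {
  expect_equal(linCCC(c(1, 2, 3), c(1, 2, 3)),
               list(ccc = 1, cB = 1, lopPct = 0, loaPct = 0))
  r <- linCCC(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$ccc, 4 / 7, tolerance = 1e-12)
  expect_equal(r$cB, 4 / 7, tolerance = 1e-12)  # r = 1 so c_b = ccc
  expect_equal(r$lopPct, 0, tolerance = 1e-9)
  expect_equal(r$loaPct, 100, tolerance = 1e-9)

  set.seed(105)
  for (k in 1:500) {
    n <- sample(5:40, 1)
    a <- rnorm(n, sd = runif(1, 0.5, 3))
    b <- runif(1, -1, 2) * a + rnorm(n, sd = runif(1, 0.2, 2)) + runif(1, -3, 3)
    r <- linCCC(a, b)
    expect_lt(abs(r$lopPct + r$loaPct - 100), 1e-9)
    expect_lte(r$ccc, abs(cor(a, b)) + 1e-12)
    expect_gt(r$cB, 0)
    expect_lte(r$cB, 1 + 1e-12)
  }
  expect_error(linCCC(rep(1, 5), 1:5), "constant")
})

test_that("the staged workflow follows gate -> Bland-Altman -> Lin", {
  set.seed(106)
  a <- rnorm(100, sd = 5)

  # constant shift: passes the gate, fails the bias threshold, Lin computed,
  # all discordance from accuracy
  rep1 <- concordanceWorkflow(a, a + 10)
  expect_identical(verdict(rep1), "discordant-accuracy-dominant")
  expect_equal(rep1@biasDeg, -10, tolerance = 1e-12)
  expect_false(is.na(rep1@ccc))
  expect_equal(rep1@lopPct, 0, tolerance = 1e-9)

  # small noise: concordant, Lin explicitly skipped
  set.seed(107)
  b <- a + rnorm(100, sd = 0.5)
  rep2 <- concordanceWorkflow(a, b)
  expect_identical(verdict(rep2), "concordant")
  expect_true(is.na(rep2@ccc) && is.na(rep2@lopPct))

  # independent samples: correlation gate fails, nothing downstream
  set.seed(108)
  rep3 <- concordanceWorkflow(rnorm(60), rnorm(60))
  expect_identical(verdict(rep3), "correlation-failed")
  expect_true(is.na(rep3@biasDeg))

  # wide scatter with no shift: precision-dominant discordance
  set.seed(109)
  x <- rnorm(200, sd = 8)
  rep4 <- concordanceWorkflow(x, x + rnorm(200, sd = 4))
  expect_identical(verdict(rep4), "discordant-precision-dominant")
  expect_gt(rep4@lopPct, 50)
})

test_that("Lin fields are never reported when the Bland-Altman stage passes", {
  set.seed(110)
  for (k in 1:50) {
    a <- rnorm(80, sd = 6)
    b <- a + rnorm(80, sd = runif(1, 0.1, 4)) + runif(1, -4, 4)
    rep <- concordanceWorkflow(a, b)
    if (identical(verdict(rep), "concordant")) {
      expect_true(is.na(rep@ccc) && is.na(rep@cB) &&
                  is.na(rep@lopPct) && is.na(rep@loaPct))
      expect_lte(abs(rep@biasDeg), 3)
      expect_lte((rep@loaHighDeg - rep@loaLowDeg) / 2, 5)
    } else if (!identical(verdict(rep), "correlation-failed")) {
      expect_false(is.na(rep@ccc))
    }
  }
})

test_that("minSampleSize reproduces the normal-approximation formula", {
  expect_identical(minSampleSize(5, 10, 0.05, 0.20), 63L)
  expect_identical(minSampleSize(1, 1, 0.05, 0.20), 16L)
  # doubling the SD quadruples the requirement before rounding
  z2 <- (qnorm(0.975) + qnorm(0.8))^2
  expect_equal(2 * z2 * (20 / 5)^2 / (2 * z2 * (10 / 5)^2), 4, tolerance = 1e-12)
  expect_identical(minSampleSize(5, 20), as.integer(ceiling(2 * z2 * 16)))
  # monotonicity
  expect_lte(minSampleSize(6, 10), minSampleSize(5, 10))
  expect_gte(minSampleSize(5, 12), minSampleSize(5, 10))
  expect_gte(minSampleSize(5, 10, alpha = 0.01), minSampleSize(5, 10, alpha = 0.05))
  expect_gte(minSampleSize(5, 10, beta = 0.1), minSampleSize(5, 10, beta = 0.2))
  expect_error(minSampleSize(-1, 10), "delta")
})

test_that("discrepancyOutliers applies the lone-outlier rule per case", {
  r <- discrepancyOutliers(c(0, 0, 0), c(0, 4, 0), c(9, 8, 0))
  # case 1: bflf 9 deg from both agreeing others -> flagged
  expect_identical(unname(r$counts), c(0L, 0L, 1L))
  expect_true(r$flags$bflf[1])
  # case 2: (0, 4, 8) -> no method qualifies under the rule
  expect_false(any(r$flags$y_axis[2], r$flags$gt_line[2], r$flags$bflf[2]))
  # case 3: all equal -> nothing flagged, zero max difference
  expect_false(any(unlist(r$flags[3, -1])))
  expect_equal(r$maxPairwiseDiff[3], 0)
  # pairwise rates count |diff| >= 5: y-gt (0,4,0), y-bflf (9,8,0), gt-bflf (9,4,0)
  expect_equal(unname(r$pairwiseRatePct), c(0, 100 * 2 / 3, 100 * 1 / 3))
  expect_error(discrepancyOutliers(1:3, 1:3, 1:2), "length")
})
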