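test_that("perfect agreement gives alpha, ICC and Dice of 1", {
  m <- cbind(c(1, 2, 3, 1, 2, 3, 1), c(1, 2, 3, 1, 2, 3, 1))
  expect_equal(krippendorff_alpha(m), 1)
  icc <- icc_2k(m)
  expect_equal(icc$icc, 1)
  expect_lt(icc$p, 0.001)
  d <- dice_per_category(m[, 1], m[, 2])
  expect_true(all(d == 1))
})

test_that("alpha matches the brute-force coincidence oracle", {
  # 10 units, 2 raters, 2 missing cells, 1 disagreement
  m <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 1), c(2, 2), c(1, 2),
             c(3, 3), c(NA, 1), c(2, NA), c(1, 1))
  expect_equal(krippendorff_alpha(m), alpha_oracle_ordinal(m),
               tolerance = 1e-10)
  expect_equal(krippendorff_alpha(m), 0.8863636, tolerance = 1e-6)

  # randomized matrices with missing data, several sizes
  set.seed(99)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    mm <- matrix(sample(1:3, n * 3, replace = TRUE), ncol = 3)
    mm[sample(length(mm), round(length(mm) * 0.15))] <- NA
    keep <- rowSums(!is.na(mm)) >= 2
    if (sum(keep) < 2) next
    mm <- mm[keep, , drop = FALSE]
    if (length(unique(na.omit(as.vector(mm)))) < 2) next
    expect_equal(krippendorff_alpha(mm), alpha_oracle_ordinal(mm),
                 tolerance = 1e-9)
  }
})

test_that("alpha of statistically independent raters is near zero", {
  set.seed(2024)
  m <- cbind(sample(1:3, 10000, TRUE), sample(1:3, 10000, TRUE))
  expect_lt(abs(krippendorff_alpha(m)), 0.03)
})

test_that("alpha treats the N/A codes as missing and errors when empty", {
  m <- rbind(c(0, 0.5), c(1, 1), c(2, 2), c(3, 3), c(1, 2))
  m_na <- rbind(c(NA, NA), c(1, 1), c(2, 2), c(3, 3), c(1, 2))
  expect_equal(krippendorff_alpha(m), krippendorff_alpha(m_na))
  expect_error(krippendorff_alpha(rbind(c(0, 0.5), c(NA, 0))), "missing")
})

test_that("ICC(2,k) matches the mean-squares decomposition", {
  # frozen two-way random-effects oracle (average measures) for this grid
  r1 <- c(1, 3, 2, 2, 2, 3, 1, 3, 1, 1, 2, 3, 3, 3, 3, 3, 2, 1, 3, 2)
  r2 <- r1
  r2[3] <- 3
  res <- icc_2k(cbind(r1, r2))
  expect_equal(res$icc, 0.982059, tolerance = 1e-6)
  expect_equal(res$p, 9.002525e-13, tolerance = 1e-4)
  expect_equal(res$n_units, 20L)

  # direct ANOVA-identity oracle on a random matrix
  set.seed(5)
  m <- matrix(rnorm(30), ncol = 3)
  a <- stats::aov(y ~ Error(unit) + rater, data = data.frame(
    y = as.vector(m), unit = factor(rep(1:10, 3)),
    rater = factor(rep(1:3, each = 10))))
  msr <- summary(a)[[1]][[1]]["Residuals", "Mean Sq"]
  tab <- summary(a)[[2]][[1]]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  expected <- (msr - mse) / (msr + (msc - mse) / 10)
  expect_equal(icc_2k(m)$icc, expected, tolerance = 1e-9)
})

test_that("degenerate ICC inputs are reported as errors", {
  expect_error(icc_2k(cbind(c(2, 2, 2, 2), c(2, 2, 2, 2))), "variance")
  expect_error(icc_2k(cbind(c(1, 2), c(1, 2))), "3 complete units")
  # N/A codes dropped listwise
  m <- rbind(c(1, 1), c(0, 2), c(2, 2), c(3, 3), c(1, 1))
  expect_equal(icc_2k(m)$n_units, 4L)
})

test_that("Dice coefficients follow the set-overlap definition", {
  r1 <- c("na", "na", "na", "imp", "imp", "no", "wor", "wor")
  r2 <- c("na", "na", "imp", "imp", "na", "no", "wor", "no")
  d <- dice_per_category(r1, r2)
  expect_equal(unname(d["na"]), 2 * 2 / (3 + 3), tolerance = 1e-12)
  expect_equal(unname(d["imp"]), 2 * 1 / (2 + 2))
  expect_equal(unname(d["wor"]), 2 * 1 / (2 + 1))
  # symmetry and identity
  expect_equal(dice_per_category(r2, r1)[names(d)], d)
  expect_true(all(dice_per_category(r1, r1) == 1))
  # category present in one rater only
  expect_equal(unname(dice_per_category(c("a", "b"), c("b", "b"))["a"]), 0)
  expect_error(dice_per_category(1:3, 1:4), "equal length")
})

test_that("Spearman correlation matches the rank-definition oracle", {
  x <- c(1, 2, 2, 3, 1, 3, 2, 1, 3, 2)
  y <- c(1, 3, 2, 5, 2, 6, 4, 1, 7, 4)
  res <- spearman_rho(x, y)
  oracle <- stats::cor(rank(x), rank(y))
  expect_equal(res$rho, oracle, tolerance = 1e-12)
  expect_equal(res$n, 10L)

  expect_equal(spearman_rho(1:5, c(10, 20, 30, 40, 50))$rho, 1)
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
  # N/A codes excluded pairwise
  res2 <- spearman_rho(c(0, x), c(5, y))
  expect_equal(res2$n, 10L)
})

test_that("reliability statistics are invariant to permuting units", {
  set.seed(31)
  m <- cbind(sample(1:3, 12, TRUE), sample(1:3, 12, TRUE))
  p <- sample(12)
  expect_equal(krippendorff_alpha(m), krippendorff_alpha(m[p, ]))
  expect_equal(icc_2k(m)$icc, icc_2k(m[p, ])$icc)
  d1 <- dice_per_category(m[, 1], m[, 2])
  d2 <- dice_per_category(m[p, 1], m[p, 2])
  expect_equal(d1, d2[names(d1)])
})
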