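test_that("ICC(2,1) matches a from-scratch ANOVA mean-squares oracle", {
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  # oracle: explicit two-way ANOVA decomposition
  icc_oracle <- function(a, b) {
    n <- length(a); k <- 2
    y <- c(a, b)
    subj <- rep(seq_len(n), 2)
    rater <- rep(1:2, each = n)
    gm <- mean(y)
    ms_s <- k * sum((tapply(y, subj, mean) - gm)^2) / (n - 1)
    ms_r <- n * sum((tapply(y, rater, mean) - gm)^2) / (k - 1)
    sse <- sum((y - ave(y, subj) - ave(y, rater) + gm)^2)
    ms_e <- sse / ((n - 1) * (k - 1))
    (ms_s - ms_e) / (ms_s + (k - 1) * ms_e + k / n * (ms_r - ms_e))
  }
  expect_equal(icc_2way_absolute(a, b), icc_oracle(a, b), tolerance = 1e-10)
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(12, 50, 10)
    y <- x + rnorm(12, 1, 2)
    expect_equal(icc_2way_absolute(x, y), icc_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("ICC is 1 for identical raters and penalized by constant bias", {
  x <- c(1, 5, 9, 13, 2, 7)
  expect_equal(icc_2way_absolute(x, x), 1.0)
  biased <- icc_2way_absolute(x, x + 3)
  expect_lt(biased, 1.0)
  # strictly decreasing as the bias grows (absolute-agreement signature)
  expect_lt(icc_2way_absolute(x, x + 6), biased)
  # invariant under a common affine rescaling of both raters
  set.seed(2)
  a <- rnorm(20, 10, 3); b <- a + rnorm(20, 0.5, 1)
  expect_equal(icc_2way_absolute(2 * a + 7, 2 * b + 7),
               icc_2way_absolute(a, b), tolerance = 1e-10)
  expect_warning(res <- icc_2way_absolute(rep(3, 5), rep(3, 5)), "undefined")
  expect_true(is.na(res))
})

test_that("Bland-Altman matches direct moments and handles degenerate cases", {
  x <- c(10, 12, 9, 14, 11)
  expect_equal(bland_altman(x, x)$bias, 0)
  expect_equal(bland_altman(x, x)$loa_low, 0)
  off <- bland_altman(x + 2.5, x)
  expect_equal(off$bias, 2.5)
  expect_equal(off$loa_low, 2.5)
  expect_equal(off$loa_high, 2.5)
  set.seed(3)
  a <- rnorm(40, 100, 15); b <- a + rnorm(40, 1, 4)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$points$mean, (a + b) / 2)
})

test_that("limits of agreement cover ~95% of Gaussian differences", {
  set.seed(77)
  n <- 10000
  a <- rnorm(n, 50, 5)
  b <- a + rnorm(n, 0, 2)
  ba <- bland_altman(a, b)
  inside <- mean(ba$points$diff >= ba$loa_low & ba$points$diff <= ba$loa_high)
  se <- sqrt(0.95 * 0.05 / n)
  expect_lt(abs(inside - 0.95), 4 * se)
})

test_that("trend test equals the closed-form OLS slope", {
  # zero-noise line: lm warns about the perfect fit, which is the point here
  r <- suppressWarnings(trend_test(c(1, 2, 3), c(0, 1, 2)))
  expect_equal(r$slope, 1.0)
  expect_lt(r$p_trend, 1e-8)
  set.seed(21)
  g <- sample(0:2, 30, TRUE)
  v <- 2 + 1.5 * g + rnorm(30)
  r2 <- trend_test(v, g)
  slope_oracle <- sum((g - mean(g)) * (v - mean(v))) / sum((g - mean(g))^2)
  expect_equal(r2$slope, slope_oracle, tolerance = 1e-10)
  expect_error(trend_test(c(1, 2, 3), c(1, 1, 1)), "distinct")
})

test_that("trend p-value is consistent with a permutation reference", {
  set.seed(55)
  g <- rep(0:2, each = 10)
  v <- 1 + 0.8 * g + rnorm(30, 0, 1.2)
  obs <- trend_test(v, g)
  perm <- replicate(1000, trend_test(v, sample(g))$slope)
  expect_lt(abs(mean(perm)), 3 * sd(perm) / sqrt(1000))
  p_perm <- mean(abs(perm) >= abs(obs$slope))
  # both should call the trend at the same significance scale
  expect_equal(p_perm < 0.05, obs$p_trend < 0.05)
})

test_that("group t-test matches the textbook formulas", {
  expect_equal(group_ttest(c(3, 3, 3), c(3, 3, 3)), list(t = 0, p = 1))
  far <- group_ttest(rnorm(20, 0, 0.1), rnorm(20, 50, 0.1))
  expect_lt(far$p, 1e-6)
  set.seed(6)
  x <- rnorm(15, 5, 2); y <- rnorm(12, 6, 3)
  w <- group_ttest(x, y)
  se <- sqrt(var(x) / 15 + var(y) / 12)
  expect_equal(w$t, (mean(x) - mean(y)) / se, tolerance = 1e-10)
  sp2 <- ((15 - 1) * var(x) + (12 - 1) * var(y)) / (15 + 12 - 2)
  tp <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 15 + 1 / 12))
  expect_equal(group_ttest(x, y, var_equal = TRUE)$t, tp, tolerance = 1e-10)
})

test_that("Pearson correlation honors affine invariance and sign", {
  a <- c(1, 4, 2, 8, 5, 7)
  expect_equal(pearson(a, 2 * a + 3), 1.0)
  expect_equal(pearson(a, -a), -1.0)
  set.seed(10)
  x <- rnorm(25); y <- rnorm(25)
  cov_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), cov_oracle, tolerance = 1e-12)
  expect_warning(r <- pearson(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r))
})
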