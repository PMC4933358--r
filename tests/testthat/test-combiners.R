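# Independent-case combined p-value statistics and their exact nulls.

test_that("Lancaster statistic matches the inverse chi-square transform", {
  # closed form -2 log p at w = 2, checked against the numeric inverse CDF
  expect_equal(lancaster_statistic(c(0.5, 0.5), c(2, 2)), -4 * log(0.5))
  expect_equal(lancaster_statistic(c(0.5, 0.5), c(2, 2)), 2.77259, tolerance = 1e-5)
  expect_equal(lancaster_statistic(0.05, 2), 5.99146, tolerance = 1e-5)
  expect_equal(lancaster_statistic(0.05, 2),
               qchisq(0.95, 2), tolerance = 1e-10)
  # a p-value of exactly 1 contributes 0
  expect_identical(lancaster_statistic(1, 3), 0)
  # general weights agree with the quantile oracle
  set.seed(1)
  p <- runif(6, 0.01, 0.99); w <- runif(6, 0.5, 8)
  expect_equal(lancaster_statistic(p, w),
               sum(qchisq(1 - p, w)), tolerance = 1e-7)
})

test_that("invalid p-values and mismatched lengths are rejected", {
  expect_error(lancaster_statistic(c(0.5, 0), c(2, 2)), "<= 0")
  expect_error(lancaster_statistic(c(0.5, 1.2), c(2, 2)), "> 1")
  expect_error(lancaster_statistic(c(0.5, 0.5), c(2, 2, 2)), "length")
  expect_error(lancaster_pvalue_independent(-1, c(2, 2)), "non-negative")
})

test_that("independent Lancaster p-value is the chi-square survival", {
  expect_equal(lancaster_pvalue_independent(0, c(2, 2))$p.value, 1)
  res <- lancaster_pvalue_independent(2.77259, c(2, 2))
  expect_equal(res$p.value, 0.59657, tolerance = 1e-4)
  expect_equal(res$parameters$df, 4)
})

test_that("Fisher is Lancaster with uniform weight 2, bit-for-bit", {
  set.seed(42)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- runif(m)
    f <- combine_pvalues(p, method = "fisher")
    l <- combine_pvalues(p, w = rep(2, m), method = "lancaster")
    expect_identical(f$statistic, l$statistic)
    expect_lt(abs(f$p.value - l$p.value), 1e-10)
  }
})

test_that("every combiner reduces to the single p-value at m = 1", {
  for (p1 in c(0.9, 0.31, 0.02, 1e-6)) {
    expect_equal(combine_pvalues(p1, method = "fisher")$p.value, p1, tolerance = 1e-10)
    expect_equal(combine_pvalues(p1, w = 3.7, method = "lancaster")$p.value, p1,
                 tolerance = 1e-9)
    expect_equal(combine_pvalues(p1, method = "z")$p.value, p1, tolerance = 1e-10)
    expect_equal(combine_pvalues(p1, w = 5, method = "weighted_z")$p.value, p1,
                 tolerance = 1e-10)
    expect_equal(combine_pvalues(p1, w = 1.5, method = "good")$p.value, p1,
                 tolerance = 1e-9)
  }
})

test_that("weighted Z-test matches the normal quantile oracle", {
  res <- combine_pvalues(c(0.5, 0.5), w = c(3, 3), method = "weighted_z")
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.5)
  res <- combine_pvalues(c(0.05, 0.05), w = c(1, 1), method = "weighted_z")
  expect_equal(res$statistic, 2 * qnorm(0.95) / sqrt(2), tolerance = 1e-10)
  expect_equal(res$statistic, 2.32617, tolerance = 1e-5)
  expect_equal(res$p.value, 0.01000, tolerance = 1e-3)
  # equal weights reduce exactly to the regular Z-test
  set.seed(3); p <- runif(7)
  expect_equal(combine_pvalues(p, w = rep(4, 7), method = "weighted_z")$p.value,
               combine_pvalues(p, method = "z")$p.value, tolerance = 1e-12)
  # boundary p-values are clamped, not infinite
  expect_true(is.finite(combine_pvalues(c(1, 0.5), w = c(1, 1),
                                        method = "weighted_z")$statistic))
})

test_that("Good's null CDF has the closed form and is a valid CDF", {
  expect_equal(good_null_cdf(1, c(1, 2)), 1)
  expect_equal(good_null_cdf(0, c(1, 2)), 0)
  expect_equal(good_null_cdf(0.25, c(1, 2)), -0.25 + 2 * 0.5)
  expect_error(good_null_cdf(0.5, c(2, 2)), "distinct")
  set.seed(7)
  for (i in 1:20) {
    m <- sample(2:6, 1)
    # well-separated weights: the Lambda coefficients suffer catastrophic
    # cancellation as weights approach ties (where the closed form breaks)
    w <- sample(seq(0.5, 8, by = 0.75), m)
    q <- seq(0, 1, length.out = 101)
    cdf <- good_null_cdf(q, w)
    expect_true(all(cdf >= 0 & cdf <= 1))
    expect_true(all(diff(cdf) >= -1e-9))
    expect_equal(cdf[1], 0)
    expect_equal(cdf[101], 1, tolerance = 1e-8)
  }
})

test_that("Good's test: equal weights reduce exactly to Fisher", {
  set.seed(11)
  for (i in 1:50) {
    m <- sample(2:10, 1)
    p <- runif(m)
    g <- combine_pvalues(p, w = rep(1, m), method = "good")
    f <- combine_pvalues(p, method = "fisher")
    expect_equal(g$statistic, f$statistic / 2, tolerance = 1e-12)
    expect_lt(abs(g$p.value - f$p.value), 1e-10)
  }
})

test_that("Good's closed form agrees with a Monte-Carlo null", {
  p <- c(0.1, 0.2); w <- c(1, 2)
  res <- combine_pvalues(p, w = w, method = "good")
  set.seed(5)
  B <- 1e6
  u <- matrix(runif(2 * B), nrow = 2)
  stat_null <- -colSums(w * log(u))
  mc <- mean(stat_null >= res$statistic)
  se <- sqrt(mc * (1 - mc) / B)
  expect_lt(abs(res$p.value - mc), 3 * se)
})

test_that("tied non-uniform weights fall back to a seeded Monte-Carlo null", {
  p <- c(0.02, 0.3, 0.5)
  w <- c(1, 1, 3)
  r1 <- combine_pvalues(p, w = w, method = "good", mc_reps = 2e5, seed = 9)
  r2 <- combine_pvalues(p, w = w, method = "good", mc_reps = 2e5, seed = 9)
  expect_identical(r1$p.value, r2$p.value)
  expect_match(r1$method, "Monte-Carlo")
  # cross-check against the generalized-Fisher structure by brute force
  set.seed(31)
  u <- matrix(runif(3 * 2e5), nrow = 3)
  mc <- mean(-colSums(w * log(u)) >= r1$statistic)
  expect_lt(abs(r1$p.value - mc), 4 * sqrt(mc * (1 - mc) / 2e5))
})

test_that("combined p-values are Uniform(0,1) under the null", {
  set.seed(2024)
  R <- 3e4
  m <- 3
  w <- c(1.5, 2, 4.5)
  U <- matrix(runif(R * m), ncol = m)
  p_lanc <- pchisq(rowSums(qchisq(U, rep(w, each = R), lower.tail = FALSE)),
                   df = sum(w), lower.tail = FALSE)
  expect_gt(ks.test(p_lanc, "punif")$p.value, 0.001)
  # spot-check the package path agrees with the vectorised computation
  expect_equal(combine_pvalues(U[1, ], w = w, method = "lancaster")$p.value,
               p_lanc[1], tolerance = 1e-12)
  p_z <- pnorm(rowSums(qnorm(U, lower.tail = FALSE) %*% diag(c(1, 2, 3))) /
                 sqrt(14), lower.tail = FALSE)
  expect_gt(ks.test(p_z, "punif")$p.value, 0.001)
  expect_equal(combine_pvalues(U[2, ], w = c(1, 2, 3), method = "weighted_z")$p.value,
               p_z[2], tolerance = 1e-12)
  logq <- log(U) %*% w
  p_good <- vapply(exp(logq), function(q) good_null_cdf(q, w), numeric(1))
  expect_gt(ks.test(p_good, "punif")$p.value, 0.001)
  expect_equal(combine_pvalues(U[3, ], w = w, method = "good")$p.value,
               p_good[3], tolerance = 1e-10)
})

test_that("each combiner is monotone: smaller input p never raises the output", {
  set.seed(13)
  for (method in c("fisher", "lancaster", "weighted_z", "good")) {
    p <- runif(5, 0.05, 0.95)
    w <- if (method == "fisher") NULL else runif(5, 0.5, 4)
    base <- combine_pvalues(p, w = w, method = method)$p.value
    for (i in 1:5) {
      p2 <- p
      p2[i] <- p[i] * 0.5
      expect_lte(combine_pvalues(p2, w = w, method = method)$p.value, base)
    }
  }
})
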