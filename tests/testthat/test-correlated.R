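# Satterthwaite scaled chi-square null, covariance estimation, inflation.

test_that("Satterthwaite parameters match the two moments exactly", {
  expect_equal(satterthwaite_params(4, 8), list(c = 1, v = 4))
  expect_equal(satterthwaite_params(4, 16), list(c = 2, v = 2))
  set.seed(8)
  for (i in 1:50) {
    mu <- runif(1, 0.1, 50); va <- runif(1, 0.1, 200)
    sw <- satterthwaite_params(mu, va)
    expect_equal(sw$c * sw$v, mu, tolerance = 1e-12)
    expect_equal(2 * sw$c^2 * sw$v, va, tolerance = 1e-12)
  }
  expect_error(satterthwaite_params(0, 1), "> 0")
  expect_error(satterthwaite_params(1, -1), "> 0")
})

test_that("null moments are sum(w) and 2 sum(w) + 2 sum(rho)", {
  rho0 <- matrix(c(4, 0, 0, 4), 2)
  expect_equal(lancaster_null_moments(c(2, 2), rho0), list(mean = 4, var = 8))
  rho2 <- matrix(c(4, 2, 2, 4), 2)
  expect_equal(lancaster_null_moments(c(2, 2), rho2), list(mean = 4, var = 12))
  rho1 <- matrix(1, 3, 3); diag(rho1) <- 4
  expect_equal(lancaster_null_moments(c(2, 2, 2), rho1), list(mean = 6, var = 18))
})

test_that("permutation covariance recovers independence and duplication", {
  w <- c(2, 2)
  cov_ind <- estimate_lancaster_covariance(function(b) runif(2), B = 5000,
                                           w = w, seed = 21)
  expect_identical(cov_ind$n_resamples, 5000L)
  expect_lt(abs(cov_ind$rho[1, 2]), 0.15)
  expect_lt(abs(cov_ind$rho[1, 1] - 4), 0.3)
  expect_lt(abs(cov_ind$rho[2, 2] - 4), 0.3)
  # perfectly duplicated tests: covariance equals the variance 2w
  cov_dup <- estimate_lancaster_covariance(function(b) rep(runif(1), 2),
                                           B = 5000, w = w, seed = 22)
  expect_lt(abs(cov_dup$rho[1, 2] - 4), 0.3)
  expect_error(
    estimate_lancaster_covariance(function(b) c(0.5, runif(1)), B = 200, w = w),
    "constant")
  expect_error(
    estimate_lancaster_covariance(function(b) runif(2), B = 50, w = w),
    "at least 100")
})

test_that("copula covariance matches a brute-force Monte-Carlo oracle", {
  w <- c(2, 2)
  set.seed(1)
  cov_est <- estimate_lancaster_covariance(function(b) copula_pvalues(2, 0.5),
                                           B = 5000, w = w, seed = 12)
  # direct large-sample covariance of the transformed statistics
  set.seed(2)
  B <- 1e6
  z0 <- rnorm(B)
  z <- cbind(sqrt(0.5) * z0 + sqrt(0.5) * rnorm(B),
             sqrt(0.5) * z0 + sqrt(0.5) * rnorm(B))
  tr <- -2 * pnorm(z, lower.tail = FALSE, log.p = TRUE)
  oracle <- cov(tr[, 1], tr[, 2])
  # 3 standard errors of the B = 5000 estimate
  se <- sd((tr[, 1] - mean(tr[, 1])) * (tr[, 2] - mean(tr[, 2]))) / sqrt(5000)
  expect_lt(abs(cov_est$rho[1, 2] - oracle), 3 * se)
})

test_that("zero covariance reproduces the independent Lancaster test exactly", {
  set.seed(4)
  for (i in 1:20) {
    m <- sample(2:15, 1)
    p <- runif(m); w <- runif(m, 0.5, 5)
    r_ind <- combine_pvalues(p, w = w, method = "lancaster")
    r_cov <- correlated_lancaster_test(p, w,
      cov = lancaster_covariance(method = "analytic-zero"))
    expect_equal(r_cov$p.value, r_ind$p.value, tolerance = 1e-12)
    expect_equal(r_cov$statistic, r_ind$statistic)
  }
})

test_that("duplicated tests collapse to one effective test", {
  # all p equal with full covariance: v matches a single chi-square(w)
  w <- c(2, 2)
  rho <- matrix(4, 2, 2)
  res <- correlated_lancaster_test(c(0.2, 0.2), w, cov = rho)
  expect_equal(res$parameters$v, 2) # one effective w = 2 test
  expect_equal(res$parameters$c, 2)
  # p-value consistent with the single-test transform
  expect_equal(res$p.value,
               pchisq(-2 * log(0.2), df = 2, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("increasing the covariance sum never decreases the p-value", {
  p <- runif(10, 0.01, 0.9); w <- rep(2, 10)
  rho_sums <- seq(0, 30, by = 5)
  pv <- vapply(rho_sums, function(rs) {
    rho <- matrix(2 * rs / (10 * 9), 10, 10); diag(rho) <- 4
    correlated_lancaster_test(p, w, cov = rho)$p.value
  }, numeric(1))
  expect_true(all(diff(pv) >= -1e-12))
})

test_that("non-positive implied variance is shrunk with a warning", {
  rho <- matrix(-1, 3, 3); diag(rho) <- 4 # off-diag sum = -3, var = 12 - 6 > 0
  expect_silent(correlated_lancaster_test(c(0.1, 0.5, 0.9), c(2, 2, 2), rho))
  rho_bad <- matrix(-3, 3, 3); diag(rho_bad) <- 4 # var = 12 - 18 < 0
  expect_warning(
    res <- correlated_lancaster_test(c(0.1, 0.5, 0.9), c(2, 2, 2), rho_bad),
    "shrunk")
  expect_true(res$p.value > 0 && res$p.value <= 1)
})

test_that("Satterthwaite correction is calibrated under exchangeable copulas", {
  m <- 20; w <- rep(2, m)
  for (rho in c(0.3, 0.6)) {
    set.seed(100 + round(100 * rho))
    cov_est <- estimate_lancaster_covariance(function(b) copula_pvalues(m, rho),
                                             B = 5000, w = w, seed = 7)
    R <- 4000
    pv <- vapply(seq_len(R), function(i) {
      correlated_lancaster_test(copula_pvalues(m, rho), w, cov_est)$p.value
    }, numeric(1))
    for (alpha in c(0.05, 0.01)) {
      ci <- 2.576 * sqrt(alpha * (1 - alpha) / R)
      expect_lt(abs(mean(pv < alpha) - alpha), ci)
    }
  }
})

test_that("inflation factor is 1 on exact uniform quantiles and detects inflation", {
  m <- 1000
  expect_equal(inflation_factor((seq_len(m) - 0.5) / m), 1, tolerance = 1e-12)
  expect_gt(inflation_factor(((seq_len(m) - 0.5) / m)^2), 1)
  expect_lt(inflation_factor(sqrt((seq_len(m) - 0.5) / m)), 1)
  expect_error(inflation_factor(runif(5)), "at least 10")
  set.seed(15)
  expect_true(abs(inflation_factor(runif(1e4)) - 1) < 0.1)
})
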