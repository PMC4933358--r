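# Shared fixture generators.

# Exchangeable Gaussian-copula p-values: one shared factor with loading
# sqrt(rho). Marginals are Uniform(0,1); one-sided upper-tail convention.
copula_pvalues <- function(m, rho) {
  z <- sqrt(rho) * stats::rnorm(1) + sqrt(1 - rho) * stats::rnorm(m)
  stats::pnorm(z, lower.tail = FALSE)
}

# One-sided z-test significance level for a N(theta, 1) sample of size n,
# with the sample mean drawn directly from its sampling distribution.
ztest_pvalue <- function(n, theta = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xbar <- stats::rnorm(1, mean = theta, sd = 1 / sqrt(n))
  stats::pnorm(sqrt(n) * xbar, lower.tail = FALSE)
}

# Small random genotype matrix with fixed MAFs (binomial, no LD).
random_dosages <- function(n, maf) {
  J <- length(maf)
  matrix(stats::rbinom(n * J, 2, rep(maf, each = n)), n, J)
}
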