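#' Satterthwaite scaled chi-square parameters
#'
#' Matches the first two moments of a non-negative statistic to a scaled
#' chi-square \eqn{c\chi^2_v}: \eqn{c = \mathrm{var}(T) / (2 E(T))} and
#' \eqn{v = 2 E(T)^2 / \mathrm{var}(T)}, so that \eqn{cv = E(T)} and
#' \eqn{2c^2v = \mathrm{var}(T)} exactly.
#'
#' @param mean_T positive mean of the statistic under the null.
#' @param var_T positive variance of the statistic under the null.
#' @return List with elements \code{c} (scale) and \code{v} (degrees of
#'   freedom).
#' @examples
#' satterthwaite_params(4, 8) # c = 1, v = 4: the independent chi-square(4)
#' @export
satterthwaite_params <- function(mean_T, var_T) {
  if (!is.finite(mean_T) || mean_T <= 0) stop("'mean_T' must be > 0")
  if (!is.finite(var_T) || var_T <= 0) stop("'var_T' must be > 0 (degenerate covariance?)")
  list(c = 0.5 * var_T / mean_T, v = 2 * mean_T^2 / var_T)
}

#' Null moments of the Lancaster statistic under correlation
#'
#' \eqn{E(T) = \sum w_i} and \eqn{\mathrm{var}(T) = 2\sum w_i +
#' 2\sum_{i<j}\rho_{ij}}, where \eqn{\rho_{ij}} is the null covariance of the
#' transformed statistics \eqn{F_i^{-1}(1-P_i)}.
#'
#' @param w degrees-of-freedom weights.
#' @param cov a covariance estimate from [lancaster_covariance()] or
#'   [estimate_lancaster_covariance()], or \code{NULL} for independence.
#' @return List with \code{mean} and \code{var}.
#' @export
lancaster_null_moments <- function(w, cov = NULL) {
  w <- check_weights(w, length(w))
  off <- 0
  if (!is.null(cov)) {
    rho <- cov_matrix(cov, length(w))
    off <- sum(rho[upper.tri(rho)])
  }
  mean_T <- sum(w)
  var_T <- 2 * sum(w) + 2 * off
  if (var_T <= 0) stop("implied null variance is not positive")
  list(mean = mean_T, var = var_T)
}

#' Covariance estimate container for the correlated Lancaster test
#'
#' Wraps an m-by-m covariance matrix of the chi-square-transformed statistics
#' \eqn{F_i^{-1}(1-P_i)} under the null. \code{method = "analytic-zero"}
#' encodes independence (all off-diagonals zero).
#'
#' @param rho symmetric m-by-m covariance matrix, or \code{NULL} with
#'   \code{method = "analytic-zero"}.
#' @param method provenance tag: \code{"permutation"}, \code{"analytic-zero"}
#'   or \code{"user-supplied"}.
#' @param n_resamples resample count behind a permutation estimate.
#' @return Object of class \code{"lancaster_covariance"}.
#' @export
lancaster_covariance <- function(rho = NULL,
                                 method = c("user-supplied", "analytic-zero",
                                            "permutation"),
                                 n_resamples = NA_integer_) {
  method <- match.arg(method)
  if (is.null(rho)) {
    if (method != "analytic-zero") stop("'rho' is required unless method = 'analytic-zero'")
  } else {
    rho <- as.matrix(rho)
    if (nrow(rho) != ncol(rho)) stop("'rho' must be square")
    if (max(abs(rho - t(rho))) > 1e-8 * max(1, max(abs(rho)))) {
      stop("'rho' must be symmetric")
    }
    rho <- (rho + t(rho)) / 2
  }
  structure(list(rho = rho, method = method, n_resamples = n_resamples),
            class = "lancaster_covariance")
}

# Extract the matrix (zero matrix for analytic-zero), checking dimension.
cov_matrix <- function(cov, m) {
  if (inherits(cov, "lancaster_covariance")) {
    if (is.null(cov$rho)) return(matrix(0, m, m))
    rho <- cov$rho
  } else {
    rho <- as.matrix(cov)
  }
  if (nrow(rho) != m) {
    stop(sprintf("covariance is %d-by-%d but %d tests were supplied", nrow(rho), ncol(rho), m))
  }
  rho
}

#' Estimate the Lancaster covariance by null resampling
#'
#' Runs a user-supplied generator of null p-value vectors (typically a
#' phenotype-permutation rerun of the gene-level tests, which preserves the
#' genotype LD architecture responsible for the correlation), transforms each
#' vector by \eqn{F_i^{-1}(1-\cdot)}, and returns the sample covariance of
#' the transformed statistics.
#'
#' @param runner function of one argument (the resample index) returning a
#'   numeric p-value vector of fixed length under one null resample.
#' @param B number of resamples (at least 100).
#' @param w degrees-of-freedom weights matching the p-value vectors.
#' @param seed RNG seed making the resampling reproducible.
#' @return A \code{"lancaster_covariance"} with \code{method = "permutation"}.
#' @export
estimate_lancaster_covariance <- function(runner, B = 1000, w, seed = NULL) {
  if (B < 100) stop("'B' must be at least 100 resamples")
  w <- check_weights(w, length(w))
  m <- length(w)
  P <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = B, ncol = m)
    for (b in seq_len(B)) {
      pb <- runner(b)
      check_pvalues(pb, arg = sprintf("resample %d", b))
      if (length(pb) != m) stop("resampled p-vector length does not match 'w'")
      out[b, ] <- pb
    }
    out
  })
  cov_from_null_pvalues(P, w, method = "permutation")
}

#' Covariance from an archive of null p-values
#'
#' @param P B-by-m matrix of null-resampled p-values (rows = resamples).
#' @param w degrees-of-freedom weights (length m).
#' @param method provenance tag stored on the result.
#' @return A \code{"lancaster_covariance"}.
#' @export
cov_from_null_pvalues <- function(P, w, method = "permutation") {
  P <- as.matrix(P)
  w <- check_weights(w, ncol(P))
  if (any(apply(P, 2, function(x) diff(range(x)) == 0))) {
    stop("degenerate resamples: at least one test has constant p-values")
  }
  Tm <- matrix(chisq_inv_sf(as.vector(P), rep(w, each = nrow(P))),
               nrow = nrow(P))
  lancaster_covariance(stats::cov(Tm), method = method, n_resamples = nrow(P))
}

#' Correlation-corrected (self-contained) Lancaster test
#'
#' Computes the Lancaster statistic and refers it to the Satterthwaite scaled
#' chi-square null \eqn{c\chi^2_v} whose moments absorb the estimated
#' covariance among the transformed p-values. With a zero covariance the test
#' reduces exactly to the independent chi-square null with \eqn{\sum w_i}
#' degrees of freedom.
#'
#' If a noisy covariance estimate makes the implied total variance
#' non-positive, the off-diagonal sum is shrunk toward zero by the minimal
#' factor restoring positivity and a warning is issued.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param w degrees-of-freedom weights (default 2 each).
#' @param cov covariance estimate ([lancaster_covariance()], a raw matrix, or
#'   \code{NULL} for independence).
#' @return A \code{"combined_test"} object whose null parameters record the
#'   scale \code{c}, degrees of freedom \code{v}, and off-diagonal covariance
#'   sum.
#' @examples
#' p <- c(0.02, 0.4, 0.7)
#' correlated_lancaster_test(p)   # independent null
#' @export
correlated_lancaster_test <- function(p, w = NULL, cov = NULL) {
  check_pvalues(p)
  m <- length(p)
  w <- check_weights(w, m)
  stat <- sum(chisq_inv_sf(p, w))
  rho <- if (is.null(cov)) matrix(0, m, m) else cov_matrix(cov, m)
  off <- sum(rho[upper.tri(rho)])
  var_T <- 2 * sum(w) + 2 * off
  if (var_T <= 0) {
    shrink <- 0.99 * sum(w) / abs(off)
    warning(sprintf(
      "estimated covariance implies non-positive variance; off-diagonals shrunk by factor %.3g",
      shrink))
    off <- off * shrink
    var_T <- 2 * sum(w) + 2 * off
  }
  sw <- satterthwaite_params(sum(w), var_T)
  p_log <- stats::pchisq(stat / sw$c, df = sw$v, lower.tail = FALSE, log.p = TRUE)
  res <- combined_result("lancaster (Satterthwaite-corrected)", stat,
                         list(c = sw$c, v = sw$v, rho_sum = off), p_log, m)
  res
}

#' Q-Q inflation factor of a p-value collection
#'
#' Ratio between the area under the empirical Q-Q curve of sorted
#' \eqn{-\log_{10} p} against \eqn{-\log_{10}} expected uniform quantiles and
#' the area under the identity line over the same abscissa range (trapezoid
#' rule at the order statistics). Expected quantiles use the midpoint plotting
#' position \eqn{(i - 0.5)/m}. Values near 1 indicate calibrated p-values;
#' values above 1 indicate inflation.
#'
#' @param p at least 10 p-values in (0, 1].
#' @return The inflation factor \eqn{\lambda > 0}.
#' @examples
#' m <- 1000
#' inflation_factor((seq_len(m) - 0.5) / m) # exactly 1
#' @export
inflation_factor <- function(p) {
  check_pvalues(p)
  m <- length(p)
  if (m < 10) stop("at least 10 p-values are required")
  expected <- sort(-log10((seq_len(m) - 0.5) / m))
  observed <- sort(-log10(sort(p, decreasing = TRUE)))
  a_curve <- trapezoid_area(expected, observed)
  a_diag <- trapezoid_area(expected, expected)
  a_curve / a_diag
}
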