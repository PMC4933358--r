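# Bahadur efficiency slope calculators for the weighted combined p-value
# methods. The slope c(theta) is the almost-sure limit of -2 log(P_n)/n under
# the alternative; larger slopes mean faster decay of the significance level,
# and the ratio of two slopes is the limiting inverse ratio of sample sizes
# required to reach the same (vanishing) significance level.

check_slope_inputs <- function(lambda, c_ind, w = NULL) {
  if (length(lambda) != length(c_ind)) stop("'lambda' and 'c_ind' lengths differ")
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("all 'lambda' must be > 0")
  if (any(!is.finite(c_ind)) || any(c_ind <= 0)) stop("all 'c_ind' must be > 0")
  if (!is.null(w)) w <- check_weights(w, length(lambda))
  w
}

slope_result <- function(method, slope, penalty = 1, correlated = FALSE) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  structure(list(method = method, slope = slope, penalty = penalty,
                 correlated = correlated),
            class = "bahadur_slope")
}

#' @export
print.bahadur_slope <- function(x, ...) {
  cat(sprintf("Bahadur slope [%s]: %.6g", x$method, x$slope))
  if (x$correlated) cat(sprintf("  (correlation penalty %.4g)", x$penalty))
  cat("\n")
  invisible(x)
}

#' Bahadur slope of the Lancaster (and Fisher) combination
#'
#' \eqn{c_{Lancaster}(\theta) = \sum_i \lambda_i c_i(\theta)}: the sum of the
#' per-test slopes weighted by the limiting sample-size fractions
#' \eqn{\lambda_i = \lim n_i / n}. The slope does not depend on the
#' chi-square weights, so Fisher's method attains the same slope.
#'
#' @param lambda per-test sample-size fractions, all > 0.
#' @param c_ind per-test individual Bahadur slopes \eqn{c_i(\theta)}, all > 0.
#' @return A \code{"bahadur_slope"} object.
#' @export
slope_lancaster <- function(lambda, c_ind) {
  check_slope_inputs(lambda, c_ind)
  slope_result("lancaster", sum(lambda * c_ind))
}

#' @rdname slope_lancaster
#' @export
slope_fisher <- function(lambda, c_ind) {
  res <- slope_lancaster(lambda, c_ind)
  res$method <- "fisher"
  res
}

#' Bahadur slope of the weighted Z-test
#'
#' \eqn{c_{wZ}(\theta) = \left(\sum_i w_i \sqrt{\lambda_i c_i(\theta)}\right)^2
#' / \sum_i w_i^2}. With equal weights this reduces to the regular Z-test
#' slope \eqn{\left(\sum_i \sqrt{\lambda_i c_i}\right)^2 / m}. By
#' Cauchy-Schwarz it never exceeds the Lancaster slope, with equality only
#' when all \eqn{\lambda_i c_i / w_i^2} are equal.
#'
#' @inheritParams slope_lancaster
#' @param w positive combination weights (default all 1, the regular Z-test).
#' @export
slope_weighted_z <- function(lambda, c_ind, w = NULL) {
  w <- check_slope_inputs(lambda, c_ind, if (is.null(w)) 1 else w)
  s <- sum(w * sqrt(lambda * c_ind))^2 / sum(w^2)
  slope_result(if (all(w == w[1])) "regular_z" else "weighted_z", s)
}

#' Bahadur slope of Good's weighted product test
#'
#' \eqn{c_{Good}(\theta) = \sum_i w_i \lambda_i c_i(\theta) / \max_i w_i}.
#' Only tests carrying the maximal weight retain their full individual slope;
#' every other test contributes \eqn{(w_i / \max w) \lambda_i c_i < \lambda_i
#' c_i}, so the slope never exceeds the Lancaster slope and equals it only
#' when all weights are equal.
#'
#' @inheritParams slope_weighted_z
#' @export
slope_good <- function(lambda, c_ind, w = NULL) {
  w <- check_slope_inputs(lambda, c_ind, if (is.null(w)) 1 else w)
  slope_result("good", sum(w * lambda * c_ind) / max(w))
}

#' Approximate Bahadur slopes under correlation
#'
#' Multiplies the independent slope by a correlation penalty driven by the sum
#' of pairwise null covariances:
#' \itemize{
#'   \item Lancaster: \eqn{\frac{\sum w_i}{\sum w_i + 2\sum_{i<j}\rho_{ij}}
#'     \sum \lambda_i c_i}, with \eqn{\rho_{ij}} the covariance of the
#'     chi-square transformed statistics;
#'   \item Good: \eqn{\frac{\sum w_i}{\sum w_i^2 + 2\sum_{i<j}\tilde\rho_{ij}}
#'     \sum w_i \lambda_i c_i}, with \eqn{\tilde\rho_{ij}} the covariance of
#'     the log p-values (the denominator is the stated form; it does not
#'     reduce to the independent \eqn{\max_i w_i} form at zero correlation);
#'   \item Fisher: \eqn{\frac{m}{m + 2\sum_{i<j}\tilde\rho_{ij}}
#'     \sum \lambda_i c_i}.
#' }
#'
#' @param method \code{"lancaster"}, \code{"good"} or \code{"fisher"}.
#' @inheritParams slope_weighted_z
#' @param rho_sum the off-diagonal covariance sum \eqn{\sum_{i<j}\rho_{ij}}
#'   (Lancaster) or \eqn{\sum_{i<j}\tilde\rho_{ij}} (Good, Fisher).
#' @export
slope_correlated <- function(method = c("lancaster", "good", "fisher"),
                             lambda, c_ind, w = NULL, rho_sum = 0) {
  method <- match.arg(method)
  w <- check_slope_inputs(lambda, c_ind, if (is.null(w)) 2 else w)
  m <- length(lambda)
  base <- switch(method,
    lancaster = sum(lambda * c_ind),
    fisher    = sum(lambda * c_ind),
    good      = sum(w * lambda * c_ind))
  denom <- switch(method,
    lancaster = sum(w) + 2 * rho_sum,
    fisher    = m + 2 * rho_sum,
    good      = sum(w^2) + 2 * rho_sum)
  if (denom <= 0) stop("correlation penalty denominator is not positive")
  penalty <- switch(method,
    lancaster = sum(w) / denom,
    fisher    = m / denom,
    good      = sum(w) / denom)
  slope_result(paste0(method, " (correlated)"), penalty * base,
               penalty = penalty, correlated = TRUE)
}

#' Bahadur relative efficiency of two tests
#'
#' \eqn{\phi_{12}(\theta) = c_1(\theta) / c_2(\theta)}: the limiting ratio
#' \eqn{N^{(2)}/N^{(1)}} of sample sizes the two tests need to reach the same
#' vanishing significance level. Values of 1 or more mean test 1 needs no more
#' data than test 2.
#'
#' @param c1,c2 \code{"bahadur_slope"} objects or positive slope values.
#' @return The efficiency ratio.
#' @export
relative_efficiency <- function(c1, c2) {
  s1 <- if (inherits(c1, "bahadur_slope")) c1$slope else c1
  s2 <- if (inherits(c2, "bahadur_slope")) c2$slope else c2
  if (!is.finite(s1) || s1 <= 0 || !is.finite(s2) || s2 <= 0) {
    stop("slopes must be positive")
  }
  s1 / s2
}

#' Empirical Bahadur slope of a p-value sequence
#'
#' Verification harness for the slope theory: draws significance levels from
#' a generator at increasing sample sizes and regresses \eqn{-2\log P_n} on
#' \eqn{n} through the origin. Only the top half of the grid enters the fit,
#' since the limit is linear in \eqn{n} and small \eqn{n} carries
#' pre-asymptotic bias.
#'
#' @param pvalue_generator function \code{(n, seed)} returning one significance
#'   level at sample size \code{n}.
#' @param n_grid increasing grid of at least 3 sample sizes.
#' @param reps replicates per grid point (at least 50).
#' @param seed RNG seed.
#' @return List with \code{slope}, \code{se}, the fitted points, and a flag
#'   marking clamped (underflowed) p-values.
#' @export
empirical_slope <- function(pvalue_generator, n_grid, reps = 100, seed = NULL) {
  if (length(n_grid) < 3 || is.unsorted(n_grid, strictly = TRUE)) {
    stop("'n_grid' must be at least 3 strictly increasing sample sizes")
  }
  if (reps < 50) stop("'reps' must be at least 50")
  clamped <- FALSE
  draws <- with_seed(seed, {
    do.call(rbind, lapply(n_grid, function(n) {
      p <- vapply(seq_len(reps), function(r) {
        pvalue_generator(n, derive_seed(if (is.null(seed)) 0L else seed,
                                        n * 1000L + r))
      }, numeric(1))
      if (any(p < P_FLOOR)) {
        clamped <<- TRUE
        p <- pmax(p, P_FLOOR)
      }
      cbind(n = n, y = -2 * log(p))
    }))
  })
  top <- draws[, "n"] >= stats::median(n_grid)
  x <- draws[top, "n"]
  y <- draws[top, "y"]
  slope <- sum(x * y) / sum(x^2)
  resid <- y - slope * x
  se <- sqrt(sum(resid^2) / (length(y) - 1) / sum(x^2))
  list(slope = slope, se = se, n = draws[, "n"], neg2logp = draws[, "y"],
       clamped = clamped)
}
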