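#' Lancaster statistic for combining independent p-values
#'
#' Computes \eqn{T = \sum_i F_i^{-1}(1 - P_i)} where \eqn{F_i} is the CDF of a
#' chi-square distribution with \eqn{w_i} degrees of freedom. With all
#' \eqn{w_i = 2} this is exactly Fisher's statistic \eqn{-2\sum \log P_i}.
#'
#' @param p numeric vector of p-values, each in (0, 1].
#' @param w positive chi-square degrees-of-freedom weights, one per p-value
#'   (scalar weights are recycled). Default 2 for every test.
#' @return The non-negative Lancaster statistic. A p-value of exactly 1
#'   contributes 0.
#' @examples
#' lancaster_statistic(c(0.5, 0.5), c(2, 2)) # -2*log(0.5)*2
#' @export
lancaster_statistic <- function(p, w = NULL) {
  check_pvalues(p)
  w <- check_weights(w, length(p))
  sum(chisq_inv_sf(p, w))
}

# Build the common result container.
combined_result <- function(method, statistic, parameters, p_log, m) {
  p_log <- min(p_log, 0)
  structure(
    list(
      method = method,
      statistic = statistic,
      parameters = parameters,
      p.value = max(exp(p_log), P_FLOOR),
      log10.p = p_log / log(10),
      m = m
    ),
    class = "combined_test"
  )
}

#' @export
print.combined_test <- function(x, ...) {
  cat("Combined p-value test:", x$method, "\n")
  cat(sprintf("  statistic = %.6g on %d component test(s)\n", x$statistic, x$m))
  pstr <- if (x$p.value <= P_FLOOR) {
    sprintf("< 1e-300 (log10 p = %.4f)", x$log10.p)
  } else {
    sprintf("%.6g", x$p.value)
  }
  cat("  combined p-value =", pstr, "\n")
  if (length(x$parameters)) {
    cat("  null parameters:",
        paste(names(x$parameters), signif(unlist(x$parameters), 6),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Combine independent p-values
#'
#' Combined p-value statistics with their exact independent-case null
#' distributions: Fisher's method, the regular and weighted Z-tests
#' (one-sided, upper tail), Good's weighted Fisher method, and the Lancaster
#' procedure (weighted inverse chi-square transforms).
#'
#' Method notes:
#' \itemize{
#'   \item \code{"lancaster"}: \eqn{T = \sum F_i^{-1}(1-P_i)}, null
#'     \eqn{\chi^2} with \eqn{\sum w_i} degrees of freedom.
#'   \item \code{"fisher"}: Lancaster with every \eqn{w_i = 2} (identical
#'     statistic and p-value by construction).
#'   \item \code{"z"} / \code{"weighted_z"}:
#'     \eqn{T = \sum w_i \Phi^{-1}(1-P_i) / \sqrt{\sum w_i^2}}, standard
#'     normal null. Inputs at the boundaries are clamped to
#'     \code{[1e-300, 1 - 1e-15]} so the normal quantile stays finite.
#'   \item \code{"good"}: \eqn{-\log Q = -\sum w_i \log P_i} with
#'     \eqn{Q = \prod P_i^{w_i}}; for pairwise-distinct weights the null CDF
#'     \eqn{\Pr(Q < q) = \sum_i \Lambda_i q^{1/w_i}} is used (see
#'     [good_null_cdf()]), otherwise a seeded Monte-Carlo null.
#' }
#'
#' Combined p-values that underflow double precision are reported as
#' \code{1e-300} with the informative value carried in \code{log10.p}.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param w per-test weights. For the chi-square methods these are the
#'   degrees-of-freedom weights (default 2); for the weighted Z-test they are
#'   the linear combination weights (default 1).
#' @param method one of \code{"lancaster"}, \code{"fisher"}, \code{"z"},
#'   \code{"weighted_z"}, \code{"good"}.
#' @param mc_reps Monte-Carlo null size used by Good's method when weights are
#'   tied.
#' @param seed seed for the Monte-Carlo null (tied-weight Good only).
#' @return An object of class \code{"combined_test"}: statistic, null
#'   parameters, \code{p.value}, and \code{log10.p}.
#' @examples
#' combine_pvalues(c(0.5, 0.5), method = "fisher")
#' combine_pvalues(c(0.05, 0.2, 0.8), w = c(4, 2, 1), method = "lancaster")
#' @export
combine_pvalues <- function(p,
                            w = NULL,
                            method = c("lancaster", "fisher", "z",
                                       "weighted_z", "good"),
                            mc_reps = 1e6,
                            seed = NULL) {
  method <- match.arg(method)
  check_pvalues(p)
  m <- length(p)
  switch(method,
    lancaster = {
      w <- check_weights(w, m)
      stat <- sum(chisq_inv_sf(p, w))
      lancaster_pvalue_independent(stat, w)
    },
    fisher = {
      if (!is.null(w)) stop("Fisher's method takes no weights; use method = 'lancaster'")
      stat <- sum(chisq_inv_sf(p, rep(2, m)))
      res <- lancaster_pvalue_independent(stat, rep(2, m))
      res$method <- "fisher"
      res
    },
    z = ,
    weighted_z = {
      if (method == "z") {
        if (!is.null(w)) stop("the regular Z-test takes no weights; use method = 'weighted_z'")
        w <- rep(1, m)
      } else {
        w <- if (is.null(w)) rep(1, m) else w
        w <- check_weights(w, m)
      }
      pc <- clamp_pvalues(p)
      stat <- sum(w * stats::qnorm(pc, lower.tail = FALSE)) / sqrt(sum(w^2))
      p_log <- stats::pnorm(stat, lower.tail = FALSE, log.p = TRUE)
      combined_result(if (method == "z") "regular_z" else "weighted_z",
                      stat, list(mean = 0, sd = 1), p_log, m)
    },
    good = {
      w <- check_weights(w, m)
      good_combine(p, w, mc_reps = mc_reps, seed = seed)
    }
  )
}

#' Independent-case Lancaster p-value
#'
#' Survival probability of the Lancaster statistic under independence, where
#' the null is chi-square with \eqn{\sum w_i} degrees of freedom.
#'
#' @param statistic non-negative Lancaster statistic.
#' @param w the degrees-of-freedom weights that generated the statistic.
#' @return A \code{"combined_test"} object with \code{df} recorded in the null
#'   parameters.
#' @export
lancaster_pvalue_independent <- function(statistic, w) {
  if (!is.numeric(statistic) || length(statistic) != 1L || !is.finite(statistic) ||
      statistic < 0) {
    stop("'statistic' must be a single non-negative number")
  }
  if (any(w <= 0)) stop("all weights must be > 0")
  df <- sum(w)
  p_log <- stats::pchisq(statistic, df = df, lower.tail = FALSE, log.p = TRUE)
  combined_result("lancaster", statistic, list(df = df), p_log, length(w))
}

#' Null CDF of Good's weighted product statistic
#'
#' For \eqn{Q = \prod_i P_i^{w_i}} with independent uniform \eqn{P_i} and
#' pairwise-distinct positive weights, \eqn{\Pr(Q < q) = \sum_i \Lambda_i
#' q^{1/w_i}} with \eqn{\Lambda_i = w_i^{m-1} / \prod_{j \ne i}(w_i - w_j)}.
#'
#' @param q quantile(s) in \code{[0, 1]} (vectorised).
#' @param w pairwise-distinct positive weights.
#' @return CDF value(s) in \code{[0, 1]}.
#' @examples
#' good_null_cdf(0.25, c(1, 2)) # -0.25 + 2*0.5 = 0.75
#' @export
good_null_cdf <- function(q, w) {
  if (any(q < 0 | q > 1)) stop("'q' must lie in [0, 1]")
  w <- check_weights(w, length(w))
  lam <- good_lambda(w)
  out <- vapply(q, function(qq) {
    if (qq == 0) return(0)
    sum(lam * exp(log(qq) / w))
  }, numeric(1))
  pmin(pmax(out, 0), 1)
}

# Lambda coefficients of Good's closed-form null; errors on tied weights.
good_lambda <- function(w) {
  m <- length(w)
  if (m == 1L) return(1)
  if (anyDuplicated(w)) {
    stop("Good's closed-form null requires pairwise-distinct weights; ",
         "use the Monte-Carlo null (combine_pvalues(..., method = 'good') ",
         "falls back to it automatically)")
  }
  vapply(seq_len(m), function(i) {
    w[i]^(m - 1) / prod(w[i] - w[-i])
  }, numeric(1))
}

# Good's combined test; closed form when weights are distinct, seeded
# Monte-Carlo null otherwise.
good_combine <- function(p, w, mc_reps = 1e6, seed = NULL) {
  m <- length(p)
  log_q <- sum(w * log(p))        # log Q, <= 0
  stat <- -log_q
  if (all(w == w[1])) {
    # equal weights: -log Q = w/2 * T_Fisher, so the null is w/2 * chi2_{2m}
    p_log <- stats::pchisq(2 * stat / w[1], df = 2 * m,
                           lower.tail = FALSE, log.p = TRUE)
    return(combined_result("good", stat, list(w = w), p_log, m))
  }
  if (!anyDuplicated(w)) {
    lam <- good_lambda(w)
    pv <- sum(lam * exp(log_q / w))
    pv <- min(max(pv, 0), 1)
    p_log <- if (pv > 0) log(pv) else max(log_q / w) # leading exponential term
    res <- combined_result("good", stat, list(Lambda = lam, w = w), p_log, m)
    return(res)
  }
  # Tied weights: seeded Monte-Carlo estimate of Pr(-log Q >= stat).
  mc_reps <- as.integer(mc_reps)
  pv <- with_seed(seed, {
    hits <- 0L
    block <- 1e5L
    done <- 0L
    while (done < mc_reps) {
      nb <- min(block, mc_reps - done)
      u <- matrix(stats::runif(nb * m), nrow = m)
      stat_null <- -colSums(w * log(u))
      hits <- hits + sum(stat_null >= stat)
      done <- done + nb
    }
    hits / mc_reps
  })
  pv <- max(pv, 1 / mc_reps)
  res <- combined_result("good (Monte-Carlo null)", stat,
                         list(w = w, mc_reps = mc_reps), log(pv), m)
  res
}
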