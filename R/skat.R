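# Stage I gene-level testing: the SKAT variance-component score statistic
# Q = r' G W G' r with r the null-model residuals, referred to its
# mixture-of-one-df-chi-squares null by characteristic-function inversion
# (Imhof's method) with a three-moment (Liu-type) fallback.

#' Survival function of a positive linear combination of chi-squares
#'
#' \eqn{\Pr(\sum_k \lambda_k \chi^2_{1,k} > q)} for positive mixture weights
#' \eqn{\lambda_k}, evaluated by numerical inversion of the characteristic
#' function (Imhof's formula) via adaptive quadrature. If the quadrature
#' fails to converge the three-moment scaled noncentral chi-square
#' approximation is used and flagged.
#'
#' @param q non-negative quantile.
#' @param lambda positive mixture weights (eigenvalues).
#' @param rel.tol relative tolerance passed to the quadrature.
#' @return List with \code{p} (in (0, 1]) and \code{fallback} (logical).
#' @export
mixture_chisq_sf <- function(q, lambda, rel.tol = 1e-9) {
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0L) return(list(p = 1, fallback = FALSE))
  if (q <= 0) return(list(p = 1, fallback = FALSE))
  if (length(lambda) == 1L) {
    # one-eigenvalue mixture is an exact scaled chi-square(1)
    return(list(p = stats::pchisq(q / lambda, df = 1, lower.tail = FALSE),
                fallback = FALSE))
  }
  val <- tryCatch(imhof_integral(q, lambda, rel.tol = rel.tol),
                  error = function(e) NA_real_)
  if (is.na(val)) {
    return(list(p = liu_sf(q, lambda), fallback = TRUE))
  }
  p <- 0.5 + val / pi
  if (p < 1e-13 || p > 1 + 1e-10) {
    # below the quadrature noise floor the moment approximation is smoother
    # and strictly positive
    return(list(p = liu_sf(q, lambda), fallback = TRUE))
  }
  list(p = min(max(p, 0), 1), fallback = FALSE)
}

# Imhof's inversion integral int_0^inf sin(theta(u)) / (u rho(u)) du.
# The integrand oscillates with asymptotic frequency q/2 and decays only as
# u^-(J/2 + 1), which defeats generic adaptive quadrature on (0, Inf) for
# small J. Strategy: adaptive quadrature on the head (phase above -pi), then
# phase-tracked half-period blocks (Gauss-Legendre) whose alternating sums
# are Euler-accelerated.
imhof_integral <- function(q, lambda, rel.tol = 1e-9) {
  theta <- function(u) 0.5 * sum(atan(lambda * u)) - 0.5 * q * u
  dtheta <- function(u) 0.5 * sum(lambda / (1 + (lambda * u)^2)) - 0.5 * q
  integrand <- function(u) {
    lu <- outer(lambda, u)
    th <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(lu^2)))
    out <- sin(th) / (u * rho)
    out[u == 0] <- 0.5 * (sum(lambda) - q)
    out
  }
  # first phase crossing theta = -pi (theta is concave: rises at most once,
  # then decreases without bound at rate ~ q/2)
  hi <- (length(lambda) * pi / 2 + 2 * pi) * 2.5 / q
  while (theta(hi) > -pi) hi <- hi * 2
  u1 <- stats::uniroot(function(u) theta(u) + pi, c(0, hi),
                       tol = 1e-10 * (1 + hi))$root
  head <- stats::integrate(integrand, 0, u1, rel.tol = rel.tol,
                           abs.tol = 1e-14, subdivisions = 500L)$value
  # Gauss-Legendre nodes/weights (15-point) on [0, 1]
  gl <- gauss_legendre_15()
  n_blocks <- 18L
  uk <- u1
  th_k <- -pi
  blocks <- numeric(n_blocks)
  for (k in seq_len(n_blocks)) {
    # next crossing theta = th_k - pi by Newton from the asymptotic step
    target <- th_k - pi
    u_next <- uk + pi / (0.5 * q)
    for (it in 1:6) {
      step <- (theta(u_next) - target) / dtheta(u_next)
      u_next <- u_next - step
      if (abs(step) < 1e-12 * u_next) break
    }
    nodes <- uk + (u_next - uk) * gl$x
    blocks[k] <- (u_next - uk) * sum(gl$w * integrand(nodes))
    uk <- u_next
    th_k <- target
  }
  # Euler transformation of the alternating tail
  s <- cumsum(blocks)
  for (i in seq_len(n_blocks - 1L)) {
    s <- (s[-1] + s[-length(s)]) / 2
  }
  head + s
}

gauss_legendre_15 <- function() {
  if (is.null(.gl15$x)) {
    # Golub-Welsch from the Jacobi matrix of Legendre polynomials
    n <- 15L
    b <- (1:(n - 1)) / sqrt(4 * (1:(n - 1))^2 - 1)
    Jm <- matrix(0, n, n)
    Jm[cbind(1:(n - 1), 2:n)] <- b
    Jm[cbind(2:n, 1:(n - 1))] <- b
    e <- eigen(Jm, symmetric = TRUE)
    .gl15$x <- (rev(e$values) + 1) / 2            # map [-1,1] -> [0,1]
    .gl15$w <- rev(2 * e$vectors[1, ]^2) / 2
  }
  list(x = .gl15$x, w = .gl15$w)
}
.gl15 <- new.env(parent = emptyenv())

# Liu-Tang-Zhang three-moment approximation: match skewness (or kurtosis)
# with a scaled noncentral chi-square.
liu_sf <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- c2^3 / c3^2
  }
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta
  sigma_x <- sqrt(2) * a
  tstar <- (q - mu_q) / sigma_q
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta, lower.tail = FALSE)
}

#' MAF-based variant weights
#'
#' @param maf per-variant minor allele frequencies in (0, 0.5].
#' @param scheme \code{"beta"} (Beta(1, 25) density at the MAF, the common
#'   SKAT up-weighting of rare variants), \code{"flat"} (all 1), or
#'   \code{"invvar"} (\eqn{1 / (maf(1-maf))}).
#' @return Non-negative per-variant weights (the diagonal of W).
#' @export
variant_weights_from_maf <- function(maf, scheme = c("beta", "flat", "invvar")) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(maf)) || any(maf < 0) || any(maf > 0.5)) {
    stop("'maf' must lie in [0, 0.5]")
  }
  switch(scheme,
    beta = stats::dbeta(maf, 1, 25),
    flat = rep(1, length(maf)),
    invvar = {
      if (any(maf == 0)) stop("inv-var weights are undefined at maf = 0")
      1 / (maf * (1 - maf))
    })
}

# Null-model fit shared by the statistic and the p-value: QR of the design.
null_model_fit <- function(y, X) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1) else {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("'X' and 'y' lengths disagree")
    if (!all(abs(X[, 1] - 1) < .Machine$double.eps^0.5)) X <- cbind(1, X)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate matrix is rank deficient")
  r <- qr.resid(qx, y)
  df <- n - qx$rank
  if (df < 1) stop("more covariates than residual degrees of freedom")
  list(qx = qx, residuals = r, sigma2 = sum(r^2) / df, rank = qx$rank, n = n)
}

#' SKAT variance-component score statistic
#'
#' Fits the null linear model \eqn{y = X\alpha + \varepsilon} by least squares
#' and returns \eqn{Q = r^t G W G^t r} with \eqn{r = y - \hat\mu} and
#' \eqn{W = diag(w)}.
#'
#' @param y continuous trait vector.
#' @param G n-by-J dosage matrix (0/1/2).
#' @param X covariate matrix; an intercept column is added if absent.
#'   \code{NULL} means intercept only.
#' @param w per-variant weights (default all 1).
#' @return List with \code{Q} and the null residuals.
#' @export
skat_statistic <- function(y, G, X = NULL, w = NULL) {
  G <- as.matrix(G)
  if (nrow(G) != length(y)) stop("'G' and 'y' sizes disagree")
  if (is.null(w)) w <- rep(1, ncol(G))
  if (length(w) != ncol(G)) stop("'w' length must equal the number of variants")
  if (any(w < 0) || all(w == 0)) stop("variant weights must be >= 0 with at least one > 0")
  fit <- null_model_fit(y, X)
  score <- crossprod(G, fit$residuals)
  list(Q = sum(w * score^2), residuals = fit$residuals)
}

#' Gene-level SKAT test
#'
#' The sequence kernel association test for a continuous trait: a
#' variance-component score test of \eqn{H_0: \tau = 0} in
#' \eqn{y = X\alpha + G\beta + \varepsilon} with
#' \eqn{\beta_j \sim (0, w_j \tau)}. Under the null, \eqn{Q = r^t G W G^t r}
#' follows a mixture of one-df chi-squares with weights
#' \eqn{\hat\sigma^2 \cdot \mathrm{eig}\{W^{1/2} G^t (I - H) G W^{1/2}\}},
#' evaluated by [mixture_chisq_sf()].
#'
#' @inheritParams skat_statistic
#' @param w per-variant weights, or a scheme name accepted by
#'   [variant_weights_from_maf()] (requires \code{maf}).
#' @param maf per-variant minor allele frequencies; computed from column means
#'   of \code{G} when missing and a MAF-based scheme is requested.
#' @return An object of class \code{"skat_test"} with the statistic,
#'   eigenvalue spectrum, p-value and fallback flag.
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(600, 2, 0.1), nrow = 100)
#' y <- rnorm(100)
#' skat_test(y, G, w = "flat")
#' @export
skat_test <- function(y, G, X = NULL, w = "beta", maf = NULL) {
  G <- as.matrix(G)
  J <- ncol(G)
  if (is.character(w)) {
    if (is.null(maf)) maf <- pmin(colMeans(G) / 2, 0.5)
    w <- variant_weights_from_maf(maf, w)
  }
  st <- skat_statistic(y, G, X = X, w = w)
  fit <- null_model_fit(y, X)
  ev <- skat_null_eigenvalues(G, fit, w)
  if (length(ev) == 0L) {
    warning("no genetic variance after projection; p-value set to 1")
    res <- list(p = 1, fallback = FALSE)
    ev <- numeric(0)
  } else {
    res <- mixture_chisq_sf(st$Q, ev)
  }
  structure(list(statistic = st$Q, p.value = res$p, eigenvalues = ev,
                 fallback = res$fallback, n = fit$n, J = J,
                 sigma2 = fit$sigma2),
            class = "skat_test")
}

# Eigenvalues (already scaled by the null residual variance) of the SKAT
# null mixture for a fitted null model.
skat_null_eigenvalues <- function(G, fit, w) {
  A <- qr.resid(fit$qx, sweep(as.matrix(G), 2, sqrt(w), `*`))
  K <- crossprod(A)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev, 0) * 1e-10]
  fit$sigma2 * ev
}

#' SKAT p-value for a precomputed statistic
#'
#' @param Q the SKAT statistic.
#' @inheritParams skat_test
#' @return List with \code{p} and \code{fallback}.
#' @export
skat_pvalue <- function(Q, y, G, X = NULL, w = NULL) {
  G <- as.matrix(G)
  if (is.null(w)) w <- rep(1, ncol(G))
  fit <- null_model_fit(y, X)
  ev <- skat_null_eigenvalues(G, fit, w)
  if (length(ev) == 0L) {
    warning("no genetic variance after projection; p-value set to 1")
    return(list(p = 1, fallback = FALSE))
  }
  mixture_chisq_sf(Q, ev)
}

#' @export
print.skat_test <- function(x, ...) {
  cat("SKAT variance-component score test\n")
  cat(sprintf("  n = %d subjects, J = %d variants\n", x$n, x$J))
  cat(sprintf("  Q = %.6g, p-value = %.6g%s\n", x$statistic, x$p.value,
              if (x$fallback) " (moment-matched fallback)" else ""))
  invisible(x)
}
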