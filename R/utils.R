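# Internal helpers shared across modules.

# Validate a vector of p-values: finite, strictly positive, <= 1.
check_pvalues <- function(p, arg = "p") {
  if (length(p) < 1L) stop(sprintf("'%s' must contain at least one p-value", arg))
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p))) {
    stop(sprintf("'%s' must be finite numeric p-values", arg))
  }
  if (any(p <= 0)) {
    stop(sprintf("'%s' contains p-values <= 0; the chi-square transform diverges", arg))
  }
  if (any(p > 1)) stop(sprintf("'%s' contains p-values > 1", arg))
  invisible(p)
}

# Validate chi-square df weights, recycled to length m if scalar.
check_weights <- function(w, m, arg = "w") {
  if (is.null(w)) w <- rep(2, m)
  if (length(w) == 1L) w <- rep(w, m)
  if (length(w) != m) {
    stop(sprintf("'%s' has length %d but %d p-values were supplied", arg, length(w), m))
  }
  if (!is.numeric(w) || anyNA(w) || any(!is.finite(w)) || any(w <= 0)) {
    stop(sprintf("all '%s' must be finite and > 0", arg))
  }
  w
}

# Inverse survival transform F^{-1}(1 - p) for chi-square with df degrees of
# freedom. df = 2 has the closed form -2 log p (Fisher's transform); using it
# keeps Lancaster with uniform weight 2 exactly equal to Fisher's statistic.
chisq_inv_sf <- function(p, df) {
  if (length(df) == 1L) df <- rep(df, length(p))
  out <- numeric(length(p))
  two <- df == 2
  if (any(two)) out[two] <- -2 * log(p[two])
  if (any(!two)) out[!two] <- stats::qchisq(p[!two], df = df[!two], lower.tail = FALSE)
  out
}

# Floors used when a transform would hit an infinity (documented policy).
P_FLOOR <- 1e-300
P_CEIL  <- 1 - 1e-15

clamp_pvalues <- function(p) pmin(pmax(p, P_FLOOR), P_CEIL)

# Trapezoid-rule area under (x, y), x ascending.
trapezoid_area <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. A NULL seed leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and an index, staying inside the
# 32-bit integer range set.seed() accepts.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 9973 * as.double(k)) %% 2147483647)
}
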