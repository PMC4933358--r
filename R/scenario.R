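# End-to-end scenario evaluation: simulate genotypes, pathways and
# phenotypes, run the two-stage SKAT-Lancaster analysis per weight scheme,
# and aggregate type I error (null scenario) or stringent/lenient power plus
# the Q-Q inflation factor.

# Precompute a fast evaluator of the SKAT null survival function for a fixed
# eigenvalue spectrum. The exact Imhof inversion is evaluated on a grid of
# quantiles spanning p from 1 down to ~1e-12 and interpolated monotonically
# in log p; beyond the grid the (asymptotically linear) log tail is
# extrapolated from the last segment. Used by the simulation engine where
# the same spectrum is evaluated tens of thousands of times; single tests use
# the exact inversion directly.
skat_sf_interpolator <- function(ev, min_log10 = -12, grid_step = 0.25) {
  ev <- ev[ev > 0]
  if (length(ev) == 0L) return(function(x) rep(1, length(x)))
  targets <- 10^seq(-grid_step, min_log10, by = -grid_step)
  # invert the Liu approximation to place grid quantiles
  c1 <- sum(ev); c2 <- sum(ev^2); c3 <- sum(ev^3); c4 <- sum(ev^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2)); delta <- s1 * a^3 - a^2; l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1; delta <- 0; l <- c2^3 / c3^2
  }
  x <- stats::qchisq(targets, df = l, ncp = delta, lower.tail = FALSE)
  q <- c1 + (x - (l + delta)) / (sqrt(2) * a) * sqrt(2 * c2)
  q <- sort(unique(q[q > 0]))
  logp <- vapply(q, function(qq) {
    log(mixture_chisq_sf(qq, ev, rel.tol = 1e-7)$p)
  }, numeric(1))
  q <- c(0, q)
  logp <- c(0, logp)
  # enforce strict monotone decrease for the hyman spline
  logp <- cummin(logp)
  dup <- c(FALSE, diff(logp) == 0)
  q <- q[!dup]; logp <- logp[!dup]
  sp <- stats::splinefun(q, logp, method = "hyman")
  q_max <- q[length(q)]
  tail_slope <- (logp[length(logp)] - logp[length(logp) - 1]) /
    (q_max - q[length(q) - 1])
  logp_max <- logp[length(logp)]
  function(x) {
    out <- numeric(length(x))
    inside <- x <= q_max
    out[inside] <- sp(pmax(x[inside], 0))
    out[!inside] <- logp_max + tail_slope * (x[!inside] - q_max)
    pmin(exp(pmin(out, 0)), 1)
  }
}

# Off-diagonal covariance sum per pathway from a gene-level covariance matrix.
pathway_rho_sums <- function(rho, gene_idx_list) {
  vapply(gene_idx_list, function(idx) {
    (sum(rho[idx, idx]) - sum(diag(rho)[idx])) / 2
  }, numeric(1))
}

#' Run a full simulation scenario
#'
#' Per replicate: draws effects and a phenotype on a fixed synthetic genotype
#' and pathway structure, computes gene-level SKAT p-values, combines them
#' per pathway with the correlation-corrected Lancaster procedure under each
#' requested gene-weight scheme, and thresholds at the scenario's
#' (Bonferroni) significance level. Genotypes and pathway structure are drawn
#' once per call and phenotypes are redrawn per replicate; the gene-gene
#' covariance of the transformed statistics is estimated once from
#' \code{cov_B} null-phenotype resamples on the same genotypes.
#'
#' @param scn a [sim_scenario()].
#' @param replicates number of replicates (at least 20).
#' @param weight_schemes subset of \code{c("uniform", "gene_size", "aic",
#'   "bic")}.
#' @param cov_B null resamples behind the covariance estimate.
#' @param variant_weight_scheme Stage I variant weighting (see
#'   [variant_weights_from_maf()]).
#' @param seed RNG seed; the run is deterministic given the seed.
#' @param keep_pvalues keep the replicate-by-pathway p-value matrices.
#' @return Object of class \code{"scenario_report"}: per-scheme type I error
#'   or stringent/lenient power, inflation factor, and settings.
#' @export
run_scenario <- function(scn, replicates = 100,
                         weight_schemes = c("uniform", "gene_size", "aic", "bic"),
                         cov_B = 1000,
                         variant_weight_scheme = "beta",
                         seed = NULL,
                         keep_pvalues = TRUE) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (replicates < 20) stop("'replicates' must be at least 20")
  weight_schemes <- match.arg(weight_schemes,
                              c("uniform", "gene_size", "aic", "bic"),
                              several.ok = TRUE)
  null_law <- scn$effect_law == "null"
  with_seed(seed, {
    ## --- fixed architecture -------------------------------------------
    pw <- build_pathways(scn$n_genes, scn$n_pathways,
                         size_range = scn$genes_per_pathway,
                         overlap = scn$pathway_overlap,
                         variants_per_gene_mean = scn$variants_per_gene_mean)
    geno <- simulate_genotypes(scn$n_subjects, nrow(pw$variant_map),
                               rare_fraction = scn$rare_fraction,
                               rare_range = scn$rare_range,
                               common_range = scn$common_range,
                               ld_block_size = scn$ld_block_size,
                               ld_rho = scn$ld_rho)
    G <- geno$G
    n <- scn$n_subjects
    X <- matrix(1, n, 1)
    if (scn$n_pcs > 0) {
      Gc <- scale(G, center = TRUE, scale = FALSE)
      X <- cbind(X, svd(Gc, nu = scn$n_pcs, nv = 0)$u)
    }
    qx <- qr(X)
    resid_df <- n - qx$rank

    gene_index <- split(seq_len(nrow(pw$variant_map)), pw$variant_map$gene)
    gene_index <- gene_index[pw$genes]           # original gene order
    snp_counts <- lengths(gene_index)
    vw <- variant_weights_from_maf(pmin(geno$maf, 0.5), variant_weight_scheme)

    # Per-gene precomputations on the fixed genotypes: weighted score matrix,
    # null eigen-spectrum, survival interpolator, and an orthonormal basis
    # for the information-criterion weights.
    genes <- pw$genes
    n_genes <- length(genes)
    Mg <- vector("list", n_genes)     # G_g sqrt(W): n x J_g
    sf <- vector("list", n_genes)     # null survival function of Q/sigma2
    Qb <- vector("list", n_genes)     # orthonormal basis of projected G_g
    rk <- integer(n_genes)
    for (g in seq_len(n_genes)) {
      idx <- gene_index[[g]]
      M <- sweep(G[, idx, drop = FALSE], 2, sqrt(vw[idx]), `*`)
      A <- qr.resid(qx, M)
      K <- crossprod(A)
      ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
      ev <- ev[ev > max(ev, 0) * 1e-10]
      Mg[[g]] <- M
      sf[[g]] <- skat_sf_interpolator(ev)
      qa <- qr(qr.resid(qx, G[, idx, drop = FALSE]))
      Qb[[g]] <- qr.Q(qa)[, seq_len(qa$rank), drop = FALSE]
      rk[g] <- qa$rank
    }

    gene_p_from_y <- function(y) {
      r <- qr.resid(qx, y)
      sigma2 <- sum(r^2) / resid_df
      vapply(seq_len(n_genes), function(g) {
        sf[[g]](sum(crossprod(Mg[[g]], r)^2) / sigma2)
      }, numeric(1))
    }

    ## --- null archive: gene p-values (and IC deltas) under resampled ----
    ## null phenotypes on the fixed genotypes
    ic_schemes <- intersect(weight_schemes, c("aic", "bic"))
    P_arch <- matrix(NA_real_, cov_B, n_genes)
    D_arch <- lapply(ic_schemes, function(s) matrix(NA_real_, cov_B, n_genes))
    names(D_arch) <- ic_schemes
    for (b in seq_len(cov_B)) {
      yb <- stats::rnorm(n)
      P_arch[b, ] <- gene_p_from_y(yb)
      for (s in ic_schemes) {
        D_arch[[s]][b, ] <- gene_ic_delta_fast(yb, qx, Qb, rk, criterion = s)
      }
    }
    P_arch <- pmin(pmax(P_arch, P_FLOOR), 1)

    gene_idx_in_pw <- lapply(pw$db$pathways, function(gs) match(gs, genes))
    arch_cov <- function(w) {
      Tm <- matrix(chisq_inv_sf(as.vector(P_arch), rep(w, each = cov_B)),
                   nrow = cov_B)
      stats::cov(Tm)
    }

    # Every scheme is reduced to phenotype-independent per-gene weights so
    # the Satterthwaite moments E(T) = sum(w), var(T) = 2 sum(w) +
    # 2 sum(rho_ij) stay exact (weights computed from the same phenotype as
    # the p-values would co-vary with them and inflate type I error). The
    # information-criterion weights therefore use the expected (floored)
    # criterion improvement across the null archive: a genotype-architecture
    # summary of the variation each gene's multi-SNP regression captures.
    fixed_w <- list()
    fixed_rho_sums <- list()
    for (s in weight_schemes) {
      w <- switch(s,
        uniform   = gene_weights("uniform", n_genes = n_genes),
        gene_size = gene_weights("gene_size", snp_counts = snp_counts),
        gene_weights(s, ic_delta = colMeans(pmax(D_arch[[s]], 0.1))))
      fixed_w[[s]] <- w
      fixed_rho_sums[[s]] <- pathway_rho_sums(arch_cov(w), gene_idx_in_pw)
    }

    ## --- replicate loop ------------------------------------------------
    n_pw <- length(pw$db$pathways)
    pvals <- lapply(weight_schemes, function(s) matrix(NA_real_, replicates, n_pw))
    names(pvals) <- weight_schemes
    central <- character(replicates)
    causal_overlap <- vector("list", replicates)
    pw_w_sum <- function(w) vapply(gene_idx_in_pw, function(i) sum(w[i]), numeric(1))

    for (rep_i in seq_len(replicates)) {
      if (null_law) {
        y <- stats::rnorm(n)
        central[rep_i] <- NA_character_
      } else {
        eff <- assign_effects(pw$db, pw$variant_map, geno$maf,
                              effect_law = scn$effect_law,
                              causal_gene_fraction = scn$causal_gene_fraction,
                              causal_variant_fraction = scn$causal_variant_fraction,
                              detrimental_gene_fraction = scn$detrimental_gene_fraction,
                              detrimental_variant_fraction = scn$detrimental_variant_fraction)
        gv <- as.vector(G %*% eff$beta)
        sigma2 <- scale_noise_to_heritability(gv, scn$h2)
        y <- gv + stats::rnorm(n, sd = sqrt(sigma2))
        central[rep_i] <- eff$central_pathway
        causal_overlap[[rep_i]] <- names(pw$db$pathways)[vapply(
          pw$db$pathways, function(gs) any(eff$causal_genes %in% gs), logical(1))]
      }
      gp <- pmin(pmax(gene_p_from_y(y), P_FLOOR), 1)
      for (s in weight_schemes) {
        w <- fixed_w[[s]]
        wsum <- pw_w_sum(w)
        var_T <- pmax(2 * wsum + 2 * fixed_rho_sums[[s]], 0.02 * wsum)
        tr <- chisq_inv_sf(gp, w)
        stat <- vapply(gene_idx_in_pw, function(i) sum(tr[i]), numeric(1))
        cc <- 0.5 * var_T / wsum
        vv <- 2 * wsum^2 / var_T
        pvals[[s]][rep_i, ] <- stats::pchisq(stat / cc, df = vv,
                                             lower.tail = FALSE)
      }
    }

    ## --- aggregation ----------------------------------------------------
    rows <- lapply(weight_schemes, function(s) {
      P <- pvals[[s]]
      lam <- inflation_factor(as.vector(P))
      if (null_law) {
        data.frame(scheme = s,
                   type1_error = mean(P < scn$alpha),
                   stringent_power = NA_real_, lenient_power = NA_real_,
                   inflation_factor = lam, stringsAsFactors = FALSE)
      } else {
        hit_central <- vapply(seq_len(replicates), function(i) {
          P[i, match(central[i], names(pw$db$pathways))] < scn$alpha
        }, logical(1))
        hit_lenient <- vapply(seq_len(replicates), function(i) {
          idx <- match(causal_overlap[[i]], names(pw$db$pathways))
          any(P[i, idx] < scn$alpha)
        }, logical(1))
        data.frame(scheme = s, type1_error = NA_real_,
                   stringent_power = mean(hit_central),
                   lenient_power = mean(hit_lenient),
                   inflation_factor = lam, stringsAsFactors = FALSE)
      }
    })
    structure(list(
      results = do.call(rbind, rows),
      replicates = replicates,
      alpha = scn$alpha,
      n_pathways = n_pw,
      effect_law = scn$effect_law,
      power_defined = !null_law,
      pathway_pvalues = if (keep_pvalues) pvals else NULL,
      scenario = scn
    ), class = "scenario_report")
  })
}

# Information-criterion deltas reusing the per-gene orthonormal bases
# precomputed by run_scenario (same quantity as gene_ic_delta()).
gene_ic_delta_fast <- function(y, qx, Qb, rk, criterion = "aic") {
  r <- qr.resid(qx, y)
  rss0 <- sum(r^2)
  n <- length(y)
  pen <- if (criterion == "aic") 2 else log(n)
  vapply(seq_along(Qb), function(g) {
    z <- crossprod(Qb[[g]], r)
    rss1 <- max(rss0 - sum(z^2), rss0 * 1e-12)
    n * log(rss0 / rss1) - pen * rk[g]
  }, numeric(1))
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("Scenario report (%s effect law, %d replicates, %d pathways, alpha = %.3g)\n",
              x$effect_law, x$replicates, x$n_pathways, x$alpha))
  if (!x$power_defined) {
    cat("  null scenario: power undefined; reporting type I error\n")
  }
  print(x$results, row.names = FALSE)
  invisible(x)
}
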