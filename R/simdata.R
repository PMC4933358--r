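# Synthetic-data engine: genotypes with a rare-skewed MAF spectrum and
# blockwise LD, pathway/gene structure, the stochastic hierarchical effect
# model, heritability scaling, and full scenario evaluation (type I error,
# stringent/lenient power, Q-Q inflation factor).

#' Simulation scenario configuration
#'
#' Bundles every knob of the simulation design. The defaults mirror the
#' whole-exome pathway study design: 353 pathways of 10-100
#' genes over 3304 genes and 822 subjects, one central causal pathway with
#' 50% causal genes and 70% causal variants in those genes, 80%/20%
#' detrimental/protective sign assignment at both levels, whole-genome
#' heritability 20%, and a Bonferroni significance level 0.05 / n_pathways.
#'
#' @param scenario 1 (global null, type I error), 2 (effect sizes
#'   proportional to \eqn{|\log_{10} MAF|}) or 3 (effect sizes proportional
#'   to \eqn{1/\sqrt{MAF(1-MAF)}}).
#' @param n_subjects,n_pathways,n_genes cohort and pathway-universe sizes.
#' @param genes_per_pathway integer range of pathway sizes.
#' @param variants_per_gene_mean mean of the (shifted Poisson) per-gene
#'   variant count, minimum 1 variant per gene.
#' @param pathway_overlap target fraction of each pathway's genes shared with
#'   other pathways (see [build_pathways()]).
#' @param causal_gene_fraction,causal_variant_fraction fractions of causal
#'   genes within the central pathway and causal variants within causal genes.
#' @param detrimental_gene_fraction,detrimental_variant_fraction probability
#'   of a positive (detrimental) sign at each level.
#' @param effect_law \code{"null"}, \code{"log10maf"}, \code{"inv_sd_maf"}
#'   (\eqn{1/\sqrt{MAF(1-MAF)}}) or the literal \code{"inv_var_maf"}
#'   (\eqn{1/(MAF(1-MAF))}).
#' @param h2 whole-genome heritability target in (0, 1).
#' @param alpha pathway significance level; default Bonferroni
#'   \code{0.05 / n_pathways}.
#' @param rare_fraction,rare_range,common_range MAF spectrum: a
#'   \code{rare_fraction} share of variants has MAF uniform on
#'   \code{rare_range}, the rest uniform on \code{common_range}.
#' @param ld_block_size,ld_rho LD structure: within-block haplotype copula
#'   correlation \code{ld_rho} over blocks of \code{ld_block_size} variants.
#' @param n_pcs number of genotype principal components entered as
#'   covariates (population-stratification adjustment; the generator is
#'   single-population, so 0 by default).
#' @return Object of class \code{"sim_scenario"}.
#' @export
sim_scenario <- function(scenario = 1,
                         n_subjects = 822,
                         n_pathways = 353,
                         n_genes = 3304,
                         genes_per_pathway = c(10, 100),
                         variants_per_gene_mean = 12.4,
                         pathway_overlap = 0.1,
                         causal_gene_fraction = 0.5,
                         causal_variant_fraction = 0.7,
                         detrimental_gene_fraction = 0.8,
                         detrimental_variant_fraction = 0.8,
                         effect_law = NULL,
                         h2 = 0.2,
                         alpha = 0.05 / n_pathways,
                         rare_fraction = 0.8,
                         rare_range = c(0.001, 0.03),
                         common_range = c(0.03, 0.5),
                         ld_block_size = 10,
                         ld_rho = 0.5,
                         n_pcs = 0) {
  if (is.null(effect_law)) {
    effect_law <- switch(as.character(scenario),
                         "1" = "null", "2" = "log10maf", "3" = "inv_sd_maf",
                         stop("'scenario' must be 1, 2 or 3"))
  }
  effect_law <- match.arg(effect_law,
                          c("null", "log10maf", "inv_sd_maf", "inv_var_maf"))
  stopifnot(
    n_subjects >= 10, n_pathways >= 1, n_genes >= n_pathways,
    causal_gene_fraction >= 0, causal_gene_fraction <= 1,
    causal_variant_fraction >= 0, causal_variant_fraction <= 1,
    detrimental_gene_fraction >= 0, detrimental_gene_fraction <= 1,
    detrimental_variant_fraction >= 0, detrimental_variant_fraction <= 1,
    alpha > 0, alpha < 1,
    pathway_overlap >= 0, pathway_overlap < 1
  )
  if (effect_law != "null" && (h2 <= 0 || h2 >= 1)) {
    stop("'h2' must be in (0, 1) for a non-null effect law")
  }
  structure(as.list(environment()), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario (%s effect law)\n", x$effect_law))
  cat(sprintf("  %d subjects, %d pathways (%d-%d genes), %d genes, h2 = %g\n",
              x$n_subjects, x$n_pathways, x$genes_per_pathway[1],
              x$genes_per_pathway[2], x$n_genes, x$h2))
  cat(sprintf("  alpha = %.4g, causal genes %g%%, causal variants %g%%\n",
              x$alpha, 100 * x$causal_gene_fraction,
              100 * x$causal_variant_fraction))
  invisible(x)
}

#' Simulate genotype dosages with a rare-skewed MAF spectrum and blockwise LD
#'
#' Minor allele frequencies are drawn from a two-component spectrum (by
#' default 80% of variants rare, MAF uniform on (0.001, 0.03), the rest
#' uniform on (0.03, 0.5)). Haplotypes are generated by a blockwise
#' Gaussian-threshold copula: within each block of \code{ld_block_size}
#' consecutive variants the latent normals share correlation \code{ld_rho};
#' an allele is carried when the latent value falls below the MAF quantile.
#' Dosage is the sum of two independent haplotypes.
#'
#' @param n number of subjects.
#' @param n_variants number of variants.
#' @param maf optional fixed per-variant MAF vector in (0, 0.5]; drawn from
#'   the spectrum when NULL.
#' @inheritParams sim_scenario
#' @param seed RNG seed.
#' @return List of class \code{"sim_genotypes"}: integer dosage matrix
#'   \code{G} (n by J, values 0/1/2), the target \code{maf}, and the LD
#'   settings.
#' @export
simulate_genotypes <- function(n, n_variants, maf = NULL,
                               rare_fraction = 0.8,
                               rare_range = c(0.001, 0.03),
                               common_range = c(0.03, 0.5),
                               ld_block_size = 10, ld_rho = 0.5,
                               seed = NULL) {
  if (ld_rho < 0 || ld_rho >= 1) stop("'ld_rho' must lie in [0, 1)")
  if (!is.null(maf) && (any(maf <= 0) || any(maf > 0.5))) {
    stop("'maf' must lie in (0, 0.5]")
  }
  if (any(c(rare_range, common_range) <= 0) ||
      any(c(rare_range, common_range) > 0.5)) {
    stop("MAF spectrum ranges must lie in (0, 0.5]")
  }
  with_seed(seed, {
    J <- n_variants
    if (is.null(maf)) {
      rare <- stats::runif(J) < rare_fraction
      maf <- ifelse(rare,
                    stats::runif(J, rare_range[1], rare_range[2]),
                    stats::runif(J, common_range[1], common_range[2]))
    }
    thr <- stats::qnorm(maf)
    blocks <- split(seq_len(J), ceiling(seq_len(J) / ld_block_size))
    G <- matrix(0L, n, J)
    for (h in 1:2) {
      for (idx in blocks) {
        b <- length(idx)
        z <- sqrt(ld_rho) * stats::rnorm(n) +
          sqrt(1 - ld_rho) * matrix(stats::rnorm(n * b), n, b)
        G[, idx] <- G[, idx] +
          (z < matrix(thr[idx], n, b, byrow = TRUE))
      }
    }
    colnames(G) <- sprintf("v%05d", seq_len(J))
    structure(list(G = G, maf = maf, ld_block_size = ld_block_size,
                   ld_rho = ld_rho),
              class = "sim_genotypes")
  })
}

# Largest-remainder apportionment of `total` into parts proportional to
# `weights`, each part at least 1.
apportion <- function(total, weights) {
  raw <- total * weights / sum(weights)
  out <- pmax(1L, floor(raw))
  rem <- total - sum(out)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    add <- ord[seq_len(rem)]
    out[add] <- out[add] + 1L
  } else if (rem < 0) {
    ord <- order(out, decreasing = TRUE)
    k <- 1L
    while (rem < 0) {
      i <- ord[(k - 1L) %% length(out) + 1L]
      if (out[i] > 1L) { out[i] <- out[i] - 1L; rem <- rem + 1L }
      k <- k + 1L
    }
  }
  out
}

#' Build a synthetic pathway structure and variant-to-gene map
#'
#' Draws pathway sizes uniformly on the configured range, partitions the gene
#' universe into per-pathway cores (largest-remainder apportionment), and
#' fills each pathway up to its target size by borrowing genes from other
#' pathways' cores. Borrowing happens when the gene budget is smaller than the
#' total of the pathway sizes and additionally at the requested
#' \code{overlap} fraction, which creates the overlapping (shared-gene)
#' pathway architecture. With overlap 0 and a gene budget equal to the size
#' total, the pathways exactly partition the gene set.
#'
#' @param n_genes gene universe size.
#' @param n_pathways number of pathways.
#' @param size_range integer range of pathway sizes.
#' @param overlap target shared fraction per pathway in [0, 1).
#' @param variants_per_gene_mean mean per-gene variant count (shifted Poisson,
#'   minimum 1).
#' @param seed RNG seed.
#' @return List: \code{db} (a [pathway_db()]), \code{genes}, \code{sizes},
#'   \code{n_borrowed} per pathway, and \code{variant_map} (data.frame with
#'   columns \code{variant}, \code{gene}).
#' @export
build_pathways <- function(n_genes, n_pathways, size_range = c(10, 100),
                           overlap = 0.1, variants_per_gene_mean = 12.4,
                           seed = NULL) {
  if (n_genes < n_pathways) stop("need at least one gene per pathway")
  if (n_genes > n_pathways * size_range[2]) {
    stop("infeasible sizes: too many genes for the requested pathway count and size range")
  }
  with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_pathways, replace = TRUE)
    if (sum(sizes) < n_genes) {
      sizes <- pmin(size_range[2], pmax(size_range[1],
                    round(sizes * n_genes / sum(sizes))))
      while (sum(sizes) < n_genes) {
        i <- which.min(sizes)
        sizes[i] <- min(size_range[2], sizes[i] + (n_genes - sum(sizes)))
      }
    }
    genes <- sprintf("g%05d", seq_len(n_genes))
    cores_n <- apportion(n_genes, sizes)
    cores_n <- pmin(cores_n, sizes)
    # reassign any slack freed by the cap
    slack <- n_genes - sum(cores_n)
    while (slack > 0) {
      room <- which(cores_n < sizes)
      take <- room[seq_len(min(slack, length(room)))]
      cores_n[take] <- cores_n[take] + 1L
      slack <- n_genes - sum(cores_n)
    }
    shuffled <- sample(genes)
    core <- split(shuffled, rep(seq_len(n_pathways), cores_n))
    members <- core
    n_borrowed <- integer(n_pathways)
    for (k in seq_len(n_pathways)) {
      want <- max(sizes[k] - cores_n[k], round(overlap * sizes[k]))
      want <- min(want, sizes[k] - 1L)
      if (want <= 0) next
      keep_core <- sizes[k] - want
      own <- core[[k]]
      if (keep_core < length(own)) own <- sample(own, keep_core)
      pool <- setdiff(unlist(core[-k], use.names = FALSE), own)
      borrowed <- sample(pool, want)
      members[[k]] <- c(own, borrowed)
      n_borrowed[k] <- want
    }
    names(members) <- sprintf("PW%04d", seq_len(n_pathways))
    nv <- 1L + stats::rpois(n_genes, max(variants_per_gene_mean - 1, 0))
    variant_map <- data.frame(
      variant = sprintf("v%05d", seq_len(sum(nv))),
      gene = rep(genes, nv),
      stringsAsFactors = FALSE
    )
    list(db = pathway_db(members), genes = genes, sizes = sizes,
         n_borrowed = n_borrowed, variant_map = variant_map)
  })
}

#' Assign genetic effects under the stochastic hierarchical model
#'
#' Implements the effect model \eqn{\beta_{pgv} = C_p \times C_g d_g \times
#' C_{gv} d_{gv} \times e_{pgv}}: one central causal pathway, a random
#' fraction of its genes causal, a random fraction of the variants within
#' causal genes causal, gene- and variant-level detrimental/protective signs,
#' and an MAF-driven effect magnitude.
#'
#' @param db a [pathway_db()].
#' @param variant_map data.frame with columns \code{variant}, \code{gene}.
#' @param maf per-variant MAF aligned with \code{variant_map}.
#' @param effect_law see [sim_scenario()].
#' @param causal_gene_fraction,causal_variant_fraction,
#'   detrimental_gene_fraction,detrimental_variant_fraction see
#'   [sim_scenario()].
#' @param central_pathway pathway name; sampled uniformly when NULL.
#' @param seed RNG seed.
#' @return List: per-variant \code{beta} (named), \code{causal_genes},
#'   \code{causal_variants}, \code{central_pathway}.
#' @export
assign_effects <- function(db, variant_map, maf,
                           effect_law = "log10maf",
                           causal_gene_fraction = 0.5,
                           causal_variant_fraction = 0.7,
                           detrimental_gene_fraction = 0.8,
                           detrimental_variant_fraction = 0.8,
                           central_pathway = NULL,
                           seed = NULL) {
  effect_law <- match.arg(effect_law,
                          c("null", "log10maf", "inv_sd_maf", "inv_var_maf"))
  beta <- stats::setNames(numeric(nrow(variant_map)), variant_map$variant)
  if (effect_law == "null") {
    return(list(beta = beta, causal_genes = character(0),
                causal_variants = character(0),
                central_pathway = NA_character_))
  }
  with_seed(seed, {
    if (is.null(central_pathway)) {
      central_pathway <- sample(names(db$pathways), 1)
    }
    pw_genes <- db$pathways[[central_pathway]]
    n_cg <- max(1L, round(causal_gene_fraction * length(pw_genes)))
    causal_genes <- sample(pw_genes, n_cg)
    cand <- variant_map$variant[variant_map$gene %in% causal_genes]
    if (length(cand) == 0L) {
      warning("causal genes carry no variants; resampling causal genes")
      causal_genes <- sample(pw_genes, n_cg)
      cand <- variant_map$variant[variant_map$gene %in% causal_genes]
    }
    n_cv <- max(1L, round(causal_variant_fraction * length(cand)))
    causal_variants <- sample(cand, n_cv)
    d_g <- stats::setNames(
      ifelse(stats::runif(n_cg) < detrimental_gene_fraction, 1, -1),
      causal_genes)
    d_gv <- ifelse(stats::runif(n_cv) < detrimental_variant_fraction, 1, -1)
    vmaf <- stats::setNames(maf, variant_map$variant)[causal_variants]
    mag <- switch(effect_law,
      log10maf   = abs(log10(vmaf)),
      inv_sd_maf = 1 / sqrt(vmaf * (1 - vmaf)),
      inv_var_maf = 1 / (vmaf * (1 - vmaf)))
    vgene <- stats::setNames(variant_map$gene, variant_map$variant)[causal_variants]
    beta[causal_variants] <- d_g[vgene] * d_gv * mag
    list(beta = beta, causal_genes = causal_genes,
         causal_variants = causal_variants,
         central_pathway = central_pathway)
  })
}

#' Noise variance matching a target heritability
#'
#' Solves \eqn{h^2 = Var(X\beta) / (Var(X\beta) + \sigma^2)} for
#' \eqn{\sigma^2}: the phenotype \eqn{y = X\beta + N(0, \sigma^2)} then has
#' the configured heritability in expectation.
#'
#' @param genetic_value the genetic value vector \eqn{X\beta}.
#' @param h2 target heritability in (0, 1).
#' @return The noise variance \eqn{\sigma^2 = Var(X\beta)(1-h^2)/h^2}.
#' @export
scale_noise_to_heritability <- function(genetic_value, h2) {
  if (h2 <= 0 || h2 >= 1) stop("'h2' must be in (0, 1)")
  vg <- stats::var(as.vector(genetic_value))
  if (!is.finite(vg) || vg <= 0) {
    stop("genetic value has zero variance; cannot target a positive heritability")
  }
  vg * (1 - h2) / h2
}

#' Per-gene Lancaster weights
#'
#' Weight functions for the pathway-level combination step:
#' \itemize{
#'   \item \code{"uniform"}: 2 for every gene (Fisher's method).
#'   \item \code{"gene_size"}: \eqn{2\tilde n / n_i} with \eqn{n_i} the
#'     gene's variant count and \eqn{\tilde n} the median count, removing the
#'     bias of large genes.
#'   \item \code{"maf_common"}: \eqn{4 \cdot MAF(1-MAF)} of the gene's mean
#'     MAF (up-weights common variation).
#'   \item \code{"maf_rare"}: \eqn{1 / (MAF(1-MAF))} (up-weights rare
#'     variation).
#'   \item \code{"aic"} / \code{"bic"}: information-criterion improvement of
#'     the gene's multi-SNP regression over the covariate-only null,
#'     floored at \code{floor} and normalised so the median weight is 2
#'     (supply \code{ic_delta}, e.g. from [gene_ic_delta()]).
#' }
#'
#' @param scheme weight scheme name.
#' @param snp_counts per-gene variant counts (gene_size scheme).
#' @param gene_maf per-gene mean MAF (MAF schemes).
#' @param ic_delta per-gene information-criterion improvements (aic/bic).
#' @param n_genes number of genes (uniform scheme when nothing else given).
#' @param floor positive floor applied to information-criterion deltas.
#' @return Positive per-gene weights.
#' @export
gene_weights <- function(scheme = c("uniform", "gene_size", "maf_common",
                                    "maf_rare", "aic", "bic"),
                         snp_counts = NULL, gene_maf = NULL, ic_delta = NULL,
                         n_genes = NULL, floor = 0.1) {
  scheme <- match.arg(scheme)
  switch(scheme,
    uniform = {
      m <- if (!is.null(n_genes)) n_genes
           else if (!is.null(snp_counts)) length(snp_counts)
           else stop("supply 'n_genes' or 'snp_counts' for the uniform scheme")
      rep(2, m)
    },
    gene_size = {
      if (is.null(snp_counts)) stop("'snp_counts' required for gene_size weights")
      if (any(snp_counts < 1)) stop("every gene must have at least one variant")
      2 * stats::median(snp_counts) / snp_counts
    },
    maf_common = {
      if (is.null(gene_maf)) stop("'gene_maf' required")
      4 * gene_maf * (1 - gene_maf)
    },
    maf_rare = {
      if (is.null(gene_maf)) stop("'gene_maf' required")
      if (any(gene_maf == 0)) stop("maf_rare weights undefined at MAF 0")
      1 / (gene_maf * (1 - gene_maf))
    },
    aic = ,
    bic = {
      if (is.null(ic_delta)) stop("'ic_delta' required for aic/bic weights; see gene_ic_delta()")
      d <- pmax(ic_delta, floor)
      2 * d / stats::median(d)
    })
}

#' Information-criterion improvement of per-gene multi-SNP regressions
#'
#' For each gene, compares the covariate-only null regression with the model
#' adding the gene's variants and returns the AIC (or BIC) improvement
#' \eqn{IC_{null} - IC_{full}} (larger = more variation captured by the gene).
#'
#' @param y trait vector.
#' @param G full dosage matrix.
#' @param gene_index named list mapping gene id to variant column indices.
#' @param X covariates (intercept added).
#' @param criterion \code{"aic"} or \code{"bic"}.
#' @return Named per-gene delta vector.
#' @export
gene_ic_delta <- function(y, G, gene_index, X = NULL,
                          criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  fit <- null_model_fit(y, X)
  n <- fit$n
  pen <- if (criterion == "aic") 2 else log(n)
  rss0 <- sum(fit$residuals^2)
  vapply(gene_index, function(idx) {
    A <- qr.resid(fit$qx, as.matrix(G[, idx, drop = FALSE]))
    qa <- qr(A)
    rk <- qa$rank
    if (rk == 0L) return(0)
    z <- qr.qty(qa, fit$residuals)[seq_len(rk)]
    rss1 <- max(rss0 - sum(z^2), rss0 * 1e-12)
    n * log(rss0 / rss1) - pen * rk
  }, numeric(1))
}
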