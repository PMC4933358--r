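# Top-level two-stage pipeline: gene-level SKAT (optional, skipped in
# meta-analysis mode where per-gene p-values are supplied), pathway-level
# self-contained and/or competitive Lancaster, multiplicity control, and a
# reproducibility manifest.

#' Two-stage SKAT-Lancaster pathway test
#'
#' The central fitting function. In full mode, Stage I computes one SKAT
#' p-value per gene from genotype dosages and a continuous trait; in
#' meta-analysis mode, per-gene p-values (e.g. from published summary
#' statistics) are supplied directly and Stage I is skipped. Stage II
#' combines the gene p-values within each pathway by the Lancaster procedure
#' with per-gene weights, using either the independent chi-square null or the
#' Satterthwaite correlation-corrected null with a covariance estimated by
#' phenotype permutation. Optionally a competitive gene-shuffling permutation
#' p-value is added, and pathway p-values are multiplicity-adjusted.
#'
#' @param db a [pathway_db()] (e.g. from [read_gmt()]).
#' @param gene_p named per-gene p-values (meta-analysis mode); NULL to run
#'   Stage I.
#' @param y,G,X,variant_map Stage I inputs: continuous trait, dosage matrix
#'   with variant-id column names, optional covariates, and a data.frame
#'   \code{variant}, \code{gene} mapping variants to genes.
#' @param gene_weight_scheme per-gene Lancaster weight scheme (see
#'   [gene_weights()]) or a named numeric vector of weights.
#' @param variant_weight_scheme Stage I variant weighting (see
#'   [variant_weights_from_maf()]).
#' @param cov_policy \code{"zero"} (independent null), \code{"permutation"}
#'   (phenotype-permutation covariance, full mode only), or a gene-by-gene
#'   covariance matrix with gene-id dimnames.
#' @param cov_B permutation resamples for the covariance estimate.
#' @param competitive also run the competitive permutation test.
#' @param L competitive permutations.
#' @param multiplicity \code{"bonferroni"} or \code{"fdr_bh"}.
#' @param alpha,q multiplicity levels.
#' @param drop_missing if TRUE, pathway genes missing a p-value are dropped
#'   with a message; by default they abort with an error.
#' @param seed RNG seed.
#' @return Object of class \code{"pathway_test"}: per-pathway results
#'   data.frame (\code{pathway}, \code{m_genes}, \code{statistic}, \code{c},
#'   \code{v}, \code{p_value}, \code{p_adjusted}, \code{reject}, optional
#'   \code{competitive_p}), the per-gene table, and a manifest.
#' @examples
#' db <- pathway_db(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' gp <- c(g1 = 0.01, g2 = 0.2, g3 = 0.5)
#' pathway_test(db, gene_p = gp)
#' @export
pathway_test <- function(db,
                         gene_p = NULL,
                         y = NULL, G = NULL, X = NULL, variant_map = NULL,
                         gene_weight_scheme = "uniform",
                         variant_weight_scheme = "beta",
                         cov_policy = "zero",
                         cov_B = 1000,
                         competitive = FALSE,
                         L = 1000,
                         multiplicity = c("bonferroni", "fdr_bh"),
                         alpha = 0.05, q = 0.05,
                         drop_missing = FALSE,
                         seed = NULL) {
  multiplicity <- match.arg(multiplicity)
  stopifnot(inherits(db, "pathway_db"))
  cov_mat <- NULL
  gene_tab <- NULL

  if (is.null(gene_p)) {
    ## ---- Stage I ----
    if (is.null(y) || is.null(G) || is.null(variant_map)) {
      stop("full mode needs 'y', 'G' and 'variant_map' (or supply 'gene_p')")
    }
    G <- as.matrix(G)
    if (is.null(colnames(G))) stop("'G' must carry variant ids as column names")
    bad <- setdiff(variant_map$variant, colnames(G))
    if (length(bad)) stop("variants missing from 'G': ",
                          paste(utils::head(bad, 10), collapse = ", "))
    gene_index <- split(variant_map$variant, variant_map$gene)
    maf <- pmin(colMeans(G) / 2, 0.5)
    gp_runner <- function(yy) {
      vapply(gene_index, function(vs) {
        Gg <- G[, vs, drop = FALSE]
        w <- variant_weights_from_maf(pmin(maf[vs], 0.5), variant_weight_scheme)
        st <- skat_test(yy, Gg, X = X, w = w)
        max(st$p.value, P_FLOOR)
      }, numeric(1))
    }
    gene_p <- gp_runner(y)
    gene_tab <- data.frame(gene = names(gene_index),
                           J_variants = lengths(gene_index),
                           p = unname(gene_p), stringsAsFactors = FALSE)
    if (identical(cov_policy, "permutation")) {
      gw_all <- resolve_gene_weights(gene_weight_scheme, names(gene_p),
                                     gene_index, y, G, X)
      cov_est <- with_seed(seed, estimate_lancaster_covariance(
        function(b) gp_runner(sample(y)), B = cov_B,
        w = gw_all[names(gene_p)]))
      cov_mat <- cov_est$rho
      dimnames(cov_mat) <- list(names(gene_p), names(gene_p))
    }
  } else {
    if (is.null(names(gene_p))) stop("'gene_p' must be named by gene id")
    check_pvalues(gene_p, "gene_p")
    if (identical(cov_policy, "permutation")) {
      stop("permutation covariance needs genotype-level inputs; supply a matrix or use 'zero'")
    }
  }
  if (is.matrix(cov_policy)) {
    cov_mat <- cov_policy
    if (is.null(dimnames(cov_mat))) stop("covariance matrix needs gene-id dimnames")
  }

  missing <- setdiff(db$universe, names(gene_p))
  if (length(missing)) {
    if (!drop_missing) {
      stop("pathway genes without p-values: ",
           paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
    }
    message(sprintf("dropping %d pathway genes without p-values", length(missing)))
    sets <- lapply(db$pathways, setdiff, y = missing)
    sets <- sets[lengths(sets) > 0]
    db <- pathway_db(sets)
  }

  gene_index_w <- if (exists("gene_index", inherits = FALSE)) gene_index else NULL
  gw <- resolve_gene_weights(gene_weight_scheme, names(gene_p), gene_index_w,
                             y, G, X)

  ## ---- Stage II: self-contained ----
  rows <- lapply(names(db$pathways), function(nm) {
    genes <- db$pathways[[nm]]
    p <- gene_p[genes]
    w <- gw[genes]
    covn <- if (is.null(cov_mat)) NULL else
      lancaster_covariance(cov_mat[genes, genes, drop = FALSE])
    res <- correlated_lancaster_test(p, w, cov = covn)
    data.frame(pathway = nm, m_genes = length(genes),
               statistic = res$statistic,
               c = res$parameters$c, v = res$parameters$v,
               p_value = res$p.value, log10_p = res$log10.p,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  adj <- adjust_multiplicity(results$p_value, multiplicity, alpha = alpha, q = q)
  results$p_adjusted <- adj$adjusted
  results$reject <- adj$reject

  if (competitive) {
    comp <- run_competitive(gene_p, gw, db, L = L, cov = cov_mat,
                            seed = if (is.null(seed)) NULL else derive_seed(seed, 1L))
    results$competitive_p <- comp$competitive_p[match(results$pathway, comp$pathway)]
  }

  manifest <- list(
    mode = if (is.null(gene_tab)) "meta-analysis" else "two-stage",
    n_pathways = nrow(results), n_genes = length(gene_p),
    gene_weight_scheme = if (is.character(gene_weight_scheme))
      gene_weight_scheme else "user-supplied",
    cov_policy = if (is.matrix(cov_policy)) "matrix" else cov_policy,
    competitive = competitive, L = if (competitive) L else NA_integer_,
    multiplicity = multiplicity, alpha = alpha, q = q,
    seed = if (is.null(seed)) NA_integer_ else seed,
    package_version = as.character(utils::packageVersion("lancpath")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(results = results, genes = gene_tab, gene_weights = gw,
                 manifest = manifest),
            class = "pathway_test")
}

# Gene weights from a scheme name or a user-supplied named vector.
resolve_gene_weights <- function(scheme, gene_ids, gene_index = NULL,
                                 y = NULL, G = NULL, X = NULL) {
  if (is.numeric(scheme)) {
    if (is.null(names(scheme)) || !all(gene_ids %in% names(scheme))) {
      stop("numeric gene weights must be named and cover every gene")
    }
    return(scheme[gene_ids])
  }
  w <- switch(scheme,
    uniform = gene_weights("uniform", n_genes = length(gene_ids)),
    gene_size = {
      if (is.null(gene_index)) stop("gene_size weights need genotype inputs")
      gene_weights("gene_size", snp_counts = lengths(gene_index)[gene_ids])
    },
    aic = ,
    bic = {
      if (is.null(gene_index) || is.null(y) || is.null(G)) {
        stop("aic/bic weights need genotype-level inputs")
      }
      idx <- lapply(gene_index[gene_ids], function(vs) match(vs, colnames(G)))
      gene_weights(scheme,
                   ic_delta = gene_ic_delta(y, G, idx, X = X, criterion = scheme))
    },
    stop("unknown gene weight scheme: ", scheme))
  stats::setNames(w, gene_ids)
}

#' @export
print.pathway_test <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Two-stage Lancaster pathway test (%s mode)\n", m$mode))
  cat(sprintf("  %d pathways, %d genes; weights: %s; covariance: %s; %s\n",
              m$n_pathways, m$n_genes, m$gene_weight_scheme, m$cov_policy,
              m$multiplicity))
  cat(sprintf("  %d pathway(s) significant\n", sum(x$results$reject)))
  top <- x$results[order(x$results$p_value), ]
  print(utils::head(top, 5), row.names = FALSE)
  if (nrow(top) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
summary.pathway_test <- function(object, ...) {
  object$results[order(object$results$p_value), ]
}

#' Run the pipeline from files
#'
#' File-level wrapper around [pathway_test()]: reads a GMT pathway file plus
#' either a per-gene p-value TSV (meta-analysis mode) or genotype/phenotype
#' TSVs, and writes per-pathway and per-gene result TSVs along with a run
#' manifest.
#'
#' @param gmt path to the GMT pathway definitions.
#' @param gene_p_file per-gene p-value TSV (\code{id}, \code{p}, optional
#'   \code{weight}); mutually exclusive with the genotype inputs.
#' @param genotype_file dosage TSV (header = variant ids, one row per
#'   subject).
#' @param phenotype_file TSV whose first column is the trait; remaining
#'   columns are covariates.
#' @param variant_map_file TSV with columns \code{variant}, \code{gene}.
#' @param out_prefix prefix for output files
#'   (\code{<prefix>_pathways.tsv}, \code{<prefix>_genes.tsv},
#'   \code{<prefix>_manifest.txt}).
#' @param ... further arguments passed to [pathway_test()].
#' @return The [pathway_test()] object, invisibly.
#' @export
run_pipeline <- function(gmt, gene_p_file = NULL,
                         genotype_file = NULL, phenotype_file = NULL,
                         variant_map_file = NULL,
                         out_prefix = "lancpath", ...) {
  db <- read_gmt(gmt)
  if (!is.null(gene_p_file)) {
    tab <- read_pvalue_table(gene_p_file)
    res <- pathway_test(db, gene_p = stats::setNames(tab$p, tab$id),
                        gene_weight_scheme = stats::setNames(tab$weight, tab$id),
                        ...)
  } else {
    if (is.null(genotype_file) || is.null(phenotype_file) ||
        is.null(variant_map_file)) {
      stop("supply either 'gene_p_file' or all of genotype/phenotype/variant map files")
    }
    G <- as.matrix(utils::read.delim(genotype_file, check.names = FALSE))
    ph <- utils::read.delim(phenotype_file)
    vm <- utils::read.delim(variant_map_file, stringsAsFactors = FALSE)
    X <- if (ncol(ph) > 1) as.matrix(ph[, -1, drop = FALSE]) else NULL
    res <- pathway_test(db, y = ph[[1]], G = G, X = X, variant_map = vm, ...)
  }
  utils::write.table(res$results, paste0(out_prefix, "_pathways.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$genes)) {
    utils::write.table(res$genes, paste0(out_prefix, "_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(paste(names(res$manifest),
                   vapply(res$manifest, function(v) paste(format(v), collapse = ","),
                          character(1)),
                   sep = "\t"),
             paste0(out_prefix, "_manifest.txt"))
  invisible(res)
}
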