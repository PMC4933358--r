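# Competitive pathway testing: the self-contained Lancaster p-value of each
# real pathway is ranked against Lancaster p-values of gene sets of the same
# size drawn from the pathway universe ("shuffling genes among pathways").

#' Pathway database
#'
#' A named collection of gene sets and the universe of genes they cover.
#'
#' @param pathways named list of character vectors of gene ids.
#' @param universe optional gene universe; defaults to the union of all
#'   pathway members and must contain it.
#' @return Object of class \code{"pathway_db"}.
#' @export
pathway_db <- function(pathways, universe = NULL) {
  if (length(pathways) == 0L) stop("no pathways supplied")
  if (is.null(names(pathways)) || anyDuplicated(names(pathways)) ||
      any(names(pathways) == "")) {
    stop("pathways must have unique non-empty names")
  }
  if (any(lengths(pathways) == 0L)) {
    empty <- names(pathways)[lengths(pathways) == 0L]
    stop("empty pathway(s): ", paste(utils::head(empty, 5), collapse = ", "))
  }
  pathways <- lapply(pathways, as.character)
  members <- unique(unlist(pathways, use.names = FALSE))
  if (is.null(universe)) universe <- members
  if (!all(members %in% universe)) stop("pathway genes outside the supplied universe")
  structure(list(pathways = pathways, universe = universe),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("Pathway database: %d pathways, %d genes (sizes %d-%d)\n",
              length(x$pathways), length(x$universe),
              min(lengths(x$pathways)), max(lengths(x$pathways))))
  invisible(x)
}

#' Permuted gene sets matching real pathway sizes
#'
#' For each real pathway, draws \code{L} gene sets of exactly the same size
#' (sampling without replacement from the universe), the permutation null of
#' the competitive test. Sets are drawn independently per pathway.
#'
#' @param db a [pathway_db()].
#' @param L number of permuted sets per pathway.
#' @param seed RNG seed; results are reproducible given the seed.
#' @return Named list (one element per pathway) of size-by-L character
#'   matrices of gene ids.
#' @export
permute_pathways <- function(db, L, seed = NULL) {
  if (L < 1) stop("'L' must be at least 1")
  u <- db$universe
  with_seed(seed, {
    lapply(db$pathways, function(genes) {
      s <- length(genes)
      if (s > length(u)) stop("pathway larger than the gene universe")
      matrix(vapply(seq_len(L), function(l) sample(u, s), character(s)),
             nrow = s)
    })
  })
}

#' Competitive permutation p-value
#'
#' The fraction of permuted gene sets whose self-contained p-value is at most
#' the observed one: \eqn{\sum_l I\{P_i \ge P^l\} / L}. The plain estimator
#' can return 0; set \code{add_one = TRUE} for the (1 + count)/(1 + L)
#' correction (useful before FDR control downstream).
#'
#' @param observed_p the real pathway's self-contained p-value.
#' @param permuted_p vector of permuted-set p-values.
#' @param add_one apply the add-one correction (default off, matching the
#'   plain estimator).
#' @return Value in [0, 1].
#' @export
competitive_pvalue <- function(observed_p, permuted_p, add_one = FALSE) {
  if (length(permuted_p) == 0L) stop("no permuted p-values supplied")
  if (any(c(observed_p, permuted_p) < 0) || any(c(observed_p, permuted_p) > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  hits <- sum(observed_p >= permuted_p)
  if (add_one) (1 + hits) / (1 + length(permuted_p)) else hits / length(permuted_p)
}

#' Competitive Lancaster test over a pathway database
#'
#' Step 1 computes the (independent or correlation-corrected) Lancaster
#' p-value of each real pathway from per-gene p-values; step 2 evaluates the
#' same statistic on \code{L} size-matched gene sets shuffled from the
#' universe; step 3 reports the fraction of permuted sets at least as
#' significant. Gene weights travel with the gene: a gene keeps its own
#' weight wherever it is shuffled.
#'
#' @param gene_p named vector of per-gene p-values covering every pathway
#'   gene.
#' @param gene_w named per-gene Lancaster weights (default 2 for all).
#' @param db a [pathway_db()].
#' @param L permutations per pathway (at least 100).
#' @param cov optional gene-by-gene covariance matrix (dimnames = gene ids)
#'   of the transformed statistics; when supplied, the Satterthwaite
#'   correction is applied to the real and (by default) the permuted sets.
#' @param correct_permuted apply the covariance correction inside permuted
#'   sets too (default TRUE: the same test is used on both).
#' @param add_one see [competitive_pvalue()].
#' @param seed RNG seed.
#' @return data.frame ordered by pathway id: \code{pathway}, \code{m_genes},
#'   \code{self_contained_p}, \code{competitive_p}, \code{L}.
#' @export
run_competitive <- function(gene_p, gene_w = NULL, db, L = 1000,
                            cov = NULL, correct_permuted = TRUE,
                            add_one = FALSE, seed = NULL) {
  if (L < 100) stop("'L' must be at least 100")
  if (is.null(names(gene_p))) stop("'gene_p' must be named by gene id")
  missing <- setdiff(db$universe, names(gene_p))
  if (length(missing)) {
    stop("genes missing p-values: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  }
  check_pvalues(gene_p, "gene_p")
  if (is.null(gene_w)) gene_w <- stats::setNames(rep(2, length(gene_p)), names(gene_p))
  if (is.null(names(gene_w)) || !all(db$universe %in% names(gene_w))) {
    stop("'gene_w' must be named and cover every pathway gene")
  }
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (is.null(dimnames(cov)) || !all(db$universe %in% rownames(cov))) {
      stop("'cov' must carry gene ids as dimnames covering the universe")
    }
  }
  # Transformed statistics are gene properties: precompute once.
  tr <- stats::setNames(chisq_inv_sf(gene_p[db$universe], gene_w[db$universe]),
                        db$universe)
  pw_p <- function(genes) {
    w <- gene_w[genes]
    stat <- sum(tr[genes])
    if (is.null(cov)) {
      stats::pchisq(stat, df = sum(w), lower.tail = FALSE)
    } else {
      rsub <- cov[genes, genes, drop = FALSE]
      off <- sum(rsub[upper.tri(rsub)])
      var_T <- max(2 * sum(w) + 2 * off, 0.02 * sum(w))
      sw <- satterthwaite_params(sum(w), var_T)
      stats::pchisq(stat / sw$c, df = sw$v, lower.tail = FALSE)
    }
  }
  perm_p <- function(genes_mat) {
    if (!is.null(cov) && correct_permuted) {
      apply(genes_mat, 2, pw_p)
    } else {
      w <- matrix(gene_w[genes_mat], nrow = nrow(genes_mat))
      stats::pchisq(colSums(matrix(tr[genes_mat], nrow = nrow(genes_mat))),
                    df = colSums(w), lower.tail = FALSE)
    }
  }
  perms <- permute_pathways(db, L, seed = seed)
  ord <- order(names(db$pathways))
  rows <- lapply(names(db$pathways)[ord], function(nm) {
    genes <- db$pathways[[nm]]
    p_self <- pw_p(genes)
    p_perm <- perm_p(perms[[nm]])
    data.frame(pathway = nm, m_genes = length(genes),
               self_contained_p = p_self,
               competitive_p = competitive_pvalue(p_self, p_perm,
                                                  add_one = add_one),
               L = L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
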