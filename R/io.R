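# File-format adapters and multiplicity control.

#' Read a GMT gene-set file
#'
#' One pathway per tab-separated line: name, description, then gene ids.
#' Duplicate genes within a line are removed with a warning.
#'
#' @param path file path.
#' @return A [pathway_db()]; descriptions are kept in the
#'   \code{"descriptions"} attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L) {
      stop(sprintf("malformed GMT line %d: need name, description and at least one gene", i))
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes in pathway '%s' (line %d) removed", f[1], i))
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  db <- pathway_db(sets)
  attr(db, "descriptions") <- desc
  db
}

#' Write a pathway database in GMT format
#'
#' @param db a [pathway_db()].
#' @param path output file.
#' @param descriptions optional named description strings (default "na").
#' @export
write_gmt <- function(db, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(db, "descriptions")
  lines <- vapply(names(db$pathways), function(nm) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[nm])) descriptions[nm] else "na"
    paste(c(nm, d, db$pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-test p-value table
#'
#' Tab-separated with columns \code{id}, \code{p} and optional \code{weight};
#' a missing weight column gets the uniform chi-square weight 2.
#'
#' @param path file path.
#' @return data.frame with columns \code{id}, \code{p}, \code{weight}.
#' @export
read_pvalue_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "p") %in% names(tab))) {
    stop("p-value table needs columns 'id' and 'p'")
  }
  if (anyDuplicated(tab$id)) stop("duplicate ids in p-value table")
  check_pvalues(tab$p)
  if (is.null(tab$weight)) tab$weight <- 2
  if (any(tab$weight <= 0)) stop("weights must be > 0")
  tab[, c("id", "p", "weight")]
}

#' Multiple-testing adjustment
#'
#' \code{"bonferroni"} controls the family-wise error rate: reject when
#' \eqn{p < \alpha / m}. \code{"fdr_bh"} is the Benjamini-Hochberg step-up
#' procedure: reject when the BH-adjusted p-value is at most \code{q}.
#'
#' @param p p-values in [0, 1].
#' @param policy \code{"bonferroni"} or \code{"fdr_bh"}.
#' @param alpha family-wise level (Bonferroni).
#' @param q FDR level (BH).
#' @return List: \code{adjusted} p-values, logical \code{reject}, and the
#'   Bonferroni \code{threshold} (NA under BH).
#' @examples
#' adjust_multiplicity(rep(0.001, 353), "bonferroni")$threshold # 0.05/353
#' @export
adjust_multiplicity <- function(p, policy = c("bonferroni", "fdr_bh"),
                                alpha = 0.05, q = 0.05) {
  policy <- match.arg(policy)
  if (length(p) == 0L) stop("no p-values supplied")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (policy == "bonferroni") {
    thr <- alpha / m
    list(adjusted = pmin(p * m, 1), reject = p < thr, threshold = thr)
  } else {
    if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
    adj <- stats::p.adjust(p, method = "BH")
    list(adjusted = adj, reject = adj <= q, threshold = NA_real_)
  }
}
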