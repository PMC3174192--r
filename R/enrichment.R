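#' Construct a term -> gene annotation map
#'
#' @param terms named list; each element a character vector of genes (or a
#'   list with \code{genes} and \code{description}).
#' @param descriptions optional named character vector of term descriptions.
#' @return object of class \code{"annotation_map"}.
#' @export
annotation_map <- function(terms, descriptions = NULL) {
  if (length(terms) == 0) stop_bt("annotation map has no terms")
  if (is.null(names(terms)) || any(!nzchar(names(terms))))
    stop_bt("terms must be named")
  genes <- lapply(terms, function(t) {
    g <- if (is.list(t)) t$genes else t
    sort(unique(normalize_genes(g)))
  })
  empty <- names(genes)[vapply(genes, length, 0L) == 0]
  if (length(empty) > 0)
    stop_bt("term(s) with no genes: %s", paste(empty, collapse = ", "))
  desc <- descriptions %||%
    vapply(terms, function(t) (if (is.list(t)) t$description else NULL) %||% "na", "")
  structure(list(genes = genes,
                 descriptions = stats::setNames(as.character(desc), names(genes))),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d terms, %d distinct genes\n",
              length(x$genes), length(unique(unlist(x$genes)))))
  invisible(x)
}

#' Read an annotation map from GMT
#'
#' @param path GMT file path.
#' @return an [annotation_map()].
#' @export
read_annotation_gmt <- function(path) {
  sets <- read_gmt(path)
  annotation_map(lapply(sets, function(s) s$members),
                 descriptions = vapply(sets, function(s)
                   attr(s, "description") %||% "na", ""))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted values (monotonicity enforced); input order is
#' preserved in the output.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_bt("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Pathway ratio statistic
#'
#' The number of target genes mapping to a term divided by the total number
#' of genes mapping to that term.
#'
#' @param n_hit integer, target genes in the term.
#' @param n_term integer > 0, all genes in the term.
#' @return numeric ratio in [0, 1].
#' @export
pathway_ratio <- function(n_hit, n_term) {
  if (any(n_term <= 0)) stop_bt("term size must be positive")
  if (any(n_hit < 0 | n_hit > n_term)) stop_bt("need 0 <= n_hit <= n_term")
  n_hit / n_term
}

#' Term over-representation by Fisher's exact test
#'
#' One result per annotation term intersecting the gene universe (the
#' background set). The p-value is the right tail of the hypergeometric
#' distribution including the observed table, i.e. a one-sided
#' over-representation Fisher exact test; the ratio is target hits over the
#' term's universe-restricted size. Genes without any annotation remain in
#' the universe. Significance at \code{alpha} is applied to BH-adjusted q
#' (default) or to raw p with \code{correction = "none"}.
#'
#' @param target a [gene_set()] or character vector, subset of the background.
#' @param background a [gene_set()] or character vector: the gene universe.
#' @param annotations an [annotation_map()].
#' @param alpha significance threshold (default 0.01).
#' @param correction \code{"BH"} (default) or \code{"none"}.
#' @return data.frame of class \code{"enrichment_result"}, sorted by
#'   ascending p: term, description, a/b/c/d of the 2x2 table, term_size
#'   (in universe), ratio, p, q, significant.
#' @export
fisher_enrich <- function(target, background, annotations,
                          alpha = 0.01, correction = c("BH", "none")) {
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) stop_bt("alpha must lie in (0, 1)")
  if (!inherits(annotations, "annotation_map"))
    stop_bt("annotations must be an annotation_map")
  tgt <- as_members(target)
  uni <- as_members(background)
  outside <- setdiff(tgt, uni)
  if (length(outside) > 0)
    stop_bt("target gene(s) outside the background universe: %s",
            paste(outside, collapse = ", "))
  N <- length(uni)
  n <- length(tgt)
  rows <- lapply(names(annotations$genes), function(tm) {
    term_genes <- intersect(annotations$genes[[tm]], uni)
    K <- length(term_genes)
    if (K == 0) return(NULL)
    a <- length(intersect(term_genes, tgt))
    # right tail including the observed table
    p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, description = annotations$descriptions[[tm]],
               a = a, b = n - a, c = K - a, d = N - K - (n - a),
               term_size = K, ratio = pathway_ratio(a, K), p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stop_bt("no annotation term intersects the universe")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- if (correction == "BH") out$q < alpha else out$p < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  attr(out, "terms_signature") <- terms_signature(names(annotations$genes))
  out
}

#' Compare two enrichment runs over the same annotation map
#'
#' Classifies significant terms from an all-genes run and a
#' restricted-subset run into shared, subset-only and all-only -- the
#' pattern used to flag pathways that only surface once low-expression
#' genes are removed.
#'
#' @param results_all,results_subset [fisher_enrich()] results computed over
#'   the same annotation map (enforced via a stored term signature).
#' @return list with \code{shared_terms}, \code{subset_only_terms},
#'   \code{all_only_terms} (sorted character vectors).
#' @export
compare_enrichments <- function(results_all, results_subset) {
  sa <- attr(results_all, "terms_signature")
  sb <- attr(results_subset, "terms_signature")
  if (is.null(sa) || is.null(sb) || !identical(sa, sb))
    stop_bt("enrichment results come from different annotation maps")
  siga <- results_all$term[results_all$significant]
  sigb <- results_subset$term[results_subset$significant]
  list(shared_terms = sort(intersect(siga, sigb)),
       subset_only_terms = sort(setdiff(sigb, siga)),
       all_only_terms = sort(setdiff(siga, sigb)))
}

#' Write an enrichment result table
#'
#' @param results a [fisher_enrich()] result.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
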