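#' Venn counts over two or three gene sets
#'
#' Exact membership counts for every Venn region (3 regions for two sets,
#' 7 for three), with retrievable member lists. Counts satisfy the
#' inclusion-exclusion identity by construction.
#'
#' @param sets list of two or three [gene_set()] objects (or character
#'   vectors); names are taken from the sets.
#' @return object of class \code{"venn_counts"}: \code{sizes} (per set),
#'   \code{pairwise} (named intersection sizes), \code{triple} (for three
#'   sets), \code{regions} (named list of exclusive-region member vectors),
#'   \code{union_size}.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2 || length(sets) > 3)
    stop_bt("venn_counts needs two or three gene sets")
  nm <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "gene_set")) s$name else names(sets)[i] %||% paste0("S", i)
  }, "")
  if (anyDuplicated(nm)) stop_bt("set names must be distinct")
  mem <- lapply(sets, as_members)
  names(mem) <- nm
  k <- length(mem)
  universe <- sort(unique(unlist(mem)))
  inmat <- vapply(mem, function(m) universe %in% m, logical(length(universe)))
  if (length(universe) == 1) inmat <- matrix(inmat, nrow = 1, dimnames = list(NULL, nm))
  pattern <- apply(inmat, 1, function(z) paste(ifelse(z, "1", "0"), collapse = ""))
  regions <- list()
  for (p in sort(unique(pattern))) {
    inset <- nm[strsplit(p, "")[[1]] == "1"]
    regions[[paste(inset, collapse = "&")]] <- universe[pattern == p]
  }
  pair_idx <- utils::combn(k, 2)
  pairwise <- apply(pair_idx, 2, function(ij)
    length(intersect(mem[[ij[1]]], mem[[ij[2]]])))
  names(pairwise) <- apply(pair_idx, 2, function(ij)
    paste(nm[ij], collapse = "&"))
  structure(list(
    sizes = vapply(mem, length, 0L),
    pairwise = pairwise,
    triple = if (k == 3) length(Reduce(intersect, mem)) else NULL,
    regions = regions,
    union_size = length(universe)),
    class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("venn_counts\n  sizes:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "), "\n")
  cat("  pairwise:",
      paste(sprintf("%s=%d", names(x$pairwise), x$pairwise), collapse = ", "), "\n")
  if (!is.null(x$triple)) cat("  triple:", x$triple, "\n")
  cat("  union:", x$union_size, "\n")
  invisible(x)
}

# genes of the set highly expressed per the assignments, as a named matrix
# gene x region of the highly_expressed flag
high_flag_matrix <- function(geneset, assignments) {
  genes <- as_members(geneset)
  missing <- setdiff(genes, unique(assignments$gene))
  if (length(missing) > 0)
    stop_bt("assignments do not cover: %s", paste(missing, collapse = ", "))
  a <- assignments[assignments$gene %in% genes, , drop = FALSE]
  regions <- unique(a$region)
  m <- matrix(FALSE, length(genes), length(regions),
              dimnames = list(genes, regions))
  m[cbind(match(a$gene, genes), match(a$region, regions))] <- a$highly_expressed
  m
}

#' Highly expressed members of a gene set
#'
#' Members highly expressed (per-region max RPKM at or above the high
#' threshold) in at least one region.
#'
#' @param geneset a [gene_set()] or character vector.
#' @param assignments a [assign_region_tiers()] result covering the set.
#' @return a [gene_set()] named \code{"<name>_high"} (may error if empty --
#'   use \code{allow_empty}).
#' @param allow_empty if TRUE, an empty result is returned as a character
#'   vector of length zero instead of an error.
#' @export
highly_expressed_subset <- function(geneset, assignments, allow_empty = FALSE) {
  m <- high_flag_matrix(geneset, assignments)
  hits <- rownames(m)[rowSums(m) > 0]
  nm <- if (inherits(geneset, "gene_set")) paste0(geneset$name, "_high") else "high"
  if (length(hits) == 0) {
    if (allow_empty) return(character(0))
    stop_bt("no member of the set is highly expressed in any region")
  }
  gene_set(nm, hits)
}

#' Pan-region highly expressed members
#'
#' Members highly expressed in every region of the assignments (all 11
#' canonical regions in the standard analysis).
#'
#' @inheritParams highly_expressed_subset
#' @param regions regions that must all be present; defaults to the regions
#'   in the assignments. Missing regions are an error naming them.
#' @return character vector of pan-region highly expressed members (sorted).
#' @export
pan_region_high <- function(geneset, assignments,
                            regions = unique(assignments$region)) {
  missing <- setdiff(regions, unique(assignments$region))
  if (length(missing) > 0)
    stop_bt("assignments missing region(s): %s", paste(missing, collapse = ", "))
  m <- high_flag_matrix(geneset, assignments)[, regions, drop = FALSE]
  sort(rownames(m)[rowSums(m) == length(regions)])
}

#' Region-unique highly expressed members
#'
#' Members highly expressed in the given region and in no other region of
#' the assignments.
#'
#' @inheritParams highly_expressed_subset
#' @param region a single region code present in the assignments.
#' @return character vector of members unique to \code{region} (sorted).
#' @export
region_unique_high <- function(geneset, assignments, region) {
  if (!region %in% unique(assignments$region))
    stop_bt("unknown region: %s", region)
  m <- high_flag_matrix(geneset, assignments)
  other <- setdiff(colnames(m), region)
  sort(rownames(m)[m[, region] & rowSums(m[, other, drop = FALSE]) == 0])
}

#' Overlap fraction between two gene sets
#'
#' Reports |query intersect reference| / |query| with the compact percent
#' formatting of the source tables (integer percent unless a truncated
#' decimal is non-zero: 4/130 -> "3\%", 21/444 -> "4.7\%").
#'
#' @param query a [gene_set()] or character vector (the denominator).
#' @param reference a [gene_set()] or character vector.
#' @return object of class \code{"overlap_fraction"}: \code{n_overlap},
#'   \code{n_total}, \code{fraction}, \code{percent_text}, \code{members}.
#' @export
overlap_fraction <- function(query, reference) {
  q <- as_members(query)
  if (length(q) == 0) stop_bt("empty query set")
  r <- as_members(reference)
  ov <- intersect(q, r)
  structure(list(n_overlap = length(ov), n_total = length(q),
                 fraction = length(ov) / length(q),
                 percent_text = format_percent_short(length(ov) / length(q)),
                 members = sort(ov)),
            class = "overlap_fraction")
}

#' @export
print.overlap_fraction <- function(x, ...) {
  cat(sprintf("%d/%d (%s)\n", x$n_overlap, x$n_total, x$percent_text))
  invisible(x)
}

#' @export
format.overlap_fraction <- function(x, ...) {
  sprintf("%d/%d (%s)", x$n_overlap, x$n_total, x$percent_text)
}
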