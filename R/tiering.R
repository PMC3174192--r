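#' Quintile tier scheme
#'
#' Expression tiers are half-open, left-closed RPKM bins. The defaults give
#' five tiers [0,20), [20,40), [40,60), [60,100), [100,Inf): genes are
#' "detected" at 1 RPKM and "highly expressed" at 60 RPKM (the top-three-tier
#' criterion). Under normal biological variance, calibrated on constantly
#' expressed housekeeping genes, per-sample tiers stay within
#' \code{span_limit} consecutive tiers; a wider span flags qualitative
#' differential expression.
#'
#' @param boundaries strictly increasing RPKM thresholds.
#' @param detection_threshold RPKM below which a gene is not detected.
#' @param high_threshold RPKM at or above which (for at least one time point)
#'   a gene counts as highly expressed; must be one of the boundaries.
#' @param span_limit maximum number of consecutive tiers attributable to
#'   normal variance.
#' @return object of class \code{"tier_scheme"}.
#' @examples
#' tier_scheme()
#' @export
tier_scheme <- function(boundaries = c(20, 40, 60, 100),
                        detection_threshold = 1,
                        high_threshold = 60,
                        span_limit = 3) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 1 || is.unsorted(boundaries, strictly = TRUE))
    stop_bt("tier boundaries must be strictly increasing")
  if (detection_threshold >= boundaries[1])
    stop_bt("detection threshold must lie below the first tier boundary")
  if (!high_threshold %in% boundaries)
    stop_bt("high threshold must be one of the tier boundaries")
  structure(list(boundaries = boundaries,
                 n_tiers = length(boundaries) + 1L,
                 detection_threshold = detection_threshold,
                 high_threshold = high_threshold,
                 span_limit = as.integer(span_limit)),
            class = "tier_scheme")
}

#' @export
print.tier_scheme <- function(x, ...) {
  lo <- c(0, x$boundaries)
  hi <- c(x$boundaries, Inf)
  cat(sprintf("tier_scheme: %d tiers %s; detected >= %g, high >= %g, span limit %d\n",
              x$n_tiers,
              paste(sprintf("[%g,%g)", lo, hi), collapse = " "),
              x$detection_threshold, x$high_threshold, x$span_limit))
  invisible(x)
}

#' Map RPKM values to tier indices
#'
#' Left-closed binning: a value exactly on a boundary belongs to the upper
#' tier (20 RPKM is tier 2, 60 is tier 4, 100 is tier 5).
#'
#' @param value numeric vector of non-negative RPKM values.
#' @param scheme a [tier_scheme()].
#' @return integer vector of 1-based tier indices.
#' @examples
#' rpkm_to_tier(c(0, 19.99, 20, 150))
#' @export
rpkm_to_tier <- function(value, scheme = tier_scheme()) {
  if (any(value < 0)) stop_bt("RPKM values must be non-negative")
  findInterval(value, scheme$boundaries) + 1L
}

#' Assign per-region expression tiers
#'
#' For every (gene, region) pair the tier is determined by the gene's
#' highest RPKM across that region's time points; a gene at 150 RPKM at one
#' time point and 80 at all others lands in the top tier. Detection and
#' highly-expressed flags use the same per-region maximum.
#'
#' @param atlas an [expression_atlas()], already filtered to the analysis ages.
#' @param scheme a [tier_scheme()].
#' @return data.frame of class \code{"tier_assignment"}: one row per
#'   gene x region with \code{tier}, \code{max_rpkm}, \code{detected},
#'   \code{highly_expressed}.
#' @export
assign_region_tiers <- function(atlas, scheme = tier_scheme()) {
  regions <- atlas_regions(atlas)
  per_region <- lapply(regions, function(r) {
    cols <- atlas$samples$region == r
    if (!any(cols)) stop_bt("region %s has no time points", r)
    mx <- apply(atlas$values[, cols, drop = FALSE], 1, max)
    data.frame(gene = atlas$genes, region = r,
               tier = rpkm_to_tier(mx, scheme), max_rpkm = unname(mx),
               detected = unname(mx >= scheme$detection_threshold),
               highly_expressed = unname(mx >= scheme$high_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_region)
  rownames(out) <- NULL
  class(out) <- c("tier_assignment", "data.frame")
  attr(out, "scheme") <- scheme
  out
}

#' Tier-span report
#'
#' Computes per-sample tiers on individual RPKM values (not per-region
#' maxima) and reports, per gene, the min tier, max tier and span over the
#' chosen scope. A span exceeding the scheme's limit flags the gene as
#' qualitatively differentially expressed.
#'
#' @param atlas an [expression_atlas()].
#' @param genes gene identifiers to report (default: all atlas genes).
#' @param scope \code{"global"} (all retained samples, the default used for
#'   housekeeping calibration) or \code{"per_region"}.
#' @param scheme a [tier_scheme()].
#' @return data.frame with \code{gene} (and \code{region} for per-region
#'   scope), \code{min_tier}, \code{max_tier}, \code{span},
#'   \code{differential}.
#' @export
span_report <- function(atlas, genes = atlas$genes,
                        scope = c("global", "per_region"),
                        scheme = tier_scheme()) {
  scope <- match.arg(scope)
  genes <- normalize_genes(genes)
  missing <- setdiff(genes, atlas$genes)
  if (length(missing) > 0)
    stop_bt("gene(s) not in atlas: %s", paste(missing, collapse = ", "))
  v <- atlas$values[genes, , drop = FALSE]
  tiers <- matrix(rpkm_to_tier(v, scheme), nrow = nrow(v))
  one <- function(tt, gene, region = NULL) {
    mn <- min(tt); mx <- max(tt)
    d <- data.frame(gene = gene, min_tier = mn, max_tier = mx,
                    span = mx - mn + 1L,
                    differential = (mx - mn + 1L) > scheme$span_limit,
                    stringsAsFactors = FALSE)
    if (!is.null(region)) d <- cbind(data.frame(region = region), d)
    d
  }
  if (scope == "global") {
    out <- do.call(rbind, lapply(seq_along(genes), function(i)
      one(tiers[i, ], genes[i])))
  } else {
    regions <- atlas_regions(atlas)
    out <- do.call(rbind, unlist(lapply(seq_along(genes), function(i) {
      lapply(regions, function(r)
        one(tiers[i, atlas$samples$region == r], genes[i], r))
    }), recursive = FALSE))
    out <- out[, c("gene", "region", "min_tier", "max_tier", "span", "differential")]
  }
  rownames(out) <- NULL
  out
}

#' Housekeeping variance calibration
#'
#' Checks that a set of constantly expressed housekeeping genes stays within
#' the scheme's tier-span limit across all retained samples. The calibration
#' passes when every housekeeping gene spans at most \code{span_limit}
#' consecutive tiers; offending genes are listed for manual exclusion.
#'
#' @param atlas an [expression_atlas()].
#' @param housekeeping a [gene_set()] (or character vector) of housekeeping
#'   genes, all present in the atlas.
#' @param scheme a [tier_scheme()].
#' @return list with \code{spans} (the [span_report()] rows),
#'   \code{n_within_limit}, \code{offending} (character) and \code{passed}.
#' @export
housekeeping_calibration <- function(atlas, housekeeping,
                                     scheme = tier_scheme()) {
  hk <- as_members(housekeeping)
  if (length(hk) == 0) stop_bt("housekeeping set is empty")
  spans <- span_report(atlas, genes = hk, scope = "global", scheme = scheme)
  offending <- spans$gene[spans$differential]
  list(spans = spans,
       n_within_limit = sum(!spans$differential),
       offending = offending,
       passed = length(offending) == 0)
}

#' Export a tier heatmap table
#'
#' Writes a genes x regions table of tier indices as TSV: deterministic row
#' order (input order of the assignments) and canonical region column order.
#'
#' @param assignments a [assign_region_tiers()] result.
#' @param path output TSV path.
#' @return the tier matrix (genes x regions data.frame), invisibly.
#' @export
export_heatmap <- function(assignments, path) {
  genes <- unique(assignments$gene)
  regions <- unique(assignments$region)
  regions <- regions[order(region_rank(regions))]
  wide <- matrix(NA_integer_, length(genes), length(regions),
                 dimnames = list(genes, regions))
  wide[cbind(match(assignments$gene, genes),
             match(assignments$region, regions))] <- assignments$tier
  df <- data.frame(gene = genes, wide, check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a tier heatmap table written by [export_heatmap()]
#'
#' @param path TSV path.
#' @return data.frame with \code{gene} then one integer column per region.
#' @export
read_heatmap <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Export per-sample tiers
#'
#' The per-sample companion of [export_heatmap()]: tiers of individual RPKM
#' values for every (gene, sample).
#'
#' @param atlas an [expression_atlas()].
#' @param path output TSV path.
#' @param scheme a [tier_scheme()].
#' @return the written data.frame, invisibly.
#' @export
export_sample_tiers <- function(atlas, path, scheme = tier_scheme()) {
  tiers <- matrix(rpkm_to_tier(atlas$values, scheme), nrow = nrow(atlas$values),
                  dimnames = dimnames(atlas$values))
  df <- data.frame(gene = atlas$genes, tiers, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Per-region expression summary of a gene set
#'
#' For each region: the share of the gene set never exceeding the first
#' tier boundary (max < 20 RPKM), the share highly expressed (top three
#' tiers), and the number/share with no detectable transcript (max < 1
#' RPKM). Percentages are 100 x count / set size, reported at one decimal
#' (half-up); raw counts are included.
#'
#' @param geneset a [gene_set()] (or character vector), covered by the
#'   assignments.
#' @param assignments a [assign_region_tiers()] result.
#' @return data.frame, one row per region, with counts and percentages.
#' @export
summarize_region <- function(geneset, assignments) {
  genes <- as_members(geneset)
  if (length(genes) == 0) stop_bt("empty gene set")
  missing <- setdiff(genes, unique(assignments$gene))
  if (length(missing) > 0)
    stop_bt("gene(s) without tier assignment: %s", paste(missing, collapse = ", "))
  a <- assignments[assignments$gene %in% genes, , drop = FALSE]
  n <- length(genes)
  regions <- unique(a$region)
  regions <- regions[order(region_rank(regions))]
  rows <- lapply(regions, function(r) {
    ar <- a[a$region == r, , drop = FALSE]
    n_below <- sum(ar$tier == 1L)
    n_high <- sum(ar$highly_expressed)
    n_nd <- sum(!ar$detected)
    data.frame(region = r, n_genes = n,
               n_below_20 = n_below,
               pct_below_20 = round_half_up(100 * n_below / n, 1),
               n_mid = n - n_below - n_high,
               pct_mid = round_half_up(100 * (n - n_below - n_high) / n, 1),
               n_highly_expressed = n_high,
               pct_highly_expressed = round_half_up(100 * n_high / n, 1),
               n_not_detected = n_nd,
               pct_not_detected = round_half_up(100 * n_nd / n, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
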