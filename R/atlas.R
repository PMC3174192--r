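#' Construct an expression atlas
#'
#' A genes x samples matrix of RPKM values where every sample is a
#' (brain region, developmental age) pair. Values must be non-negative,
#' gene identifiers unique, and (region, age) sample keys unique. Samples
#' are stored sorted by (region, developmental age).
#'
#' @param values numeric matrix, genes in rows; rownames are gene symbols.
#' @param regions character vector, one region code per column of \code{values}.
#' @param ages character vector of age labels (see [parse_age()]), one per column.
#' @return an object of class \code{"expression_atlas"}: a list with
#'   \code{values} (matrix), \code{samples} (data.frame of region/age metadata)
#'   and \code{genes}.
#' @examples
#' m <- matrix(c(10, 0, 20, 5), 2, dimnames = list(c("A", "B"), NULL))
#' expression_atlas(m, regions = c("Hipp", "Hipp"), ages = c("24wg", "1y"))
#' @export
expression_atlas <- function(values, regions, ages) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_bt("values must be a numeric matrix")
  genes <- rownames(values)
  if (is.null(genes)) stop_bt("values must have gene rownames")
  if (anyDuplicated(genes))
    stop_bt("duplicate gene identifier(s): %s",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (length(regions) != ncol(values) || length(ages) != ncol(values))
    stop_bt("regions and ages must match the number of sample columns")
  if (anyNA(values)) stop_bt("missing values are not allowed in the matrix")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop_bt("negative RPKM for gene %s, sample %s.%s",
            genes[idx[1]], regions[idx[2]], ages[idx[2]])
  }
  age <- parse_age(ages)
  samples <- data.frame(region = as.character(regions),
                        age = age$label, stage = age$stage,
                        order_key = age$order_key,
                        stringsAsFactors = FALSE)
  key <- paste(samples$region, samples$age, sep = ".")
  if (anyDuplicated(key))
    stop_bt("duplicate (region, age) sample(s): %s",
            paste(unique(key[duplicated(key)]), collapse = ", "))
  o <- order(region_rank(samples$region), samples$order_key)
  samples <- samples[o, , drop = FALSE]
  values <- values[, o, drop = FALSE]
  # order_index: rank of the age on the pooled developmental axis
  uk <- sort(unique(samples$order_key))
  samples$order_index <- match(samples$order_key, uk)
  rownames(samples) <- NULL
  colnames(values) <- paste(samples$region, samples$age, sep = ".")
  structure(list(values = values, samples = samples, genes = genes),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("expression_atlas: %d genes x %d samples (%d regions, %d ages)\n",
              length(x$genes), nrow(x$samples),
              length(unique(x$samples$region)),
              length(unique(x$samples$age))))
  cat("  regions:", paste(unique(x$samples$region), collapse = " "), "\n")
  cat("  ages:   ", paste(unique(x$samples$age[order(x$samples$order_key)]),
                          collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expression_atlas <- function(x) dim(x$values)

atlas_regions <- function(atlas) unique(atlas$samples$region)

#' Read an expression matrix
#'
#' Reads a CSV/TSV expression matrix whose first column is the gene symbol
#' and whose remaining column headers encode the sample as
#' \code{"REGION.AGE"} (e.g. \code{"Hipp.24wg"}). Unknown region codes are
#' rejected unless mapped by \code{aliases} or admitted via \code{known_regions}.
#'
#' @param path file path (.csv comma-separated, otherwise tab-separated).
#' @param orientation \code{"genes_in_rows"} (default) or
#'   \code{"genes_in_columns"} (matrix is transposed after reading).
#' @param known_regions admissible region codes; defaults to the canonical 11.
#' @param aliases optional named character vector mapping foreign region codes
#'   to admissible ones.
#' @param blank_as_zero if TRUE, blank cells are read as 0 with a message
#'   reporting the count; otherwise blanks are an error.
#' @return an [expression_atlas()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows", "genes_in_columns"),
                                   known_regions = canonical_regions(),
                                   aliases = NULL,
                                   blank_as_zero = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_bt("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop_bt("expression matrix needs a gene column and >=1 sample")
  if (orientation == "genes_in_columns") {
    smp <- as.character(df[[1]])
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(m) <- smp
  } else {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
  }
  if (anyNA(m)) {
    if (blank_as_zero) {
      n_blank <- sum(is.na(m))
      message(sprintf("converted %d blank cell(s) to 0", n_blank))
      m[is.na(m)] <- 0
    } else {
      stop_bt("non-numeric or blank cells in the matrix (see blank_as_zero)")
    }
  }
  hdr <- colnames(m)
  dot <- regexpr(".", hdr, fixed = TRUE)
  if (any(dot < 0))
    stop_bt("malformed sample header(s): %s (expected REGION.AGE)",
            paste(hdr[dot < 0], collapse = ", "))
  regions <- substr(hdr, 1, dot - 1)
  ages <- substr(hdr, dot + 1, nchar(hdr))
  regions <- resolve_regions(regions, known = known_regions, aliases = aliases)
  rownames(m) <- normalize_genes(rownames(m))
  expression_atlas(m, regions = regions, ages = ages)
}

#' Write an expression atlas
#'
#' Inverse of [read_expression_matrix()]: first column \code{gene}, then one
#' \code{REGION.AGE} column per sample.
#'
#' @param atlas an [expression_atlas()].
#' @param path output path (.csv comma-separated, otherwise tab-separated).
#' @return the path, invisibly.
#' @export
write_expression_matrix <- function(atlas, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = atlas$genes, atlas$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an atlas to ages up to a maximum
#'
#' Drops every sample whose developmental age lies beyond \code{max_age}
#' (e.g. \code{"23y"} retains everything up to and including 23 postnatal
#' years). Genes are unchanged.
#'
#' @param atlas an [expression_atlas()].
#' @param max_age age label (see [parse_age()]).
#' @return filtered [expression_atlas()].
#' @export
filter_ages <- function(atlas, max_age) {
  cutoff <- parse_age(max_age)$order_key
  keep <- atlas$samples$order_key <= cutoff
  if (!any(keep)) stop_bt("age filter at %s removes every sample", max_age)
  expression_atlas(atlas$values[, keep, drop = FALSE],
                   regions = atlas$samples$region[keep],
                   ages = atlas$samples$age[keep])
}

#' Restrict an atlas to a set of regions
#'
#' @param atlas an [expression_atlas()].
#' @param regions character vector of region codes, all present in the atlas.
#' @return filtered [expression_atlas()]; relative age order is preserved.
#' @export
subset_regions <- function(atlas, regions) {
  unknown <- setdiff(regions, atlas_regions(atlas))
  if (length(unknown) > 0)
    stop_bt("region(s) not in atlas: %s", paste(unknown, collapse = ", "))
  keep <- atlas$samples$region %in% regions
  expression_atlas(atlas$values[, keep, drop = FALSE],
                   regions = atlas$samples$region[keep],
                   ages = atlas$samples$age[keep])
}
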