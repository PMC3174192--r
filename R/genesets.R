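#' Construct a named gene set
#'
#' Members are normalized (trimmed, uppercased) and de-duplicated; an empty
#' set is an error.
#'
#' @param name set name (e.g. a disease database name).
#' @param members character vector of gene symbols.
#' @param provenance optional named character vector gene -> evidence label.
#' @return object of class \code{"gene_set"} with \code{name}, sorted unique
#'   \code{members}, and \code{provenance}.
#' @export
gene_set <- function(name, members, provenance = NULL) {
  members <- sort(unique(normalize_genes(members)))
  if (length(members) == 0) stop_bt("gene set '%s' has no members", name)
  if (!is.null(provenance)) {
    names(provenance) <- normalize_genes(names(provenance))
    provenance <- provenance[names(provenance) %in% members]
  }
  structure(list(name = as.character(name), members = members,
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

as_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else sort(unique(normalize_genes(x)))
}

#' Parse a gene list against an atlas
#'
#' Reads one gene symbol per record (plain text, or the first column of a
#' TSV) and restricts the set to genes present in the atlas. Identifiers not
#' in the atlas are reported, never silently dropped; duplicates are
#' collapsed with a message.
#'
#' @param path file path, one symbol per line (or first TSV column).
#' @param atlas an [expression_atlas()] defining the admissible namespace.
#' @param name set name; defaults to the file base name.
#' @return list with \code{set} (a [gene_set()]), \code{excluded}
#'   (identifiers absent from the atlas) and \code{n_duplicates}.
#' @export
parse_gene_list <- function(path, atlas, name = NULL) {
  if (!file.exists(path)) stop_bt("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  ids <- normalize_genes(vapply(strsplit(lines, "\t"), function(z) z[1] %||% "", ""))
  if (length(ids) == 0) stop_bt("empty gene list: %s", path)
  n_dup <- sum(duplicated(ids))
  if (n_dup > 0) message(sprintf("collapsed %d duplicate identifier(s)", n_dup))
  ids <- unique(ids)
  present <- ids %in% atlas$genes
  excluded <- ids[!present]
  if (!any(present)) stop_bt("no gene of %s is present in the atlas", path)
  list(set = gene_set(name %||% tools::file_path_sans_ext(basename(path)),
                      ids[present]),
       excluded = excluded, n_duplicates = n_dup)
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated: name, description, then members.
#'
#' @param path GMT file path.
#' @return named list of [gene_set()] objects; descriptions kept as the
#'   \code{"description"} attribute on each set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_bt("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_bt("empty GMT file: %s", path)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_bt("malformed GMT line (need name, description, members): %s",
                               substr(l, 1, 60))
    s <- gene_set(f[1], f[-(1:2)])
    attr(s, "description") <- f[2]
    s
  })
  stats::setNames(sets, vapply(sets, function(s) s$name, ""))
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set()] or list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, attr(s, "description") %||% "na", s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
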