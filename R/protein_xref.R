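#' Parse ordinal immunohistochemistry staining symbols
#'
#' Maps the four-level staining notation to ordinals: negative
#' (\code{"-"} or Unicode minus) -> 0, weak \code{"+"} -> 1, moderate
#' \code{"++"} -> 2, strong \code{"+++"} -> 3.
#'
#' @param symbol character vector of staining symbols.
#' @return integer vector of ordinals 0-3.
#' @examples
#' parse_staining(c("-", "+", "++", "+++"))
#' @export
parse_staining <- function(symbol) {
  lut <- c("-" = 0L, "−" = 0L, "–" = 0L,
           "+" = 1L, "++" = 2L, "+++" = 3L)
  symbol <- trimws(as.character(symbol))
  out <- lut[symbol]
  if (anyNA(out))
    stop_bt("unknown staining symbol(s): %s",
            paste(unique(symbol[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Format staining ordinals back to symbols
#'
#' @param level integer vector of ordinals 0-3.
#' @return character vector of symbols (ASCII hyphen for negative).
#' @export
format_staining <- function(level) {
  if (any(!level %in% 0:3)) stop_bt("staining ordinals must lie in 0..3")
  c("-", "+", "++", "+++")[level + 1L]
}

neuron_sites <- c("neuron_cortex", "neuron_hipp", "neuron_latvent")
glia_sites <- c("glia_cortex", "glia_hipp", "glia_latvent")
cb_sites <- c("cb_purkinje", "cb_granular", "cb_molecular")

#' Read an ordinal staining table
#'
#' TSV with a \code{gene} column followed by nine staining columns: neurons
#' and glia each at cortex / hippocampus / lateral ventricle, plus the
#' three cerebellar layers (Purkinje, granular, molecular). Cells hold the
#' symbols understood by [parse_staining()].
#'
#' @param path TSV path.
#' @return data.frame of class \code{"staining_table"} with integer ordinal
#'   columns.
#' @export
read_staining_table <- function(path) {
  if (!file.exists(path)) stop_bt("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          encoding = "UTF-8")
  need <- c("gene", neuron_sites, glia_sites, cb_sites)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_bt("staining table missing column(s): %s", paste(miss, collapse = ", "))
  out <- data.frame(gene = normalize_genes(df$gene), stringsAsFactors = FALSE)
  for (col in c(neuron_sites, glia_sites, cb_sites))
    out[[col]] <- parse_staining(df[[col]])
  class(out) <- c("staining_table", "data.frame")
  out
}

#' Write an ordinal staining table
#'
#' @param table a \code{staining_table} (integer ordinals).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_staining_table <- function(table, path) {
  df <- data.frame(gene = table$gene, stringsAsFactors = FALSE)
  for (col in c(neuron_sites, glia_sites, cb_sites))
    df[[col]] <- format_staining(table[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call cell-type specificity from staining levels
#'
#' The source data never formalizes "mainly detected in glia"; the declared,
#' parameterized interpretation used here is: glial when the strongest glial
#' site reaches \code{strong_threshold} and every neuronal site is negative;
#' neuronal symmetrically; none when both compartments are entirely
#' negative; otherwise mixed. Cerebellar layers mix cell types and are
#' excluded from the call by default; \code{fold_cerebellum = TRUE} folds
#' the Purkinje and granular layers into the neuronal compartment. Genes
#' listed in \code{genes} but absent from the table are reported as
#' \code{"not_assayed"} (never \code{"none"}).
#'
#' @param table a \code{staining_table} from [read_staining_table()].
#' @param strong_threshold minimum ordinal (default 2, "moderate") on the
#'   specific side.
#' @param fold_cerebellum fold Purkinje/granular layers into neurons.
#' @param genes optional gene vector; table rows are restricted/augmented to
#'   it, absentees called \code{not_assayed}.
#' @return data.frame: gene, call
#'   (\code{neuronal}/\code{glial}/\code{mixed}/\code{none}/\code{not_assayed}),
#'   neuron_max, glia_max.
#' @export
specificity_call <- function(table, strong_threshold = 2,
                             fold_cerebellum = FALSE, genes = NULL) {
  nsites <- neuron_sites
  if (fold_cerebellum) nsites <- c(nsites, "cb_purkinje", "cb_granular")
  nmax <- apply(as.matrix(table[, nsites, drop = FALSE]), 1, max)
  gmax <- apply(as.matrix(table[, glia_sites, drop = FALSE]), 1, max)
  call <- ifelse(nmax == 0 & gmax == 0, "none",
          ifelse(gmax >= strong_threshold & nmax == 0, "glial",
          ifelse(nmax >= strong_threshold & gmax == 0, "neuronal", "mixed")))
  out <- data.frame(gene = table$gene, call = call,
                    neuron_max = as.integer(nmax), glia_max = as.integer(gmax),
                    stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    genes <- sort(unique(normalize_genes(genes)))
    absent <- setdiff(genes, out$gene)
    out <- out[out$gene %in% genes, , drop = FALSE]
    if (length(absent) > 0)
      out <- rbind(out, data.frame(gene = absent, call = "not_assayed",
                                   neuron_max = NA_integer_,
                                   glia_max = NA_integer_,
                                   stringsAsFactors = FALSE))
    out <- out[order(out$gene), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Summarize specificity calls
#'
#' @param calls a [specificity_call()] result.
#' @return list with \code{counts} (named integer vector over neuronal,
#'   glial, mixed, none and, when present, not_assayed) and \code{genes}
#'   (member lists per call). Counts sum to the number of rows.
#' @export
summarize_specificity <- function(calls) {
  if (nrow(calls) == 0) stop_bt("no specificity calls to summarize")
  lev <- c("neuronal", "glial", "mixed", "none")
  if (any(calls$call == "not_assayed")) lev <- c(lev, "not_assayed")
  tab <- table(factor(calls$call, levels = lev))
  list(counts = stats::setNames(as.integer(tab), names(tab)),
       genes = lapply(stats::setNames(lev, lev),
                      function(l) sort(calls$gene[calls$call == l])))
}
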