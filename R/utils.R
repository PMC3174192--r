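#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; reported percentages here follow
#' the half-up convention of the source tables.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny guard against representation error in fractions like 46/219
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Truncate a percentage at one decimal and strip a trailing ".0":
# 3.0769 -> "3%", 4.7297 -> "4.7%", 3.2258 -> "3.2%".
format_percent_short <- function(fraction) {
  pct <- fraction * 100
  one <- floor(pct * 10 + 1e-9) / 10
  ifelse(one == floor(one),
         sprintf("%d%%", as.integer(floor(one))),
         sprintf("%.1f%%", one))
}

# One declared gene-identifier normalization: trim + uppercase symbol.
normalize_genes <- function(x) {
  x <- trimws(as.character(x))
  toupper(x[nzchar(x)])
}

stop_bt <- function(...) stop(sprintf(...), call. = FALSE)

# stable signature for provenance checks (no external digest dependency)
terms_signature <- function(term_ids) paste(sort(term_ids), collapse = "\r")
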