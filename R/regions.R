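#' Canonical brain-region vocabulary
#'
#' The eleven brain regions retained for the analysis, in their canonical
#' display order: four prefrontal subregions, two temporal cortices,
#' hippocampus, amygdala, striatum, cerebellum and primary motor cortex.
#'
#' @param long logical; return long names instead of codes.
#' @return character vector of 11 region codes (or long names, named by code).
#' @examples
#' canonical_regions()
#' @export
canonical_regions <- function(long = FALSE) {
  codes <- c("DLPC", "VLPC", "MPC", "OPC", "PMC", "PSTC", "ILTC",
             "Hipp", "Amyg", "Stri", "Cere")
  if (!long) return(codes)
  stats::setNames(c("Dorsolateral Prefrontal Cortex",
                    "Ventrolateral Prefrontal Cortex",
                    "Medial Prefrontal Cortex",
                    "Orbital Prefrontal Cortex",
                    "Primary Motor Cortex",
                    "Posterior Superior Temporal Cortex",
                    "Inferior Lateral Temporal Cortex",
                    "Hippocampus", "Amygdala", "Striatum", "Cerebellum"),
                  codes)
}

# Resolve region codes against a vocabulary plus optional alias map
# (named character vector alias -> canonical). Errors name offending codes.
resolve_regions <- function(codes, known = canonical_regions(), aliases = NULL) {
  codes <- as.character(codes)
  if (!is.null(aliases)) {
    hit <- codes %in% names(aliases)
    codes[hit] <- unname(aliases[codes[hit]])
  }
  unknown <- setdiff(unique(codes), known)
  if (length(unknown) > 0)
    stop_bt("unknown region code(s): %s", paste(unknown, collapse = ", "))
  codes
}

# canonical-first ordering for a set of region codes; unknown-but-allowed
# extras follow alphabetically after the canonical block
region_rank <- function(codes) {
  canon <- canonical_regions()
  r <- match(codes, canon)
  extra <- sort(unique(codes[is.na(r)]))
  r[is.na(r)] <- length(canon) + match(codes[is.na(r)], extra)
  r
}
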