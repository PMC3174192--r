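#' Parse developmental age labels
#'
#' Ages on the developmental axis are written \code{"<N>wg"} (weeks of
#' gestation), \code{"<N>mo"} (postnatal months) or \code{"<N>y"} (postnatal
#' years). All gestational ages precede all postnatal ages; within a stage,
#' ordering is numeric. Gestational ages are kept as (stage, weeks) rather
#' than any negative-years encoding.
#'
#' @param labels character vector of age labels, e.g. \code{c("24wg","6mo","23y")}.
#' @return data.frame with columns \code{label}, \code{stage}
#'   (\code{"gestational"} or \code{"postnatal"}), \code{value} (numeric, in
#'   the unit of the label), \code{weeks_gestation} (NA for postnatal),
#'   \code{years_postnatal} (NA for gestational), and \code{order_key}
#'   (numeric sort key, consistent with chronology).
#' @examples
#' parse_age(c("24wg", "4mo", "1y"))
#' @export
parse_age <- function(labels) {
  labels <- as.character(labels)
  m <- regmatches(labels, regexec("^([0-9]+(?:\\.[0-9]+)?)(wg|mo|y)$", labels))
  bad <- labels[vapply(m, length, 1L) == 0L]
  if (length(bad) > 0)
    stop_bt("unparseable age label(s): %s (expected <N>wg, <N>mo or <N>y)",
            paste(unique(bad), collapse = ", "))
  value <- vapply(m, function(z) as.numeric(z[2]), 0)
  unit <- vapply(m, function(z) z[3], "")
  stage <- ifelse(unit == "wg", "gestational", "postnatal")
  years <- ifelse(unit == "y", value, ifelse(unit == "mo", value / 12, NA_real_))
  weeks <- ifelse(unit == "wg", value, NA_real_)
  # gestational always sorts before postnatal; 60 weeks >> term keeps keys clear
  key <- ifelse(stage == "gestational", value / 60 - 1, years)
  data.frame(label = labels, stage = stage, value = value,
             weeks_gestation = weeks, years_postnatal = years,
             order_key = key, stringsAsFactors = FALSE)
}

#' Format parsed ages back to labels
#'
#' Inverse of [parse_age()]; parsing then formatting round-trips.
#'
#' @param age data.frame as returned by [parse_age()].
#' @return character vector of labels.
#' @export
format_age <- function(age) {
  unit <- ifelse(age$stage == "gestational", "wg",
                 ifelse(!is.na(age$years_postnatal) &
                          abs(age$value - age$years_postnatal) < 1e-9, "y", "mo"))
  paste0(ifelse(age$value == round(age$value),
                as.character(as.integer(round(age$value))),
                as.character(age$value)), unit)
}

# order keys for a vector of labels
age_order_key <- function(labels) parse_age(labels)$order_key
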