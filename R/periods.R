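#' The three postglacial time periods
#'
#' The analysis divides the postglacial record into exactly three ordered
#' slices: the Holocene (11,700 BP to AD 1900), the historical period
#' (AD 1900 to AD 2000) and the modern period (post-AD 2000). Locality
#' records carry one of the two pre-modern labels; modern distributions
#' arrive as published range polygons, not points.
#'
#' @return data.frame with columns `label`, `bounds` and `order`
#'   (1 = oldest).
#' @export
time_periods <- function() {
  data.frame(
    label = c("holocene", "historical", "modern"),
    bounds = c("11,700 BP - AD 1900", "AD 1900 - AD 2000", "post-AD 2000"),
    order = 1:3,
    stringsAsFactors = FALSE
  )
}

#' Validate and normalize period labels
#'
#' @param x character vector of period labels (case-insensitive).
#' @param allow subset of labels considered valid (locality tables only
#'   accept the two pre-modern periods).
#' @return normalized character vector; invalid entries become `NA`.
#' @export
as_period <- function(x, allow = c("holocene", "historical", "modern")) {
  x <- tolower(trimws(as.character(x)))
  x[!x %in% allow] <- NA_character_
  x
}

# canonical species-id normalization: Newick tips use underscores, tables
# use spaces, and capitalization differs between sources
normalize_species_id <- function(x) {
  gsub("[ _]+", "_", tolower(trimws(as.character(x))))
}
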