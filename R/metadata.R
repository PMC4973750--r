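#' Read per-individual sample metadata
#'
#' CSV with header
#' `individual,breeding_year,horticultural_group,geographic_origin,ploidy,status`.
#' Empty fields are unknown. Individuals with an unknown breeding year are
#' kept in the dataset (they simply drop out of temporal analyses), and a
#' temporal class is derived for the known years.
#'
#' @param path CSV path.
#' @param scheme Temporal-class scheme, see [temporal_classes()].
#' @return Tibble with the six declared columns plus a derived
#'   `temporal_class` factor.
#' @export
read_metadata <- function(path, scheme = temporal_classes()) {
  x <- readr::read_csv(path, col_types = readr::cols(
    individual = readr::col_character(),
    breeding_year = readr::col_integer(),
    horticultural_group = readr::col_character(),
    geographic_origin = readr::col_character(),
    ploidy = readr::col_integer(),
    status = readr::col_character()
  ), progress = FALSE)
  req <- c("individual", "breeding_year", "horticultural_group",
           "geographic_origin", "ploidy", "status")
  if (!all(req %in% names(x))) {
    abort(sprintf("metadata CSV must have columns: %s", paste(req, collapse = ", ")))
  }
  bad_ploidy <- !is.na(x$ploidy) & !(x$ploidy %in% 2:6)
  if (any(bad_ploidy)) {
    abort(sprintf("ploidy outside 2..6 for: %s",
                  paste(x$individual[bad_ploidy], collapse = ", ")))
  }
  bad_status <- !is.na(x$status) & !(x$status %in% c("botanical", "cultivated"))
  if (any(bad_status)) {
    abort("status must be 'botanical' or 'cultivated' when known")
  }
  x %>% mutate(temporal_class = assign_temporal_class(.data$breeding_year, scheme))
}

#' Write sample metadata
#'
#' @param meta Metadata tibble (derived columns are dropped).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  cols <- c("individual", "breeding_year", "horticultural_group",
            "geographic_origin", "ploidy", "status")
  readr::write_csv(as_tibble(meta)[, cols], path, progress = FALSE)
  invisible(path)
}
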