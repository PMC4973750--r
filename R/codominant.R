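#' Read a codominant genotype table
#'
#' Reads the long CSV dialect used for multi-allelic codominant calls with
#' unknown dosage: header `individual,locus,alleles`, one row per individual
#' and locus, with `alleles` a semicolon-separated list of allele (bin)
#' labels. An empty allele field records missing data — the convention for a
#' total absence of amplification at a primer pair. Allele labels are opaque
#' text, compared by equality only.
#'
#' @param path Path to a CSV file (may be several files' rows concatenated;
#'   duplicated `(individual, locus)` rows must agree).
#' @param locus_defs Optional tibble with columns `locus` and `allele`
#'   declaring the admissible allele bins per locus. When absent, bins are
#'   auto-discovered from the data.
#' @return A codominant tibble with columns `individual`, `locus`, `alleles`
#'   (character, `;`-separated, `NA` = missing). Row order of first
#'   appearance is preserved.
#' @export
read_codominant <- function(path, locus_defs = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("individual", "locus", "alleles") %in% names(raw))) {
    abort("codominant CSV must have header 'individual,locus,alleles'")
  }
  bad <- which(is.na(raw$individual) | is.na(raw$locus) |
                 raw$individual == "" | raw$locus == "")
  if (length(bad)) {
    abort(sprintf("malformed codominant row(s) at line(s) %s: empty individual or locus",
                  paste(bad + 1L, collapse = ", ")))
  }
  tbl <- raw %>%
    mutate(alleles = normalise_allele_field(.data$alleles))
  # duplicate (individual, locus) rows must carry identical calls
  key <- paste(tbl$individual, tbl$locus, sep = "\r")
  if (anyDuplicated(key)) {
    split_calls <- split(tbl$alleles, key)
    conflict <- names(split_calls)[vapply(split_calls, function(v)
      length(unique(v)) > 1L, logical(1))]
    if (length(conflict)) {
      abort(sprintf("conflicting duplicate calls for: %s",
                    paste(gsub("\r", "/", conflict), collapse = ", ")))
    }
    tbl <- tbl[!duplicated(key), ]
  }
  validate_codominant(tbl, locus_defs)
  codominant_tbl(tbl)
}

# Sort labels inside the field and canonicalise empties to NA.
normalise_allele_field <- function(x) {
  vapply(x, function(f) {
    if (is.na(f) || f == "") return(NA_character_)
    labs <- strsplit(f, ";", fixed = TRUE)[[1]]
    labs <- labs[labs != ""]
    if (!length(labs)) return(NA_character_)
    if (anyDuplicated(labs)) labs <- unique(labs)
    paste(sort(labs), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

validate_codominant <- function(tbl, locus_defs = NULL) {
  if (!is.null(locus_defs)) {
    known <- paste(locus_defs$locus, locus_defs$allele, sep = "\r")
    seen <- tbl %>%
      filter(!is.na(.data$alleles)) %>%
      tidyr::separate_longer_delim("alleles", ";")
    bad <- !(paste(seen$locus, seen$alleles, sep = "\r") %in% known)
    if (any(bad)) {
      abort(sprintf("allele label(s) not in locus definitions: %s",
                    paste(unique(paste0(seen$locus[bad], ":", seen$alleles[bad])),
                          collapse = ", ")))
    }
  }
  invisible(tbl)
}

codominant_tbl <- function(tbl) {
  tbl <- as_tibble(tbl)[, c("individual", "locus", "alleles")]
  class(tbl) <- c("codominant_tbl", class(tbl))
  tbl
}

#' Write a codominant genotype table
#'
#' Inverse of [read_codominant()]; missing calls are written as an empty
#' allele field.
#'
#' @param tbl A codominant tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_codominant <- function(tbl, path) {
  out <- as_tibble(tbl)[, c("individual", "locus", "alleles")]
  out$alleles[is.na(out$alleles)] <- ""
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
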