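#' Allele-phenotype (presence/absence) matrices
#'
#' When allele dosage cannot be resolved — the normal situation for mixed
#' 2x--6x material scored on capillary SSR profiles — a genotype is reduced to
#' its *allele phenotype*: the set of allele bins observed at each locus.
#' `to_presence_absence()` expands a codominant table into one binary column
#' per `(locus, allele)` pair. Missingness is recorded per `(individual,
#' locus)`: when a primer pair gave no peak at all, every column of that locus
#' is `NA` for that individual, so "masked" is distinct from "absent".
#'
#' The result is a wide tibble: column `individual`, then one `locus.allele`
#' column per allele bin, values 0/1/NA. All of a locus's columns are `NA`
#' together or observed together; for any observed `(individual, locus)` at
#' least one of the locus's columns is 1.
#'
#' @param tbl A codominant tibble from [read_codominant()].
#' @param locus_defs Optional tibble (`locus`, `allele`) fixing the column
#'   set and order; defaults to bins discovered in the data, in order of
#'   first appearance.
#' @return A `pheno_tbl`: wide binary tibble as described above.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   individual = c("i1", "i1", "i2", "i2"),
#'   locus = c("L1", "L2", "L1", "L2"),
#'   alleles = c("165;167", "90", NA, "92")
#' )
#' to_presence_absence(tbl)
to_presence_absence <- function(tbl, locus_defs = NULL) {
  stopifnot(all(c("individual", "locus", "alleles") %in% names(tbl)))
  if (any(grepl(".", tbl$locus, fixed = TRUE))) {
    abort("locus names must not contain '.' (reserved as the locus.allele separator)")
  }
  individuals <- unique(tbl$individual)
  if (is.null(locus_defs)) {
    long <- tbl %>%
      filter(!is.na(.data$alleles)) %>%
      tidyr::separate_longer_delim("alleles", ";")
    locus_defs <- long %>%
      distinct(.data$locus, allele = .data$alleles)
    # keep loci that are entirely missing in the data as zero-allele loci is
    # impossible; such loci are dropped with a warning
    all_loci <- unique(tbl$locus)
    lost <- setdiff(all_loci, locus_defs$locus)
    if (length(lost)) {
      warn(sprintf("locus(es) with no observed call dropped: %s",
                   paste(lost, collapse = ", ")))
      tbl <- tbl %>% filter(!(.data$locus %in% lost))
    }
  }
  loci <- unique(locus_defs$locus)
  cols <- paste(locus_defs$locus, locus_defs$allele, sep = ".")
  mat <- matrix(0L, nrow = length(individuals), ncol = length(cols),
                dimnames = list(individuals, cols))
  # start from NA for every (individual, locus) never seen in the table
  mat[] <- NA_integer_
  ind_idx <- match(tbl$individual, individuals)
  col_of_locus <- split(seq_along(cols), factor(locus_defs$locus, levels = loci))
  for (r in seq_len(nrow(tbl))) {
    ci <- col_of_locus[[tbl$locus[r]]]
    if (is.na(tbl$alleles[r])) {
      mat[ind_idx[r], ci] <- NA_integer_
    } else {
      labs <- strsplit(tbl$alleles[r], ";", fixed = TRUE)[[1]]
      hit <- match(paste(tbl$locus[r], labs, sep = "."), cols[ci])
      if (anyNA(hit)) {
        abort(sprintf("allele label(s) %s at locus %s not in locus definitions",
                      paste(labs[is.na(hit)], collapse = ", "), tbl$locus[r]))
      }
      mat[ind_idx[r], ci] <- 0L
      mat[ind_idx[r], ci[hit]] <- 1L
    }
  }
  new_pheno_tbl(tibble(individual = individuals) %>%
                  bind_cols(as_tibble(mat)))
}

new_pheno_tbl <- function(x) {
  x <- as_tibble(x)
  stopifnot(names(x)[1] == "individual")
  class(x) <- unique(c("pheno_tbl", class(x)))
  x
}

#' Locus/allele map of a phenotype matrix
#'
#' @param m A `pheno_tbl`.
#' @return Tibble with one row per binary column: `column`, `locus`, `allele`.
#' @export
pheno_loci <- function(m) {
  cols <- setdiff(names(m), "individual")
  dot <- regexpr(".", cols, fixed = TRUE)
  if (any(dot < 0)) abort("binary columns must be named 'locus.allele'")
  tibble(
    column = cols,
    locus = substr(cols, 1L, dot - 1L),
    allele = substr(cols, dot + 1L, nchar(cols))
  )
}

# Numeric matrix view (individuals in rows, rownames set).
pheno_matrix <- function(m) {
  mat <- as.matrix(m[, setdiff(names(m), "individual"), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- m$individual
  mat
}

# Per-(individual, locus) observed indicator matrix (individuals x loci).
locus_observed <- function(m) {
  info <- pheno_loci(m)
  mat <- pheno_matrix(m)
  loci <- unique(info$locus)
  obs <- vapply(loci, function(l) {
    !is.na(mat[, info$column[info$locus == l][1], drop = TRUE])
  }, logical(nrow(mat)))
  obs <- matrix(obs, nrow = nrow(mat), dimnames = list(m$individual, loci))
  obs
}

validate_pheno_tbl <- function(m) {
  info <- pheno_loci(m)
  mat <- pheno_matrix(m)
  for (l in unique(info$locus)) {
    cols <- info$column[info$locus == l]
    block <- mat[, cols, drop = FALSE]
    nas <- is.na(block)
    mixed <- rowSums(nas) %% length(cols) != 0
    if (any(mixed)) {
      abort(sprintf("locus %s partially missing for individual(s) %s: missingness is per locus",
                    l, paste(m$individual[mixed], collapse = ", ")))
    }
    observed <- !nas[, 1]
    if (any(observed) && any(rowSums(block[observed, , drop = FALSE]) < 1)) {
      abort(sprintf("observed individual(s) with no allele at locus %s", l))
    }
  }
  invisible(m)
}

#' Recover the codominant table from a phenotype matrix
#'
#' The presence/absence coding discards dosage but nothing else: the
#' per-locus allele sets are recoverable exactly.
#'
#' @param m A `pheno_tbl`.
#' @return A codominant tibble (`individual`, `locus`, `alleles`).
#' @export
from_presence_absence <- function(m) {
  info <- pheno_loci(m)
  mat <- pheno_matrix(m)
  loci <- unique(info$locus)
  rows <- purrr::map(loci, function(l) {
    cols <- info$column[info$locus == l]
    als <- info$allele[info$locus == l]
    calls <- apply(mat[, cols, drop = FALSE], 1L, function(v) {
      if (anyNA(v)) NA_character_ else paste(sort(als[v == 1]), collapse = ";")
    })
    tibble(individual = m$individual, locus = l, alleles = unname(calls))
  })
  codominant_tbl(bind_rows(rows))
}

#' Filter individuals by missing-data fraction
#'
#' Retains individuals whose fraction of masked loci is *strictly below*
#' `max_fraction`, the convention used when collections are pruned at "<30%"
#' (structure analyses) or "<20%" (distance analyses) missing data. Order is
#' preserved; thresholds compose: filtering at t1 then t2 equals filtering at
#' min(t1, t2).
#'
#' @param m A `pheno_tbl`.
#' @param max_fraction Single proportion in (0, 1].
#' @return The filtered `pheno_tbl`.
#' @export
filter_by_missingness <- function(m, max_fraction) {
  assert_scalar_prop(max_fraction, "max_fraction")
  obs <- locus_observed(m)
  frac_missing <- 1 - rowMeans(obs)
  keep <- frac_missing < max_fraction
  if (!any(keep)) abort("no individuals pass the missingness filter")
  new_pheno_tbl(m[keep, , drop = FALSE])
}

#' Write / read a binary phenotype matrix as TSV
#'
#' Lossless round trip of the wide binary format: first column `individual`,
#' then `locus.allele` headers, cells 0/1/NA with NA spanning all columns of
#' a masked locus.
#'
#' @param m A `pheno_tbl`.
#' @param path TSV path.
#' @return `write_pheno_tbl()` returns `path` invisibly; `read_pheno_tbl()`
#'   returns the `pheno_tbl`.
#' @export
write_pheno_tbl <- function(m, path) {
  readr::write_tsv(as_tibble(m), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_pheno_tbl
#' @export
read_pheno_tbl <- function(path) {
  x <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    individual = readr::col_character(), .default = readr::col_integer()),
    progress = FALSE))
  if (names(x)[1] != "individual") abort("first column must be 'individual'")
  m <- new_pheno_tbl(x)
  pheno_loci(m)  # errors on malformed headers
  validate_pheno_tbl(m)
  m
}

#' Export in a GenAlEx-compatible binary layout
#'
#' One row per individual, 0/1 columns, -1 for missing — convenient for
#' cross-checking AMOVA results against spreadsheet implementations.
#'
#' @param m A `pheno_tbl`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(m, path) {
  mat <- pheno_matrix(m)
  mat[is.na(mat)] <- -1
  out <- bind_cols(tibble(individual = m$individual), as_tibble(mat))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
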