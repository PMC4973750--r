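#' Per-locus diversity indices for allele-phenotype data
#'
#' With dosage unknown, classical allele-frequency indices are replaced by
#' carriage-based analogues computed per SSR locus \eqn{\alpha} over the
#' \eqn{N_\alpha} individuals genotyped (unmasked) there:
#'
#' * `Ao` — number of observed alleles (columns with at least one carrier);
#' * `Am` — mean number of alleles per individual,
#'   \eqn{Am_\alpha = \sum_k n_{k\alpha} / N_\alpha}, where
#'   \eqn{n_{k\alpha}} is the number of alleles individual \eqn{k} carries;
#' * `Ae` — effective number of alleles,
#'   \eqn{Ae_\alpha = 1 / \sum_i (N_{i\alpha}/N_\alpha)^2}, with
#'   \eqn{N_{i\alpha}} the number of carriers of allele \eqn{i}. Carriage
#'   proportions need not sum to 1, so `Ae` can drop below 1 when many
#'   individuals share many alleles;
#' * rare alleles — carried by strictly less than `rare_threshold` (default
#'   1%) of the genotyped individuals.
#'
#' `diversity_table()` assembles all of these per locus; the helper functions
#' expose the individual quantities.
#'
#' @param m A `pheno_tbl` (see [to_presence_absence()]).
#' @param locus A locus name present in `m`.
#' @param rare_threshold Strict carriage-proportion cutoff for rarity.
#' @return `diversity_table()`: a tibble with one row per locus (`locus`,
#'   `n_genotyped`, `missing_fraction`, `ao`, `am`, `ae`, `rare_count`,
#'   `rare_fraction`) and an attached `totals` attribute (a one-row tibble:
#'   summed `ao`/`rare_count`, averaged `am`/`ae`/`missing_fraction`).
#' @export
diversity_table <- function(m, rare_threshold = 0.01) {
  info <- pheno_loci(m)
  loci <- unique(info$locus)
  rows <- purrr::map(loci, function(l) {
    st <- locus_stats(m, l)
    if (st$n == 0L) {
      return(tibble(locus = l, n_genotyped = 0L, missing_fraction = 1,
                    ao = NA_integer_, am = NA_real_, ae = NA_real_,
                    rare_count = NA_integer_, rare_fraction = NA_real_))
    }
    rare <- sum(st$carriers > 0 & st$carriers / st$n < rare_threshold)
    ao <- sum(st$carriers > 0)
    tibble(
      locus = l, n_genotyped = st$n,
      missing_fraction = 1 - st$n / nrow(m),
      ao = ao,
      am = sum(st$per_ind) / st$n,
      ae = 1 / sum((st$carriers / st$n)^2),
      rare_count = rare,
      rare_fraction = if (ao > 0) rare / ao else NA_real_
    )
  })
  out <- bind_rows(rows)
  with_data <- out %>% filter(.data$n_genotyped > 0)
  attr(out, "totals") <- tibble(
    ao = sum(with_data$ao), rare_count = sum(with_data$rare_count),
    am = mean(with_data$am), ae = mean(with_data$ae),
    missing_fraction = mean(out$missing_fraction)
  )
  out
}

# carriage bookkeeping for one locus: n unmasked, per-allele carrier counts,
# per-individual allele counts
locus_stats <- function(m, locus) {
  info <- pheno_loci(m)
  cols <- info$column[info$locus == locus]
  if (!length(cols)) abort(sprintf("unknown locus: %s", locus))
  block <- pheno_matrix(m)[, cols, drop = FALSE]
  observed <- !is.na(block[, 1])
  block <- block[observed, , drop = FALSE]
  list(
    n = sum(observed),
    carriers = colSums(block),
    per_ind = rowSums(block),
    alleles = info$allele[info$locus == locus]
  )
}

#' @rdname diversity_table
#' @export
observed_alleles <- function(m, locus) {
  st <- locus_stats(m, locus)
  sum(st$carriers > 0)
}

#' @rdname diversity_table
#' @export
mean_alleles_per_individual <- function(m, locus) {
  st <- locus_stats(m, locus)
  if (st$n == 0L) abort(sprintf("all individuals masked at locus %s", locus))
  sum(st$per_ind) / st$n
}

#' @rdname diversity_table
#' @export
effective_alleles <- function(m, locus) {
  st <- locus_stats(m, locus)
  if (st$n == 0L) abort(sprintf("all individuals masked at locus %s", locus))
  if (all(st$carriers == 0)) abort(sprintf("no observed allele at locus %s", locus))
  1 / sum((st$carriers / st$n)^2)
}

#' @rdname diversity_table
#' @export
rare_alleles <- function(m, locus, rare_threshold = 0.01) {
  assert_scalar_prop(rare_threshold, "rare_threshold", closed_top = FALSE)
  st <- locus_stats(m, locus)
  if (st$n == 0L) return(character(0))
  st$alleles[st$carriers > 0 & st$carriers / st$n < rare_threshold]
}

#' Carriage frequency of one allele column
#'
#' Fraction of individuals genotyped at the allele's locus that carry the
#' allele — the frequency-of-occurrence measure used when dosage is unknown.
#'
#' @param m A `pheno_tbl`.
#' @param allele A binary column name, `"locus.allele"`.
#' @return A single proportion in \[0, 1\].
#' @export
carriage_frequency <- function(m, allele) {
  if (!allele %in% names(m)) abort(sprintf("unknown allele column: %s", allele))
  v <- m[[allele]]
  n <- sum(!is.na(v))
  if (n == 0L) abort(sprintf("all individuals masked at the locus of %s", allele))
  sum(v, na.rm = TRUE) / n
}
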