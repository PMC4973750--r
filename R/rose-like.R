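#' Rose-like two-pool admixture generator with temporal structure
#'
#' Synthetic stand-in for a garden-rose-style collection: two differentiated
#' ancestral pools ("A", the old European-type background, and "B", the
#' introgressing Asian-type background), breeding-year classes whose pool-B
#' admixture proportion follows a linear gradient from `gradient[1]` to
#' `gradient[2]`, a reference sample of pure pool-B individuals, planted
#' pool-specific alleles whose carriage frequencies satisfy the shift rule
#' by construction, per-(individual, locus) missingness, and a mixed-ploidy
#' composition. Each locus carries `n_shared` alleles at equal frequency in
#' both pools plus `n_specific` alleles private to each pool; a p-ploid
#' individual with admixture proportion a draws p alleles from the mixture
#' `(1 - a) * f_A + a * f_B` of the pool frequency vectors.
#'
#' All pool-specific alleles are the planted "shifted" truth: frequent in
#' their own pool, absent from the other. Shared alleles have identical
#' frequencies in both pools and can only violate the shift rule by
#' sampling noise.
#'
#' @param n_per_class Individuals per temporal class.
#' @param class_years Named list: class label -> inclusive year range
#'   `c(from, to)` used to draw breeding years.
#' @param n_pool_b Individuals in the pure pool-B reference sample.
#' @param n_loci Number of loci.
#' @param n_shared,n_specific Alleles per locus shared between pools /
#'   private to each pool.
#' @param specific_freq Total frequency mass on each pool's private alleles
#'   (split evenly among them); the remainder goes to the shared alleles.
#' @param gradient Pool-B admixture proportion of the first and last class;
#'   intermediate classes interpolate linearly.
#' @param missing_rate Per-(individual, locus) masking probability.
#' @param ploidy_probs Named probabilities of ploidy levels for sampled
#'   individuals.
#' @param seed Integer seed.
#' @return A `rose_sim` list: `pheno`, `codominant`, `metadata` (with
#'   `temporal_class`), `classes` (named id list incl. the `"Asia"`
#'   reference), `truth` (`planted_a`, `planted_b` column names,
#'   per-individual admixture), `seed`.
#' @export
rose_like_sim <- function(n_per_class = 30,
                          class_years = default_rose_classes(),
                          n_pool_b = 40,
                          n_loci = 16,
                          n_shared = 2, n_specific = 2,
                          specific_freq = 0.6,
                          gradient = c(0, 1),
                          missing_rate = 0.03,
                          ploidy_probs = c("2" = 0.3, "3" = 0.1, "4" = 0.6),
                          seed = NULL) {
  stopifnot(n_per_class >= 1, n_pool_b >= 1, n_loci >= 1,
            n_shared >= 1, n_specific >= 0,
            specific_freq > 0, specific_freq < 1,
            all(gradient >= 0), all(gradient <= 1),
            missing_rate >= 0, missing_rate < 1)
  if (abs(sum(ploidy_probs) - 1) > 1e-8) abort("ploidy_probs must sum to 1")
  n_classes <- length(class_years)
  admix <- seq(gradient[1], gradient[2], length.out = n_classes)
  with_seed(seed, {
    loci <- sprintf("L%02d", seq_len(n_loci))
    # frequency vectors: columns = alleles a1..aS (A-private), b1..bS, s1..sH
    # n_specific = 0 gives two identical (undifferentiated) pools
    n_all <- 2 * n_specific + n_shared
    freq_a <- freq_b <- matrix(0, n_loci, n_all)
    shared_mass <- if (n_specific > 0) 1 - specific_freq else 1
    shared <- shared_mass / n_shared
    if (n_specific > 0) {
      spec <- specific_freq / n_specific
      freq_a[, seq_len(n_specific)] <- spec
      freq_b[, n_specific + seq_len(n_specific)] <- spec
    }
    freq_a[, 2 * n_specific + seq_len(n_shared)] <- shared
    freq_b[, 2 * n_specific + seq_len(n_shared)] <- shared
    allele_names <- c(paste0("a", seq_len(n_specific)),
                      paste0("b", seq_len(n_specific)),
                      paste0("s", seq_len(n_shared)))

    draw_individual <- function(id, a_mix, ploidy) {
      calls <- vapply(seq_len(n_loci), function(l) {
        if (runif(1) < missing_rate) return(NA_character_)
        f <- (1 - a_mix) * freq_a[l, ] + a_mix * freq_b[l, ]
        draws <- sample.int(n_all, ploidy, replace = TRUE, prob = f)
        paste(sort(unique(allele_names[draws])), collapse = ";")
      }, character(1))
      tibble(individual = id, locus = loci, alleles = calls)
    }

    ploidies <- as.integer(names(ploidy_probs))
    rows <- list(); meta <- list()
    for (ci in seq_len(n_classes)) {
      yr <- class_years[[ci]]
      for (k in seq_len(n_per_class)) {
        id <- sprintf("c%02d_%03d", ci, k)
        p <- ploidies[sample.int(length(ploidies), 1L, prob = ploidy_probs)]
        rows[[length(rows) + 1L]] <- draw_individual(id, admix[ci], p)
        meta[[length(meta) + 1L]] <- tibble(
          individual = id,
          breeding_year = sample(seq(yr[1], yr[2]), 1L),
          horticultural_group = NA_character_,
          geographic_origin = "Europe", ploidy = p, status = "cultivated",
          admixture = admix[ci]
        )
      }
    }
    for (k in seq_len(n_pool_b)) {
      id <- sprintf("asia_%03d", k)
      p <- ploidies[sample.int(length(ploidies), 1L, prob = ploidy_probs)]
      rows[[length(rows) + 1L]] <- draw_individual(id, 1, p)
      meta[[length(meta) + 1L]] <- tibble(
        individual = id, breeding_year = NA_integer_,
        horticultural_group = NA_character_,
        geographic_origin = "Asia", ploidy = p, status = "cultivated",
        admixture = 1
      )
    }
    codominant <- codominant_tbl(bind_rows(rows))
    # ensure every individual keeps at least one observed locus
    metadata <- bind_rows(meta) %>%
      mutate(temporal_class = assign_temporal_class(.data$breeding_year))
    pheno <- to_presence_absence(
      codominant,
      locus_defs = tidyr::expand_grid(locus = loci, allele = allele_names)
    )
    classes <- c(
      purrr::imap(setNames(seq_len(n_classes), names(class_years)), function(ci, nm) {
        metadata$individual[grepl(sprintf("^c%02d_", ci), metadata$individual)]
      }),
      list(Asia = metadata$individual[metadata$geographic_origin == "Asia"])
    )
    planted_a <- planted_b <- character(0)
    if (n_specific > 0) {
      planted_a <- as.vector(outer(loci, paste0("a", seq_len(n_specific)),
                                   paste, sep = "."))
      planted_b <- as.vector(outer(loci, paste0("b", seq_len(n_specific)),
                                   paste, sep = "."))
    }
    structure(
      list(pheno = pheno, codominant = codominant, metadata = metadata,
           classes = classes,
           truth = list(planted_a = sort(planted_a), planted_b = sort(planted_b),
                        admixture = setNames(metadata$admixture,
                                             metadata$individual)),
           seed = seed),
      class = "rose_sim"
    )
  })
}

#' Default breeding-year bins for the rose-like generator
#'
#' Six decade bins spanning the 19th century, each mapping to a distinct
#' temporal class of [temporal_classes()].
#'
#' @return Named list of `c(from, to)` year ranges.
#' @export
default_rose_classes <- function() {
  list(
    "1800–1809" = c(1800, 1809),
    "1820–1829" = c(1820, 1829),
    "1840–1849" = c(1840, 1849),
    "1860–1869" = c(1860, 1869),
    "1880–1889" = c(1880, 1889),
    "1900–1909" = c(1900, 1909)
  )
}
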