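#' Pairwise PhiPT across temporal classes plus a reference pool
#'
#' Splits one pool of individuals (typically European-bred material) into
#' breeding-year classes and computes pairwise PhiPT among the classes and
#' against a reference pool (typically the Asian accessions), in
#' chronological order. A decreasing PhiPT of successive classes against the
#' reference is the signature of progressive introgression from that pool.
#' Classes below `min_size` are dropped with a warning naming them.
#'
#' @param dd A `dice_dist` covering all individuals involved.
#' @param metadata Metadata tibble with `individual` and `temporal_class`
#'   (factor with chronological levels, e.g. from [read_metadata()]).
#' @param reference_pool Character vector of individual ids forming the
#'   reference group (must not overlap the classed individuals used).
#' @param min_size Minimum class size retained (default 5).
#' @param reference_label Name for the reference group column/row.
#' @inheritParams amova
#' @return A `pairwise_phipt` tibble (see [pairwise_phipt()]) whose groups
#'   are the retained classes in chronological order followed by the
#'   reference; a `dropped_classes` attribute lists undersized classes.
#' @export
temporal_phipt_matrix <- function(dd, metadata, reference_pool,
                                  min_size = 5, n_perm = 1000, seed = NULL,
                                  reference_label = "reference") {
  stopifnot(all(c("individual", "temporal_class") %in% names(metadata)))
  d <- distance_matrix_of(dd)
  ids <- rownames(d)
  meta <- metadata %>%
    filter(.data$individual %in% ids, !is.na(.data$temporal_class),
           !(.data$individual %in% reference_pool))
  ref <- intersect(reference_pool, ids)
  if (!length(ref)) abort("reference pool has no individuals in the distance matrix")
  cls <- factor(meta$temporal_class)
  lv <- levels(droplevels(cls))
  sizes <- table(droplevels(cls))
  keep_lv <- names(sizes)[sizes >= min_size]
  dropped <- setdiff(lv, keep_lv)
  if (length(dropped)) {
    warn(sprintf("temporal class(es) below min_size = %d dropped: %s",
                 min_size, paste(dropped, collapse = ", ")))
  }
  if (!length(keep_lv)) abort("no temporal class meets min_size")
  keep_lv <- lv[lv %in% keep_lv]           # chronological order
  meta <- meta %>% filter(as.character(.data$temporal_class) %in% keep_lv)
  use <- c(meta$individual, ref)
  labels <- setNames(
    c(as.character(meta$temporal_class), rep(reference_label, length(ref))),
    use
  )
  sub <- d[use, use, drop = FALSE]
  # reorder so groups appear chronologically, reference last
  ord <- order(match(labels[use], c(keep_lv, reference_label)))
  sub <- sub[ord, ord, drop = FALSE]
  out <- pairwise_phipt(sub, labels[rownames(sub)], n_perm = n_perm, seed = seed)
  attr(out, "dropped_classes") <- dropped
  attr(out, "class_order") <- c(keep_lv, reference_label)
  out
}

#' Detect alleles shifted in frequency between two pools
#'
#' Flags alleles carried at high frequency (strictly above `hi`, default
#' 20%) in one pool and at null-or-low frequency (strictly below `lo`,
#' default 10%; absence counts as low) in the other. Both directions are
#' reported. Carriage frequencies use, per pool, the individuals unmasked at
#' the allele's locus.
#'
#' @param m A `pheno_tbl`.
#' @param pool_a,pool_b Disjoint, non-empty character vectors of individual
#'   ids.
#' @param hi,lo Frequency thresholds (strict), `hi > lo`.
#' @return Tibble: `direction` (`"pool_a"` = frequent in A, low in B, or
#'   `"pool_b"`), `column`, `locus`, `allele`, `freq_pool_a`, `freq_pool_b`.
#' @export
detect_shifted_alleles <- function(m, pool_a, pool_b, hi = 0.20, lo = 0.10) {
  if (!length(pool_a) || !length(pool_b)) abort("pools must be non-empty")
  if (length(intersect(pool_a, pool_b))) abort("pools must be disjoint")
  missing_ids <- setdiff(c(pool_a, pool_b), m$individual)
  if (length(missing_ids)) {
    abort(sprintf("unknown individual(s): %s", paste(missing_ids, collapse = ", ")))
  }
  fa <- pool_frequencies(m, pool_a)
  fb <- pool_frequencies(m, pool_b)
  info <- pheno_loci(m)
  base <- info %>%
    mutate(freq_pool_a = unname(fa[.data$column]),
           freq_pool_b = unname(fb[.data$column]))
  a_type <- base %>%
    filter(!is.na(.data$freq_pool_a), !is.na(.data$freq_pool_b),
           .data$freq_pool_a > hi, .data$freq_pool_b < lo) %>%
    mutate(direction = "pool_a")
  b_type <- base %>%
    filter(!is.na(.data$freq_pool_a), !is.na(.data$freq_pool_b),
           .data$freq_pool_b > hi, .data$freq_pool_a < lo) %>%
    mutate(direction = "pool_b")
  bind_rows(a_type, b_type) %>%
    select("direction", "column", "locus", "allele",
           "freq_pool_a", "freq_pool_b")
}

# per-column carriage frequency within a subset of individuals
pool_frequencies <- function(m, ids) {
  sub <- pheno_matrix(m)[match(ids, m$individual), , drop = FALSE]
  n_obs <- colSums(!is.na(sub))
  f <- colSums(sub, na.rm = TRUE) / n_obs
  f[n_obs == 0] <- NA_real_
  f
}

#' Carriage-frequency trajectories of alleles across classes
#'
#' For a chosen set of allele columns, computes the per-class carriage
#' frequency (classes are any partition of individuals — temporal classes,
#' pooled periods, or a reference pool appended as its own class).
#'
#' @param m A `pheno_tbl`.
#' @param classes Named list mapping class label to individual ids, in
#'   display order.
#' @param alleles Character vector of binary column names.
#' @return A `trajectories` tibble: `column`, `class` (factor in given
#'   order), `frequency` (`NA` flagged when every individual of the class is
#'   masked at the locus), `n_genotyped`, `n_class`.
#' @export
frequency_trajectories <- function(m, classes, alleles) {
  stopifnot(length(classes) > 0, !is.null(names(classes)))
  bad <- setdiff(alleles, names(m))
  if (length(bad)) abort(sprintf("unknown allele column(s): %s", paste(bad, collapse = ", ")))
  empty <- names(classes)[lengths(classes) == 0]
  if (length(empty)) warn(sprintf("empty class(es): %s", paste(empty, collapse = ", ")))
  rows <- purrr::imap(classes, function(ids, cl) {
    if (!length(ids)) {
      return(tibble(column = alleles, class = cl, frequency = NA_real_,
                    n_genotyped = 0L, n_class = 0L))
    }
    sub <- pheno_matrix(m)[match(ids, m$individual), alleles, drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    f <- colSums(sub, na.rm = TRUE) / n_obs
    f[n_obs == 0] <- NA_real_
    tibble(column = alleles, class = cl, frequency = unname(f),
           n_genotyped = unname(n_obs), n_class = length(ids))
  })
  out <- bind_rows(rows) %>%
    mutate(class = factor(.data$class, levels = names(classes)))
  class(out) <- c("trajectories", class(out))
  out
}

#' Compare per-class allele-frequency distributions (Tukey letters)
#'
#' Treats each allele's carriage frequency in a class as one observation,
#' fits a one-way ANOVA of frequency on class, and summarises Tukey HSD
#' pairwise contrasts as compact letter groupings at `alpha` (default 0.01):
#' classes sharing a letter are not significantly different.
#'
#' @param trajectories Output of [frequency_trajectories()].
#' @param alpha Family-wise significance level for the letters.
#' @return Tibble: `class`, `n_alleles`, `mean_frequency`, `letters`.
#' @export
compare_class_frequencies <- function(trajectories, alpha = 0.01) {
  df <- trajectories %>%
    filter(!is.na(.data$frequency)) %>%
    mutate(class = droplevels(.data$class))
  counts <- table(df$class)
  thin <- names(counts)[counts < 2]
  if (length(thin)) {
    warn(sprintf("class(es) with fewer than 2 observations excluded: %s",
                 paste(thin, collapse = ", ")))
    df <- df %>% filter(!(as.character(.data$class) %in% thin)) %>%
      mutate(class = droplevels(.data$class))
  }
  if (nlevels(df$class) < 2L) abort("need at least two classes with data")
  fit <- aov(frequency ~ class, data = df)
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(class = "Tukey"))
  letters <- multcomp::cld(glht_fit, level = alpha)$mcletters$Letters
  df %>%
    group_by(class = .data$class) %>%
    summarise(n_alleles = dplyr::n(),
              mean_frequency = mean(.data$frequency), .groups = "drop") %>%
    mutate(letters = unname(letters[as.character(.data$class)]))
}

#' Pool temporal classes into coarser display periods
#'
#' Convenience builder of a `classes` list for
#' [frequency_trajectories()]: maps each individual's temporal class into one
#' of a small number of labelled periods. The default 7-period preset pools
#' the 15-class scheme into pre-1800, three double decades of the 19th
#' century, the turn of the century, 1910--1914 and post-1914.
#'
#' @param metadata Metadata tibble with `individual` and `temporal_class`.
#' @param periods Named list mapping period label to the temporal-class
#'   labels it pools.
#' @return Named list of individual-id vectors, in period order.
#' @export
pool_temporal_classes <- function(metadata, periods = default_periods()) {
  purrr::map(periods, function(cls) {
    metadata$individual[as.character(metadata$temporal_class) %in% cls]
  })
}

default_periods <- function() {
  list(
    "<1800" = c("<1700", "1700–1799"),
    "1800–1829" = c("1800–1809", "1810–1819", "1820–1829"),
    "1830–1859" = c("1830–1839", "1840–1849", "1850–1859"),
    "1860–1889" = c("1860–1869", "1870–1879", "1880–1889"),
    "1890–1909" = c("1890–1899", "1900–1909"),
    "1910–1914" = "1910–1914",
    ">1914" = ">1914"
  )
}
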