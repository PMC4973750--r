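#' Dice genetic distance on allele-phenotype profiles
#'
#' For two individuals, over the allele columns of loci observed (unmasked)
#' in *both*, let `a` be the number of shared present alleles, `b` those
#' present only in the first and `c` only in the second. The Dice distance is
#' \deqn{d = 1 - 2a / (2a + b + c).}
#' Shared absences never enter, which is what makes the coefficient suitable
#' for dominant/binary marker data where an absent peak carries little
#' information. Missing loci are handled pairwise-complete: each pair is
#' compared on the intersection of its observed loci, and the number of loci
#' used is recorded per pair.
#'
#' @param m A `pheno_tbl` with at least two individuals.
#' @return A `dice_dist` object: list with `d` (symmetric distance matrix,
#'   zero diagonal, `NA` + flag for pairs with no commonly observed locus),
#'   `loci_used` (symmetric integer matrix), `individuals`, and
#'   `incomparable` (tibble of flagged pairs).
#' @export
dice_dist <- function(m) {
  if (nrow(m) < 2L) abort("need at least two individuals")
  mat <- pheno_matrix(m)
  obs_locus <- locus_observed(m)
  info <- pheno_loci(m)
  # column-level observed indicator and zero-filled presence matrix
  obs_col <- !is.na(mat)
  pres <- mat
  pres[!obs_col] <- 0
  storage.mode(pres) <- "double"
  oc <- matrix(as.double(obs_col), nrow = nrow(mat))
  a <- tcrossprod(pres)              # shared presences (both observed by construction)
  po <- tcrossprod(pres, oc)         # presences of i over columns observed in j
  denom <- po + t(po)                # 2a + b + c
  d <- 1 - 2 * a / denom
  loci_used <- tcrossprod(matrix(as.double(obs_locus), nrow = nrow(obs_locus)))
  storage.mode(loci_used) <- "integer"
  dimnames(d) <- dimnames(loci_used) <- list(m$individual, m$individual)
  diag(d) <- 0
  bad <- which(loci_used == 0 & upper.tri(loci_used), arr.ind = TRUE)
  d[loci_used == 0] <- NA_real_
  diag(d) <- 0
  incomparable <- tibble(
    individual_1 = m$individual[bad[, 1]],
    individual_2 = m$individual[bad[, 2]]
  )
  if (nrow(incomparable)) {
    warn(sprintf("%d pair(s) share no observed locus and are flagged incomparable",
                 nrow(incomparable)))
  }
  structure(
    list(d = d, loci_used = loci_used, individuals = m$individual,
         incomparable = incomparable, boot = NULL),
    class = "dice_dist"
  )
}

#' @export
print.dice_dist <- function(x, ...) {
  cat(sprintf("Dice distance matrix: %d individuals", length(x$individuals)))
  if (nrow(x$incomparable)) cat(sprintf(", %d incomparable pair(s)", nrow(x$incomparable)))
  if (!is.null(x$boot)) cat(sprintf("; bootstrap support over %d locus resamples", x$boot$n_boot))
  cat("\n")
  invisible(x)
}

#' Dice distance between two profiles
#'
#' Convenience scalar form of [dice_dist()] for two named individuals.
#'
#' @param m A `pheno_tbl`.
#' @param i,j Individual identifiers.
#' @return A single distance in \[0, 1\].
#' @export
dice_pair <- function(m, i, j) {
  idx <- match(c(i, j), m$individual)
  if (anyNA(idx)) abort("unknown individual")
  dd <- suppressWarnings(dice_dist(new_pheno_tbl(m[idx, , drop = FALSE])))
  if (is.na(dd$d[1, 2])) abort(sprintf("individuals %s and %s share no observed locus", i, j))
  dd$d[1, 2]
}

#' Locus bootstrap support for Dice distances
#'
#' Resamples loci (whole blocks of allele columns, preserving within-locus
#' dependence) with replacement `n_boot` times and records, per pair, the
#' mean and standard deviation of the resampled distances. Point estimates
#' are never altered.
#'
#' @param m A `pheno_tbl`.
#' @param n_boot Number of locus resamples (the conventional choice is 1000).
#' @param seed Integer seed for reproducible resampling.
#' @return A `dice_dist` whose `boot` field holds `mean` and `sd` matrices,
#'   `n_boot` and `seed`.
#' @export
bootstrap_dice <- function(m, n_boot = 1000, seed = NULL) {
  if (!is.numeric(n_boot) || n_boot < 1) abort("n_boot must be >= 1")
  n_boot <- as.integer(n_boot)
  base <- dice_dist(m)
  info <- pheno_loci(m)
  loci <- unique(info$locus)
  if (length(loci) < 2L) {
    # a single locus resamples to itself: support is degenerate
    base$boot <- list(mean = base$d, sd = base$d * 0, n_boot = n_boot, seed = seed)
    return(base)
  }
  cols_by_locus <- split(info$column, factor(info$locus, levels = loci))
  n <- nrow(m)
  full <- pheno_matrix(m)
  acc <- matrix(0, n, n)
  acc2 <- matrix(0, n, n)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      pick <- sample.int(length(loci), length(loci), replace = TRUE)
      cols <- unlist(cols_by_locus[pick], use.names = FALSE)
      boot_mat <- full[, match(cols, colnames(full)), drop = FALSE]
      # duplicated loci get distinct locus names so per-locus masks stay coherent
      colnames(boot_mat) <- make.unique(cols, sep = "#")
      sub <- new_pheno_tbl(bind_cols(tibble(individual = m$individual),
                                     as_tibble(boot_mat, .name_repair = "minimal")))
      db <- suppressWarnings(dice_dist(rename_boot_cols(sub)))$d
      acc <- acc + ifelse(is.na(db), 0, db)
      acc2 <- acc2 + ifelse(is.na(db), 0, db)^2
    }
  })
  bm <- acc / n_boot
  bs <- sqrt(pmax(acc2 / n_boot - bm^2, 0))
  dimnames(bm) <- dimnames(bs) <- dimnames(base$d)
  base$boot <- list(mean = bm, sd = bs, n_boot = n_boot, seed = seed)
  base
}

# bootstrap duplicates a locus block; give copies fresh locus names so that
# 'locus.allele' parsing and per-locus masks stay coherent
rename_boot_cols <- function(sub) {
  cols <- names(sub)[-1]
  dup <- grepl("#", cols, fixed = TRUE)
  if (any(dup)) {
    suffix <- sub("^.*#", "", cols[dup])
    bare <- sub("#.*$", "", cols[dup])
    dot <- regexpr(".", bare, fixed = TRUE)
    cols[dup] <- paste0(substr(bare, 1, dot - 1), "r", suffix,
                        substr(bare, dot, nchar(bare)))
  }
  names(sub) <- c("individual", cols)
  sub
}

#' Concordance of repeated-control replicates
#'
#' Genotyping plates typically carry repeated control accessions; their
#' within-group Dice distances measure scoring reliability (ideally all
#' zero). Reports the fraction of within-group pairs at exactly zero and the
#' maximum distance observed.
#'
#' @param dd A `dice_dist`.
#' @param replicate_groups Named list mapping group name to a character
#'   vector (>= 2) of individual ids.
#' @return Tibble: `group`, `n_pairs`, `fraction_zero`, `max_distance`, plus
#'   an `overall` attribute with the pooled summary.
#' @export
replicate_concordance <- function(dd, replicate_groups) {
  if (!length(replicate_groups)) {
    out <- tibble(group = character(0), n_pairs = integer(0),
                  fraction_zero = double(0), max_distance = double(0))
    attr(out, "overall") <- tibble(n_pairs = 0L, fraction_zero = NA_real_,
                                   max_distance = NA_real_)
    return(out)
  }
  rows <- purrr::imap(replicate_groups, function(ids, g) {
    if (length(ids) < 2L) abort(sprintf("replicate group %s has fewer than 2 members", g))
    idx <- match(ids, dd$individuals)
    if (anyNA(idx)) {
      abort(sprintf("unknown individual(s) in group %s: %s", g,
                    paste(ids[is.na(idx)], collapse = ", ")))
    }
    sub <- dd$d[idx, idx]
    vals <- sub[upper.tri(sub)]
    tibble(group = g, n_pairs = length(vals),
           fraction_zero = mean(vals == 0), max_distance = max(vals))
  })
  out <- bind_rows(rows)
  all_vals <- unlist(purrr::map(replicate_groups, function(ids) {
    idx <- match(ids, dd$individuals)
    sub <- dd$d[idx, idx]
    sub[upper.tri(sub)]
  }))
  attr(out, "overall") <- tibble(
    n_pairs = length(all_vals),
    fraction_zero = mean(all_vals == 0),
    max_distance = max(all_vals)
  )
  out
}

#' Write / read a square distance matrix as TSV
#'
#' @param dd A `dice_dist` (or plain matrix with dimnames).
#' @param path TSV path.
#' @return `path` invisibly / a numeric matrix.
#' @export
write_distance_tsv <- function(dd, path) {
  d <- if (inherits(dd, "dice_dist")) dd$d else dd
  out <- bind_cols(tibble(individual = rownames(d)), as_tibble(d))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    individual = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  d <- as.matrix(x[, -1])
  rownames(d) <- x$individual
  d
}
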