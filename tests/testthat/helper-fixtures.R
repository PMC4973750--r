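# Builders and independent oracles used across test files.

# Codominant tibble from a compact list: list(i1 = list(L1 = "165;167", ...))
make_codominant <- function(calls) {
  rows <- purrr::imap(calls, function(loci, ind) {
    tibble::tibble(
      individual = ind,
      locus = names(loci),
      alleles = vapply(loci, function(a) if (is.null(a)) NA_character_ else a,
                       character(1), USE.NAMES = FALSE)
    )
  })
  dplyr::bind_rows(rows)
}

make_pheno <- function(calls) to_presence_absence(make_codominant(calls))

# Random pheno_tbl: n individuals, n_loci loci with n_alleles bins each,
# every call a non-empty random subset; optional per-(ind, locus) masking.
random_pheno <- function(n, n_loci = 3, n_alleles = 3, miss_rate = 0) {
  calls <- list()
  for (i in seq_len(n)) {
    ind <- sprintf("i%02d", i)
    loci <- list()
    for (l in seq_len(n_loci)) {
      nm <- sprintf("L%02d", l)
      if (runif(1) < miss_rate) {
        loci[[nm]] <- NULL
        loci[nm] <- list(NULL)
      } else {
        k <- sample.int(n_alleles, 1)
        loci[[nm]] <- paste(sort(sample(as.character(100 + seq_len(n_alleles)), k)),
                            collapse = ";")
      }
    }
    calls[[ind]] <- loci
  }
  make_pheno(calls)
}

# Brute-force Dice oracle: explicit per-pair loop over loci and alleles.
dice_oracle <- function(m) {
  info <- pheno_loci(m)
  mat <- as.matrix(m[, -1])
  rownames(mat) <- m$individual
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(m$individual, m$individual))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- b <- cc <- 0
    used <- FALSE
    for (l in unique(info$locus)) {
      cols <- info$column[info$locus == l]
      xi <- mat[i, cols]; xj <- mat[j, cols]
      if (anyNA(xi) || anyNA(xj)) next
      used <- TRUE
      a <- a + sum(xi == 1 & xj == 1)
      b <- b + sum(xi == 1 & xj == 0)
      cc <- cc + sum(xi == 0 & xj == 1)
    }
    d[i, j] <- if (!used) NA_real_ else 1 - 2 * a / (2 * a + b + cc)
  }
  d
}

# Naive AMOVA SS decomposition: double loops, no matrix algebra.
amova_oracle <- function(d, groups) {
  n <- nrow(d)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1) {
      for (ii in seq_len(length(idx) - 1)) for (jj in (ii + 1):length(idx)) {
        s <- s + d[idx[ii], idx[jj]]^2
      }
    }
    ss_within <- ss_within + s / length(idx)
  }
  list(ss_total = ss_total, ss_within = ss_within,
       ss_among = ss_total - ss_within)
}

# Multivariate Gaussian blob coordinates with planted group labels.
make_blobs <- function(n_per, centers, d = 30, spread = 1) {
  coords <- do.call(rbind, lapply(seq_along(centers), function(g) {
    matrix(rnorm(n_per * d, mean = centers[[g]], sd = spread), ncol = d)
  }))
  rownames(coords) <- sprintf("b%03d", seq_len(nrow(coords)))
  list(coords = coords,
       groups = rep(sprintf("g%d", seq_along(centers)), each = n_per))
}
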