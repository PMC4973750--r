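test_that("codominant CSV parsing handles calls, missing data and merges", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,locus,alleles",
               "ind1,RMS015,165;167",
               "ind1,RMS070,",
               "ind2,RMS015,165"), path)
  tbl <- read_codominant(path)
  expect_equal(tbl$alleles[tbl$individual == "ind1" & tbl$locus == "RMS015"],
               "165;167")
  expect_true(is.na(tbl$alleles[tbl$individual == "ind1" & tbl$locus == "RMS070"]))

  # two files with same individuals, disjoint loci: concatenation then
  # write/read round trip equals the in-memory merge
  merged <- dplyr::bind_rows(
    tibble::tibble(individual = c("a", "b"), locus = "L1", alleles = c("1;2", "2")),
    tibble::tibble(individual = c("a", "b"), locus = "L2", alleles = c("9", "8;9"))
  )
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_codominant(merged, p2)
  expect_equal(as.data.frame(read_codominant(p2)), as.data.frame(merged))
})

test_that("malformed and conflicting codominant rows are rejected", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,locus,alleles", ",L1,165"), p)
  expect_error(read_codominant(p), "line")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,locus,alleles", "a,L1,165", "a,L1,167"), p2)
  expect_error(read_codominant(p2), "conflicting")
  # agreeing duplicates collapse silently
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,locus,alleles", "a,L1,167;165", "a,L1,165;167",
               "b,L1,165"), p3)
  expect_equal(nrow(read_codominant(p3)), 2L)
})

test_that("presence/absence coding sets exactly the observed alleles", {
  m <- make_pheno(list(
    i1 = list(L1 = "165;167", L2 = "90"),
    i2 = list(L1 = "165", L2 = NULL),
    i3 = list(L1 = "169", L2 = "92")
  ))
  expect_equal(unname(unlist(m[m$individual == "i1",
                               c("L1.165", "L1.167", "L1.169")])), c(1L, 1L, 0L))
  # single observed allele: presence only, no dosage inferred
  expect_equal(sum(m[m$individual == "i2", c("L1.165", "L1.167", "L1.169")]), 1L)
  # missing call masks the whole locus
  expect_true(all(is.na(m[m$individual == "i2", c("L2.90", "L2.92")])))
})

test_that("binary coding is information-lossless back to the codominant table", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      m <- random_pheno(8, n_loci = 4, n_alleles = 3, miss_rate = 0.2)
      back <- from_presence_absence(m)
      round_trip <- to_presence_absence(back, locus_defs = pheno_loci(m)[, c("locus", "allele")])
      expect_equal(as.data.frame(round_trip), as.data.frame(m))
    }
  })
})

test_that("unmasked locus blocks always contain at least one presence", {
  withr::with_seed(21, {
    m <- random_pheno(12, n_loci = 5, n_alleles = 4, miss_rate = 0.3)
    info <- pheno_loci(m)
    for (l in unique(info$locus)) {
      block <- as.matrix(m[, info$column[info$locus == l]])
      observed <- !is.na(block[, 1])
      expect_true(all(rowSums(block[observed, , drop = FALSE]) >= 1))
    }
  })
})

test_that("missingness filter is strict and composes as a minimum", {
  calls <- list()
  for (i in 1:3) {
    loci <- list()
    for (l in 1:32) {
      nm <- sprintf("L%02d", l)
      # individual 1: 10/32 masked (31.25%); ind 2: 5/32; ind 3: complete
      masked <- (i == 1 && l <= 10) || (i == 2 && l <= 5)
      if (masked) loci[nm] <- list(NULL) else loci[[nm]] <- "1"
    }
    calls[[sprintf("i%d", i)]] <- loci
  }
  m <- make_pheno(calls)
  expect_equal(filter_by_missingness(m, 0.30)$individual, c("i2", "i3"))
  expect_equal(filter_by_missingness(m, 0.20)$individual, c("i2", "i3"))
  expect_equal(filter_by_missingness(m, 0.15)$individual, "i3")
  # composition = min of thresholds
  expect_equal(
    filter_by_missingness(filter_by_missingness(m, 0.30), 0.20)$individual,
    filter_by_missingness(m, 0.20)$individual
  )
  incomplete <- m[1:2, ]
  class(incomplete) <- class(m)
  expect_error(filter_by_missingness(incomplete, 0.1), "no individuals")
})

test_that("temporal scheme has 15 classes that partition the integers", {
  sch <- temporal_classes()
  expect_equal(nrow(sch), 15L)
  expect_equal(as.character(assign_temporal_class(1845)), "1840–1849")
  expect_equal(as.character(assign_temporal_class(1699)), "<1700")
  expect_equal(as.character(assign_temporal_class(1912)), "1910–1914")
  expect_true(is.na(assign_temporal_class(NA)))
  years <- c(-500:0, 1500:2100)
  lab <- assign_temporal_class(years)
  expect_false(anyNA(lab))
  expect_setequal(levels(lab), sch$label)
})

test_that("binary TSV round trip preserves masks and degenerate matrices", {
  m <- make_pheno(list(
    i1 = list(L1 = "1;2", L2 = NULL),
    i2 = list(L1 = NULL, L2 = NULL),   # fully masked individual
    i3 = list(L1 = "2", L2 = "9")
  ))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_pheno_tbl(m, p)
  expect_equal(as.data.frame(read_pheno_tbl(p)), as.data.frame(m))
  # 0-individual matrix round-trips empty
  p0 <- withr::local_tempfile(fileext = ".tsv")
  write_pheno_tbl(m[0, ], p0)
  expect_equal(nrow(read_pheno_tbl(p0)), 0L)
  # header mismatch errors
  pbad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tL1.1", "x\t1"), pbad)
  expect_error(read_pheno_tbl(pbad), "individual")
})

test_that("metadata reader validates ploidy and derives temporal classes", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,breeding_year,horticultural_group,geographic_origin,ploidy,status",
               "r1,1845,HGal,France,4,cultivated",
               "r2,,T,Asia,2,botanical"), p)
  meta <- read_metadata(p)
  expect_equal(as.character(meta$temporal_class), c("1840–1849", NA))
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,breeding_year,horticultural_group,geographic_origin,ploidy,status",
               "r1,1845,HGal,France,9,cultivated"), p2)
  expect_error(read_metadata(p2), "ploidy")
})
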