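test_that("shifted-allele detection applies strict thresholds in both directions", {
  # pool A: 20 individuals; pool B: 20 individuals, one locus, crafted carriage
  calls <- list()
  for (i in 1:20) {
    # "hi" carried by 5/20 = 25% of A; "edge" by 4/20 = 20%; base by all
    al <- c("base", if (i <= 5) "hi", if (i <= 4) "edge")
    calls[[sprintf("a%02d", i)]] <- list(L1 = paste(al, collapse = ";"))
  }
  for (i in 1:20) {
    # in B: "hi" at 1/20 = 5%, "edge" absent, "zero" only in A at 0%
    al <- c("base", if (i == 1) "hi")
    calls[[sprintf("b%02d", i)]] <- list(L1 = paste(al, collapse = ";"))
  }
  m <- to_presence_absence(
    make_codominant(calls),
    locus_defs = tibble::tibble(locus = "L1",
                                allele = c("base", "hi", "edge", "zero"))
  )
  pool_a <- sprintf("a%02d", 1:20)
  pool_b <- sprintf("b%02d", 1:20)
  out <- detect_shifted_alleles(m, pool_a, pool_b)
  # hi: 25% in A (> 20%), 5% in B (< 10%) -> selected, A-type
  expect_true("L1.hi" %in% out$column[out$direction == "pool_a"])
  # edge: exactly 20% fails the strict > rule
  expect_false("L1.edge" %in% out$column)
  # base is common in both: never selected
  expect_false("L1.base" %in% out$column)
  expect_error(detect_shifted_alleles(m, pool_a, c(pool_b, "a01")), "disjoint")
  # directions are mutually exclusive whenever hi > lo
  both <- intersect(out$column[out$direction == "pool_a"],
                    out$column[out$direction == "pool_b"])
  expect_length(both, 0)
})

test_that("zero-frequency in the low pool still satisfies the shift rule", {
  m <- make_pheno(c(
    purrr::map(setNames(1:10, sprintf("a%02d", 1:10)), function(i)
      list(L1 = "base;marker")),
    purrr::map(setNames(1:10, sprintf("b%02d", 1:10)), function(i)
      list(L1 = "base"))
  ))
  out <- detect_shifted_alleles(m, sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
  expect_equal(out$column[out$direction == "pool_a"], "L1.marker")
  expect_equal(unname(out$freq_pool_b[out$column == "L1.marker"]), 0)
})

test_that("frequency trajectories respect class structure and masking", {
  m <- make_pheno(list(
    e1 = list(L1 = "1;2"), e2 = list(L1 = "1"),
    l1 = list(L1 = "2"), l2 = list(L1 = "2"),
    x1 = list(L1 = NULL)
  ))
  cls <- list(early = c("e1", "e2"), late = c("l1", "l2"), ghost = "x1")
  tr <- frequency_trajectories(m, cls, c("L1.1", "L1.2"))
  expect_equal(tr$frequency[tr$column == "L1.1" & tr$class == "early"], 1)
  expect_equal(tr$frequency[tr$column == "L1.1" & tr$class == "late"], 0)
  # class fully masked at the locus -> flagged NA
  expect_true(is.na(tr$frequency[tr$column == "L1.1" & tr$class == "ghost"]))
  # an allele absent everywhere traces an all-zero trajectory
  m2 <- to_presence_absence(from_presence_absence(m),
                            locus_defs = tibble::tibble(
                              locus = "L1", allele = c("1", "2", "never")))
  tr2 <- frequency_trajectories(m2, cls["early"], "L1.never")
  expect_equal(tr2$frequency, 0)
  # invariant to individual order and to individuals outside all classes
  m_rev <- m[rev(seq_len(nrow(m))), ]
  class(m_rev) <- class(m)
  tr_rev <- frequency_trajectories(m_rev, cls, c("L1.1", "L1.2"))
  expect_equal(as.data.frame(tr_rev), as.data.frame(tr))
})

test_that("Tukey letter groupings separate planted class differences", {
  withr::with_seed(181, {
    low <- tibble::tibble(column = sprintf("al%02d", 1:15), class = "low",
                          frequency = runif(15, 0.05, 0.15))
    high <- tibble::tibble(column = sprintf("al%02d", 1:15), class = "high",
                           frequency = runif(15, 0.7, 0.9))
    same <- tibble::tibble(column = sprintf("al%02d", 1:15), class = "high2",
                           frequency = runif(15, 0.7, 0.9))
  })
  tr <- dplyr::bind_rows(low, high, same) %>%
    dplyr::mutate(class = factor(class, levels = c("low", "high", "high2")))
  class(tr) <- c("trajectories", class(tr))
  out <- compare_class_frequencies(tr, alpha = 0.01)
  expect_false(out$letters[out$class == "low"] ==
                 out$letters[out$class == "high"])
  expect_equal(out$letters[out$class == "high"],
               out$letters[out$class == "high2"])
  # single class errors
  solo <- dplyr::filter(tr, class == "low")
  expect_error(compare_class_frequencies(solo), "two classes")
})

test_that("temporal PhiPT matrix orders classes and drops undersized ones", {
  withr::with_seed(191, rs <- rose_like_sim(n_per_class = 12, n_pool_b = 12,
                                            n_loci = 8, seed = 5))
  dd <- dice_dist(rs$pheno)
  meta_small <- rs$metadata
  # shrink the first class below min_size
  first_ids <- rs$classes[[1]][1:10]
  meta_small <- dplyr::filter(meta_small, !(individual %in% first_ids))
  d_sub <- dd$d[!(rownames(dd$d) %in% first_ids), !(colnames(dd$d) %in% first_ids)]
  expect_warning(
    tp <- temporal_phipt_matrix(d_sub, meta_small,
                                reference_pool = rs$classes$Asia,
                                min_size = 5, n_perm = 9, seed = 1,
                                reference_label = "Asia"),
    "dropped"
  )
  ord <- attr(tp, "class_order")
  expect_equal(ord[length(ord)], "Asia")
  expect_false(names(rs$classes)[1] %in% ord)
  # identical composition in two classes -> PhiPT 0 between them
  m <- make_pheno(c(
    purrr::map(setNames(1:5, paste0("p", 1:5)), function(i) list(L1 = "1;2")),
    purrr::map(setNames(1:5, paste0("q", 1:5)), function(i) list(L1 = "1;2")),
    purrr::map(setNames(1:5, paste0("r", 1:5)), function(i) list(L1 = "3"))
  ))
  meta <- tibble::tibble(
    individual = m$individual[1:10],
    temporal_class = factor(rep(c("1800–1809", "1820–1829"), each = 5))
  )
  tp2 <- temporal_phipt_matrix(dice_dist(m)$d, meta,
                               reference_pool = paste0("r", 1:5),
                               min_size = 2, n_perm = 9, seed = 1)
  pm <- attr(tp2, "phipt_matrix")
  expect_equal(pm["1800–1809", "1820–1829"], 0)
  expect_equal(pm["1800–1809", "reference"], 1)
  # single class + reference: one pair
  tp3 <- temporal_phipt_matrix(dice_dist(m)$d,
                               dplyr::filter(meta, temporal_class == "1800–1809"),
                               reference_pool = paste0("r", 1:5),
                               min_size = 2, n_perm = 9, seed = 1)
  expect_equal(nrow(tp3), 1L)
})

test_that("pooled period presets cover the 15-class scheme", {
  meta <- tibble::tibble(
    individual = c("a", "b", "c"),
    temporal_class = factor(c("<1700", "1845", "1905"),
                            levels = temporal_classes()$label)
  )
  meta$temporal_class <- assign_temporal_class(c(1690, 1845, 1905))
  pools <- pool_temporal_classes(meta)
  expect_equal(pools[["<1800"]], "a")
  expect_equal(pools[["1830–1859"]], "b")
  expect_equal(pools[["1890–1909"]], "c")
  all_classes <- unlist(purrr::map(default_periods(), identity))
  expect_setequal(all_classes, temporal_classes()$label)
})
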