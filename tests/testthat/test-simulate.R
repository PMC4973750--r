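# Scaled-down configs keep the forward simulator fast while preserving the
# default design's shape (the full-size defaults are exercised in the
# acceptance suite).
small_cfg <- function(divergence_time = 30) {
  sim_config(n_subpops = 3, pop_size = 60, divergence_time = divergence_time,
             n_loci = 8, burn_in = 300, haploid_sample = 40,
             ploidy_counts = c("2" = 4, "3" = 4, "4" = 4, "5" = 4, "6" = 4))
}

test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(haploid_sample = 2000, pop_size = 100), "2N")
  expect_error(sim_config(ploidy_counts = c(20, 20)), "named")
  expect_error(sim_config(n_loci = 0))
  cfg <- sim_config()
  expect_equal(cfg$n_subpops, 10L)
  expect_equal(cfg$pop_size, 500L)
  expect_equal(cfg$divergence_time, 50L)
  expect_equal(cfg$n_loci, 32L)
  expect_equal(sum(cfg$ploidy_counts), 100)
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_mixed_ploidy(small_cfg(), seed = 17)
  b <- simulate_mixed_ploidy(small_cfg(), seed = 17)
  expect_identical(as.data.frame(a$pheno), as.data.frame(b$pheno))
  expect_identical(a$truth, b$truth)
  c <- simulate_mixed_ploidy(small_cfg(), seed = 18)
  expect_false(identical(as.data.frame(a$pheno), as.data.frame(c$pheno)))
})

test_that("binary matrix derives exactly from the codominant genotypes", {
  ds <- simulate_mixed_ploidy(small_cfg(), seed = 23)
  rebuilt <- to_presence_absence(ds$codominant)
  expect_identical(as.data.frame(rebuilt), as.data.frame(ds$pheno))
  back <- from_presence_absence(ds$pheno)
  expect_setequal(
    paste(back$individual, back$locus, back$alleles),
    paste(ds$codominant$individual, ds$codominant$locus, ds$codominant$alleles)
  )
})

test_that("truth labels partition individuals into equal origin-by-ploidy cells", {
  ds <- simulate_mixed_ploidy(small_cfg(), seed = 29)
  cells <- table(ds$truth$origin, ds$truth$ploidy)
  expect_true(all(cells == 4))
  expect_equal(dim(cells), c(3L, 5L))
})

test_that("no divergence means no among-origin structure", {
  ds <- simulate_mixed_ploidy(small_cfg(divergence_time = 0), seed = 31)
  dd <- dice_dist(ds$pheno)
  fit <- amova(dd, setNames(ds$truth$origin, ds$truth$individual),
               n_perm = 99, seed = 1)
  expect_lt(fit$percent_among, 3)
})

test_that("zero mutation plus long drift fixes the loci", {
  cfg <- sim_config(n_subpops = 2, pop_size = 20, divergence_time = 400,
                    n_loci = 4, mut_rate = 0, burn_in = 0, haploid_sample = 10,
                    ploidy_counts = c("2" = 3))
  pools <- simulate_subpopulations(cfg, seed = 37)
  for (s in 1:2) for (l in 1:4) {
    expect_equal(length(unique(pools$pools[[s]][[l]])), 1L)
  }
})

test_that("higher ploidy carries more distinct alleles per locus on average", {
  ds <- simulate_mixed_ploidy(small_cfg(divergence_time = 5), seed = 41)
  am <- purrr::map_dbl(c(2, 6), function(p) {
    ids <- ds$truth$individual[ds$truth$ploidy == p]
    sub <- ds$pheno[match(ids, ds$pheno$individual), ]
    class(sub) <- class(ds$pheno)
    mean(purrr::map_dbl(sprintf("L%02d", 1:8), function(l)
      mean_alleles_per_individual(sub, l)))
  })
  expect_gt(am[2], am[1])
})

test_that("a monomorphic pool collapses to a single presence column", {
  pools <- structure(list(
    pools = list(list(rep(7L, 10))),
    cfg = sim_config(n_subpops = 1, pop_size = 10, divergence_time = 0,
                     n_loci = 1, burn_in = 0, haploid_sample = 10,
                     ploidy_counts = c("2" = 2)),
    seed = 1
  ), class = "sim_pools")
  ds <- assemble_mixed_ploidy(pools, seed = 2)
  expect_equal(setdiff(names(ds$pheno), "individual"), "L01.7")
  expect_true(all(ds$pheno$L01.7 == 1))
})

test_that("among-origin variance grows with divergence time", {
  pct <- purrr::map_dbl(c(5, 60), function(t) {
    vals <- purrr::map_dbl(1:3, function(s) {
      ds <- simulate_mixed_ploidy(small_cfg(divergence_time = t),
                                  seed = 100 * s + t)
      dd <- dice_dist(ds$pheno)
      amova(dd, setNames(ds$truth$origin, ds$truth$individual),
            n_perm = 0)$percent_among
    })
    median(vals)
  })
  expect_gt(pct[2], pct[1])
})

test_that("the rose-like generator plants its own truth", {
  rs <- rose_like_sim(n_per_class = 15, n_pool_b = 20, n_loci = 8, seed = 47)
  # metadata consistent with the temporal scheme
  expect_false(anyNA(rs$metadata$temporal_class[rs$metadata$geographic_origin == "Europe"]))
  expect_setequal(names(rs$classes),
                  c(names(default_rose_classes()), "Asia"))
  # planted columns exist in the matrix
  expect_true(all(c(rs$truth$planted_a, rs$truth$planted_b) %in% names(rs$pheno)))
  # no divergence, no planted alleles -> nothing detected
  rs0 <- rose_like_sim(n_per_class = 15, n_pool_b = 20, n_loci = 8,
                       n_specific = 0, missing_rate = 0, seed = 53)
  expect_length(rs0$truth$planted_a, 0)
  out <- detect_shifted_alleles(rs0$pheno, rs0$classes$Asia, rs0$classes[[1]])
  expect_equal(nrow(out), 0L)
  # determinism
  again <- rose_like_sim(n_per_class = 15, n_pool_b = 20, n_loci = 8, seed = 47)
  expect_identical(as.data.frame(again$pheno), as.data.frame(rs$pheno))
})

test_that("the ploidy-bias report contrasts origin and ploidy groupings", {
  rep <- ploidy_bias_experiment(small_cfg(divergence_time = 60), seed = 59,
                                n_perm = 49)
  expect_gt(rep$percent_among_origin, rep$percent_among_ploidy)
  expect_s3_class(rep$ploidy_assignment, "tbl_df")
  expect_equal(nrow(rep$ploidy_assignment), 5L)
  expect_true(all(rep$ploidy_assignment$mean_membership_true >= 0 &
                    rep$ploidy_assignment$mean_membership_true <= 1))
})
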