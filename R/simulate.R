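#' Configuration of the mixed-ploidy subpopulation simulation
#'
#' The simulation used to probe whether ploidy level biases the detection of
#' genetic structure: ten subpopulations of constant size 500 (diploid)
#' individuals split from one ancestral population 50 generations ago, 32
#' unlinked SSR loci evolving under strict stepwise mutation, 100 haploid
#' allele copies sampled per subpopulation, from which 20 individuals of
#' each ploidy 2x--6x are assembled per subpopulation under panmixia and
#' strict polysomic inheritance. The ancestral population is equilibrated by
#' a burn-in of `burn_in` generations (default 10 x the population size)
#' before the split.
#'
#' @param n_subpops Number of subpopulations.
#' @param pop_size Subpopulation size in diploid individuals (so `2 *
#'   pop_size` allele copies drift each generation).
#' @param divergence_time Generations since the ancestral split.
#' @param n_loci Number of unlinked SSR loci.
#' @param mut_rate Stepwise mutation rate per allele copy per generation.
#' @param burn_in Ancestral equilibration generations.
#' @param haploid_sample Allele copies sampled per subpopulation and locus.
#' @param ploidy_counts Named integer vector: individuals per ploidy level
#'   (names "2".."6") in each subpopulation.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subpops = 10, pop_size = 500, divergence_time = 50,
                       n_loci = 32, mut_rate = 5e-4, burn_in = 10 * pop_size,
                       haploid_sample = 100,
                       ploidy_counts = c("2" = 20, "3" = 20, "4" = 20,
                                         "5" = 20, "6" = 20)) {
  cfg <- list(
    n_subpops = as.integer(n_subpops), pop_size = as.integer(pop_size),
    divergence_time = as.integer(divergence_time), n_loci = as.integer(n_loci),
    mut_rate = mut_rate, burn_in = as.integer(burn_in),
    haploid_sample = as.integer(haploid_sample),
    ploidy_counts = ploidy_counts
  )
  with(cfg, {
    stopifnot(n_subpops >= 1, pop_size >= 1, divergence_time >= 0,
              n_loci >= 1, mut_rate >= 0, mut_rate < 1, burn_in >= 0,
              haploid_sample >= 1, all(ploidy_counts >= 0),
              sum(ploidy_counts) > 0)
    if (haploid_sample > 2 * pop_size) {
      abort("haploid_sample cannot exceed the 2N allele copies of a subpopulation")
    }
    if (is.null(names(ploidy_counts)) ||
        !all(names(ploidy_counts) %in% as.character(2:6))) {
      abort("ploidy_counts must be named with ploidy levels '2'..'6'")
    }
  })
  structure(cfg, class = "sim_config")
}

# one Wright-Fisher generation for a pool of allele copies (repeat counts):
# multinomial resampling then stepwise +/-1 mutation, reflected at 1
wf_generation <- function(pool, mut_rate) {
  pool <- pool[sample.int(length(pool), length(pool), replace = TRUE)]
  n_mut <- rbinom(1L, length(pool), mut_rate)
  if (n_mut > 0L) {
    idx <- sample.int(length(pool), n_mut)
    step <- sample(c(-1L, 1L), n_mut, replace = TRUE)
    pool[idx] <- pmax(pool[idx] + step, 1L)
  }
  pool
}

#' Simulate drifted subpopulation allele pools
#'
#' Forward Wright--Fisher simulation of `2 * pop_size` allele copies per
#' locus: the ancestral pool starts monomorphic, is equilibrated for
#' `burn_in` generations under stepwise mutation, is copied into
#' `n_subpops` subpopulations that then drift independently for
#' `divergence_time` generations, and finally `haploid_sample` copies are
#' drawn (without replacement) per subpopulation and locus.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (the whole simulation is reproducible from it).
#' @return A `sim_pools` list: `pools[[subpop]][[locus]]` integer vectors of
#'   sampled allele states (length `haploid_sample`), plus `cfg` and `seed`.
#' @export
simulate_subpopulations <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    copies <- 2L * cfg$pop_size
    ancestral <- purrr::map(seq_len(cfg$n_loci), function(l) {
      pool <- rep(20L, copies)
      for (g in seq_len(cfg$burn_in)) pool <- wf_generation(pool, cfg$mut_rate)
      pool
    })
    pools <- purrr::map(seq_len(cfg$n_subpops), function(s) {
      purrr::map(ancestral, function(pool) {
        for (g in seq_len(cfg$divergence_time)) {
          pool <- wf_generation(pool, cfg$mut_rate)
        }
        sort(pool[sample.int(copies, cfg$haploid_sample)])
      })
    })
    structure(list(pools = pools, cfg = cfg, seed = seed), class = "sim_pools")
  })
}

#' Assemble mixed-ploidy individuals from subpopulation pools
#'
#' Under panmixia and strict polysomic inheritance, a p-ploid individual is
#' p independent allele draws (with replacement) from its subpopulation's
#' sampled pool at every locus. Duplicate draws collapse in the
#' presence/absence coding, exactly as dosage-blind scoring would record
#' them.
#'
#' @param sim A `sim_pools` from [simulate_subpopulations()].
#' @param seed Integer seed for the individual assembly.
#' @return A `sim_dataset`: `pheno` (binary `pheno_tbl`), `codominant`
#'   (codominant tibble), `truth` (tibble `individual`, `origin`, `ploidy`),
#'   `cfg`, `seed`.
#' @export
assemble_mixed_ploidy <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "sim_pools"))
  cfg <- sim$cfg
  ploidies <- as.integer(names(cfg$ploidy_counts))
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (s in seq_len(cfg$n_subpops)) {
      counter <- 0L
      for (pi in seq_along(ploidies)) {
        p <- ploidies[pi]
        for (k in seq_len(cfg$ploidy_counts[pi])) {
          counter <- counter + 1L
          id <- sprintf("s%02d_p%d_%02d", s, p, k)
          calls <- vapply(seq_len(cfg$n_loci), function(l) {
            pool <- sim$pools[[s]][[l]]
            draws <- pool[sample.int(length(pool), p, replace = TRUE)]
            paste(sort(unique(draws)), collapse = ";")
          }, character(1))
          rows[[length(rows) + 1L]] <- tibble(
            individual = id,
            locus = sprintf("L%02d", seq_len(cfg$n_loci)),
            alleles = calls
          )
          truth[[length(truth) + 1L]] <- tibble(
            individual = id, origin = sprintf("s%02d", s), ploidy = p
          )
        }
      }
    }
    codominant <- codominant_tbl(bind_rows(rows))
    structure(
      list(pheno = to_presence_absence(codominant),
           codominant = codominant,
           truth = bind_rows(truth),
           cfg = cfg, seed = seed),
      class = "sim_dataset"
    )
  })
}

#' Simulate a full mixed-ploidy dataset
#'
#' Convenience wrapper: [simulate_subpopulations()] then
#' [assemble_mixed_ploidy()], with child seeds derived from one parent seed.
#'
#' @inheritParams simulate_subpopulations
#' @return A `sim_dataset`.
#' @export
simulate_mixed_ploidy <- function(cfg = sim_config(), seed = NULL) {
  pools <- simulate_subpopulations(cfg, seed = seed)
  assemble_mixed_ploidy(pools, seed = child_seed(seed, "simulate"))
}

#' Ploidy-bias experiment: does ploidy masquerade as structure?
#'
#' Runs the full analysis chain on one simulated mixed-ploidy dataset:
#' presence/absence coding, Dice distances, AMOVA grouped by true origin and
#' (on the identical distances) by ploidy level, and a DAPC discriminant
#' step on the true origin labels to summarise per-ploidy assignment
#' quality. If origin explains far more molecular variance than ploidy, the
#' allele-phenotype coding does not cluster individuals by ploidy.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param n_perm Permutations for each AMOVA.
#' @param n_pc PCs retained in the discriminant step; `NULL` = PCs covering
#'   95% of the variance.
#' @param run_dapc Set `FALSE` to skip the DAPC summary (AMOVA only).
#' @return A `ploidy_bias_report`: `amova_by_origin`, `amova_by_ploidy`
#'   (both `amova` objects), `percent_among_origin`, `percent_among_ploidy`,
#'   `ploidy_assignment` (tibble: per ploidy, mean membership in the true
#'   group, sd, fraction well-assigned), `dataset`, `seed`.
#' @export
ploidy_bias_experiment <- function(cfg = sim_config(), seed = NULL,
                                   n_perm = 1000, n_pc = NULL,
                                   run_dapc = TRUE) {
  ds <- simulate_mixed_ploidy(cfg, seed = seed)
  dd <- dice_dist(ds$pheno)
  origin <- setNames(ds$truth$origin, ds$truth$individual)
  ploidy <- setNames(as.character(ds$truth$ploidy), ds$truth$individual)
  am_origin <- amova(dd, origin, n_perm = n_perm, seed = child_seed(seed, "amova"))
  am_ploidy <- amova(dd, ploidy, n_perm = n_perm,
                     seed = child_seed(seed, "amova"))
  ploidy_assignment <- NULL
  if (run_dapc) {
    fit <- fit_dapc(ds$pheno, origin, n_pc = n_pc)
    true_prob <- fit$membership[cbind(seq_len(nrow(fit$membership)),
                                      match(origin[rownames(fit$membership)],
                                            colnames(fit$membership)))]
    correct <- fit$assignment$assigned == origin[fit$assignment$individual]
    ploidy_assignment <- tibble(
      individual = rownames(fit$membership),
      ploidy = ds$truth$ploidy[match(rownames(fit$membership),
                                     ds$truth$individual)],
      membership_true = true_prob,
      correct = correct,
      well_assigned = fit$assignment$well_assigned
    ) %>%
      group_by(.data$ploidy) %>%
      summarise(mean_membership_true = mean(.data$membership_true),
                sd_membership_true = sd(.data$membership_true),
                fraction_correct = mean(.data$correct),
                fraction_well_assigned = mean(.data$well_assigned),
                n = dplyr::n(), .groups = "drop")
  }
  structure(
    list(amova_by_origin = am_origin, amova_by_ploidy = am_ploidy,
         percent_among_origin = am_origin$percent_among,
         percent_among_ploidy = am_ploidy$percent_among,
         ploidy_assignment = ploidy_assignment,
         dataset = ds, seed = seed),
    class = "ploidy_bias_report"
  )
}

#' @export
print.ploidy_bias_report <- function(x, ...) {
  cat(sprintf("Ploidy-bias experiment (n = %d individuals)\n",
              nrow(x$dataset$truth)))
  cat(sprintf("  %% molecular variance among origins: %.1f (p = %.4g)\n",
              x$percent_among_origin, x$amova_by_origin$p_value))
  cat(sprintf("  %% molecular variance among ploidy levels: %.1f (p = %.4g)\n",
              x$percent_among_ploidy, x$amova_by_ploidy$p_value))
  if (!is.null(x$ploidy_assignment)) print(x$ploidy_assignment)
  invisible(x)
}
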