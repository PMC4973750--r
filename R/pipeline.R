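#' Pipeline configuration
#'
#' Bundles every tunable of the full analysis chain with its conventional
#' default: the 30% missingness ceiling for structure analyses and 20% for
#' distance analyses (both strict), the K-means scan range 2--35, 1000
#' K-scan runs / bootstraps / permutations (50 in reduced mode), the 0.8
#' membership threshold, the 1% rare-allele cutoff and the 20%/10% shift
#' thresholds.
#'
#' @param genotypes Path to a codominant CSV (see [read_codominant()]).
#' @param metadata Path to a metadata CSV (optional; required for temporal
#'   analyses).
#' @param out_dir Output directory.
#' @param miss_structure,miss_distance Strict missingness thresholds.
#' @param k_range K values scanned.
#' @param n_runs,n_boot,n_perm Run counts (K scan, locus bootstraps, AMOVA
#'   permutations).
#' @param membership_threshold Well-assigned cutoff.
#' @param rare_threshold Rare-allele carriage cutoff.
#' @param shift_hi,shift_lo Allele-shift thresholds.
#' @param reduced Reduced mode: caps all run counts at 50 for quick,
#'   exploratory passes.
#' @param seed Master seed; child seeds are derived per stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genotypes = NULL, metadata = NULL,
                            out_dir = tempfile("phenopop_run_"),
                            miss_structure = 0.30, miss_distance = 0.20,
                            k_range = 2:35, n_runs = 1000, n_boot = 1000,
                            n_perm = 1000, membership_threshold = 0.8,
                            rare_threshold = 0.01,
                            shift_hi = 0.20, shift_lo = 0.10,
                            reduced = FALSE, seed = 1L) {
  if (reduced) {
    n_runs <- min(n_runs, 50L); n_boot <- min(n_boot, 50L)
    n_perm <- min(n_perm, 50L)
  }
  assert_scalar_prop(miss_structure, "miss_structure")
  assert_scalar_prop(miss_distance, "miss_distance")
  assert_scalar_prop(membership_threshold, "membership_threshold")
  stopifnot(n_runs >= 1, n_boot >= 1, n_perm >= 1, shift_hi > shift_lo)
  structure(
    list(genotypes = genotypes, metadata = metadata, out_dir = out_dir,
         miss_structure = miss_structure, miss_distance = miss_distance,
         k_range = k_range, n_runs = as.integer(n_runs),
         n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
         membership_threshold = membership_threshold,
         rare_threshold = rare_threshold,
         shift_hi = shift_hi, shift_lo = shift_lo,
         reduced = reduced, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Load, filter by missingness, diversity table, Dice distances, K-scan +
#' DAPC, AMOVA on the inferred genetic groups, and (when metadata with
#' breeding years is available) temporal PhiPT and allele-shift analyses.
#' Every stage's table is written under `config$out_dir` together with a
#' `manifest.json` echoing the configuration, seed and artifact list —
#' enough to reproduce the run exactly. A stage failure aborts with a
#' stage-named error after writing a `FAILED` marker.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`pheno`,
#'   `diversity`, `distance`, `kscan`, `dapc`, `amova`, `temporal`, paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$genotypes) || !file.exists(config$genotypes)) {
    abort("configuration error: `genotypes` path is missing or unreadable")
  }
  meta <- NULL
  if (!is.null(config$metadata)) {
    if (!file.exists(config$metadata)) {
      abort("configuration error: `metadata` path does not exist")
    }
    meta <- read_metadata(config$metadata)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(config$out_dir, name)
    readr::write_csv(tbl, path, progress = FALSE)
    artifacts <<- c(artifacts, name)
    path
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", name, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  pheno_all <- stage("load", {
    to_presence_absence(read_codominant(config$genotypes))
  })
  pheno <- stage("filter", filter_by_missingness(pheno_all, config$miss_structure))
  pheno_dist <- stage("filter", filter_by_missingness(pheno_all, config$miss_distance))

  div <- stage("diversity", diversity_table(pheno, config$rare_threshold))
  emit(div, "diversity.csv")

  dd <- stage("distance", dice_dist(pheno_dist))
  emit(tidy(dd), "distance_pairs.csv")

  ks <- stage("dapc", kmeans_bic_scan(pheno, k_range = config$k_range,
                                      n_runs = config$n_runs,
                                      seed = child_seed(config$seed, "kscan")))
  emit(tidy(ks), "bic_curves.csv")
  dap <- stage("dapc", fit_dapc(pheno, ks$clusters))
  emit(tidy(dap), "membership.csv")
  emit(assign_members(dap, config$membership_threshold), "assignment.csv")
  emit(bind_cols(tibble(individual = rownames(dap$axes)),
                 as_tibble(dap$axes)), "dapc_coordinates.csv")

  groups_dist <- stage("amova", {
    setNames(as.character(ks$clusters[pheno_dist$individual]),
             pheno_dist$individual)
  })
  am <- stage("amova", amova(dd, groups_dist, n_perm = config$n_perm,
                             seed = child_seed(config$seed, "amova")))
  emit(tidy(am), "amova.csv")
  pw <- stage("amova", pairwise_phipt(dd, groups_dist, n_perm = config$n_perm,
                                      seed = child_seed(config$seed, "amova")))
  emit(as_tibble(pw), "pairwise_phipt.csv")
  emit(mpd(pw), "mpd.csv")
  emit(nsswg(dd, groups_dist), "nsswg.csv")

  temporal <- NULL
  if (!is.null(meta)) {
    temporal <- stage("temporal", {
      asian <- meta$individual[meta$geographic_origin %in% "Asia"]
      asian <- intersect(asian, pheno_dist$individual)
      if (length(asian) >= 2) {
        tp <- temporal_phipt_matrix(dd, meta, reference_pool = asian,
                                    n_perm = config$n_perm,
                                    seed = child_seed(config$seed, "temporal"))
        emit(as_tibble(tp), "temporal_phipt.csv")
        european <- setdiff(pheno_dist$individual, asian)
        shifts <- detect_shifted_alleles(pheno, asian, european,
                                         hi = config$shift_hi,
                                         lo = config$shift_lo)
        emit(shifts, "shifted_alleles.csv")
        list(phipt = tp, shifts = shifts)
      } else NULL
    })
  }

  manifest <- list(
    package = "phenopop",
    version = as.character(utils::packageVersion("phenopop")),
    seed = config$seed,
    reduced = config$reduced,
    config = config[setdiff(names(config), c("genotypes", "metadata", "out_dir"))],
    inputs = list(
      genotypes = unname(tools::md5sum(config$genotypes)),
      metadata = if (!is.null(config$metadata))
        unname(tools::md5sum(config$metadata)) else NULL
    ),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(pheno = pheno, diversity = div, distance = dd, kscan = ks,
                 dapc = dap, amova = am, pairwise = pw, temporal = temporal,
                 out_dir = config$out_dir,
                 manifest = file.path(config$out_dir, "manifest.json")))
}
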