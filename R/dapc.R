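#' PCA embedding of a binary phenotype matrix
#'
#' Centred principal components of the 0/1 allele-phenotype matrix, the
#' dimension-reduction step ahead of K-means clustering and the discriminant
#' analysis. Masked loci are imputed with the per-column mean over unmasked
#' individuals, so after centring a masked entry contributes exactly zero.
#'
#' @param m A `pheno_tbl`, or a plain numeric matrix (rows = individuals).
#' @param n_pc Number of components to return; `NULL` keeps all. Requests
#'   beyond the matrix rank are clipped with a warning.
#' @return A `pheno_pca`: list with `coords` (individuals x PCs, rownames
#'   set), `explained` (variance shares of the returned PCs, of the total
#'   variance), `n_pc`.
#' @export
pca_embed <- function(m, n_pc = NULL) {
  mat <- impute_mean(m)
  if (nrow(mat) < 2L) abort("need at least two individuals")
  fit <- prcomp(mat, center = TRUE, scale. = FALSE)
  shares <- fit$sdev^2 / sum(fit$sdev^2)
  rank <- sum(fit$sdev > sqrt(.Machine$double.eps) * max(fit$sdev, 1))
  keep <- if (is.null(n_pc)) rank else min(as.integer(n_pc), rank)
  if (!is.null(n_pc) && n_pc > rank) {
    warn(sprintf("n_pc = %d exceeds rank %d; clipped", n_pc, rank))
  }
  structure(
    list(coords = fit$x[, seq_len(keep), drop = FALSE],
         explained = shares[seq_len(keep)],
         n_pc = keep),
    class = "pheno_pca"
  )
}

# mean-impute masked entries; accepts pheno_tbl or plain matrix
impute_mean <- function(m) {
  mat <- if (is_tibble(m) || is.data.frame(m)) pheno_matrix(m) else as.matrix(m)
  if (anyNA(mat)) {
    mu <- colMeans(mat, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    nas <- which(is.na(mat), arr.ind = TRUE)
    mat[nas] <- mu[nas[, 2]]
  }
  mat
}

# PCs covering at least `target` of the variance (the K-scan convention)
pcs_for_variance <- function(pca, target = 0.95) {
  cum <- cumsum(pca$explained) / sum(pca$explained)
  max(which(cum >= target)[1], 1L)
}

#' K-means/BIC scan with modal-K selection
#'
#' Runs K-means at each K in `k_range` on PCA coordinates and scores each
#' partition with \deqn{BIC(K) = N \ln(WSS_K/N) + K \ln N,} recording the
#' BIC-minimising K of every run. Because K-means is stochastic, the scan is
#' repeated `n_runs` times and the modal per-run optimum is returned (ties
#' broken toward the smaller K, the parsimonious choice). The classic
#' protocol scans K = 2..35 with 1000 runs; tests and reduced mode use fewer
#' runs.
#'
#' @param x A `pheno_tbl`, `pheno_pca`, or coordinate matrix. For a
#'   `pheno_tbl`, PCs covering >= 95% variance are used.
#' @param k_range Integer range of K values (default 2:35).
#' @param n_runs Number of repeated scans.
#' @param seed Integer seed.
#' @return A `kscan` object: `runs` tibble (`run`, `k`, `bic`), `best_k`
#'   per-run tibble, `modal_k`, `k_range`, `n_runs`, `seed`, and the
#'   clustering of one final K-means at `modal_k` (`clusters`).
#' @export
kmeans_bic_scan <- function(x, k_range = 2:35, n_runs = 1000, seed = NULL) {
  coords <- scan_coords(x)
  n <- nrow(coords)
  if (any(!is.finite(coords))) abort("coordinates must be finite")
  if (all(apply(coords, 2, function(v) max(v) - min(v)) <
          sqrt(.Machine$double.eps))) {
    abort("degenerate input: all individuals have identical coordinates")
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range >= n)) {
    warn(sprintf("K values >= N (%d) capped at N - 1", n))
    k_range <- unique(pmin(k_range, n - 1L))
  }
  if (any(k_range < 1L)) abort("K must be >= 1")
  runs <- with_seed(seed, {
    purrr::map(seq_len(n_runs), function(r) {
      bic <- vapply(k_range, function(k) {
        km <- suppressWarnings(kmeans(coords, centers = k, nstart = 1,
                                      iter.max = 50))
        n * log(km$tot.withinss / n) + k * log(n)
      }, numeric(1))
      tibble(run = r, k = k_range, bic = bic)
    })
  })
  runs <- bind_rows(runs)
  best <- runs %>%
    group_by(.data$run) %>%
    summarise(k = .data$k[which.min(.data$bic)], .groups = "drop")
  modal_k <- modal_min(best$k)
  clusters <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    best_km <- NULL
    for (rep in 1:10) {
      km <- suppressWarnings(kmeans(coords, centers = modal_k, nstart = 1,
                                    iter.max = 50))
      if (is.null(best_km) || km$tot.withinss < best_km$tot.withinss) best_km <- km
    }
    setNames(best_km$cluster, rownames(coords))
  })
  structure(
    list(runs = runs, best_k = best, modal_k = modal_k,
         k_range = k_range, n_runs = as.integer(n_runs), seed = seed,
         clusters = clusters),
    class = "kscan"
  )
}

scan_coords <- function(x, variance_target = 0.95) {
  if (inherits(x, "pheno_pca")) return(x$coords)
  if (is_tibble(x) || is.data.frame(x)) {
    pca <- pca_embed(x)
    return(pca$coords[, seq_len(pcs_for_variance(pca, variance_target)),
                      drop = FALSE])
  }
  as.matrix(x)
}

#' @export
print.kscan <- function(x, ...) {
  cat(sprintf("K-means/BIC scan: K in [%d, %d], %d runs; modal K = %d\n",
              min(x$k_range), max(x$k_range), x$n_runs, x$modal_k))
  invisible(x)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Fits linear discriminant axes to group labels on a reduced set of
#' principal components — the two-step construction that sidesteps both the
#' singularity of the raw binary matrix and any Hardy--Weinberg assumption,
#' which makes it usable on mixed-ploidy allele-phenotype data. Membership
#' probabilities are computed from squared Euclidean distances to the group
#' centroids in the sphered discriminant space via softmax normalisation
#' (equal priors), so each row sums to 1.
#'
#' @param x A `pheno_tbl`, `pheno_pca`, or coordinate matrix.
#' @param groups Group labels (named by individual, or in row order).
#' @param n_pc Number of PCs to retain (see [a_score_select()] for a
#'   data-driven choice). `NULL` keeps PCs covering 95% of the variance.
#' @param n_da Number of discriminant axes to report (default all, G - 1).
#' @return A `dapc` object: `n_pc`, `var_explained` (fraction of total
#'   variance carried by the retained PCs), `axes` (individual coordinates
#'   on the discriminant axes), `membership` (individuals x groups),
#'   `assignment` tibble, `groups`, `group_levels`.
#' @export
fit_dapc <- function(x, groups, n_pc = NULL, n_da = NULL) {
  prep <- dapc_coords(x, n_pc)
  coords <- prep$coords
  groups <- align_groups(groups, rownames(coords))
  g_levels <- unique(groups)
  if (length(g_levels) < 2L) abort("need at least two groups")
  scaling <- tryCatch(
    suppressWarnings(
      MASS::lda(coords, grouping = factor(groups, levels = g_levels))$scaling
    ),
    error = function(e) ridge_lda_scaling(coords, groups)
  )
  sph <- coords %*% scaling                # sphered discriminant space
  centroids <- rowsum(sph, groups)
  centroids <- centroids / as.vector(table(groups)[rownames(centroids)])
  centroids <- centroids[g_levels, , drop = FALSE]
  d2 <- outer(rowSums(sph^2), rep(1, nrow(centroids))) -
    2 * sph %*% t(centroids) +
    outer(rep(1, nrow(sph)), rowSums(centroids^2))
  logw <- -0.5 * d2
  logw <- logw - apply(logw, 1, max)
  membership <- exp(logw) / rowSums(exp(logw))
  colnames(membership) <- g_levels
  n_da_max <- ncol(sph)
  n_da <- if (is.null(n_da)) n_da_max else min(as.integer(n_da), n_da_max)
  structure(
    list(
      n_pc = prep$n_pc,
      var_explained = prep$var_explained,
      axes = sph[, seq_len(n_da), drop = FALSE],
      membership = membership,
      assignment = assign_members_impl(membership, 0.8),
      groups = setNames(groups, rownames(coords)),
      group_levels = g_levels
    ),
    class = "dapc"
  )
}

# Discriminant axes when the pooled within-group scatter is singular
# (perfectly separated groups): ridge-regularise W and solve the
# generalised eigenproblem directly, sphering axes to unit within-variance.
ridge_lda_scaling <- function(coords, groups) {
  g_levels <- unique(groups)
  centroids <- rowsum(coords, groups) / as.vector(table(groups)[unique(groups)])
  centroids <- centroids[g_levels, , drop = FALSE]
  centred <- coords - centroids[match(groups, g_levels), , drop = FALSE]
  W <- crossprod(centred) / max(nrow(coords) - length(g_levels), 1)
  ridge <- 1e-6 * mean(diag(W)) + 1e-10
  Wr <- W + diag(ridge, ncol(W))
  gm <- colMeans(coords)
  Bc <- sweep(centroids, 2, gm)
  B <- crossprod(Bc * sqrt(as.vector(table(groups)[g_levels]))) / nrow(coords)
  ev <- eigen(solve(Wr, B))
  n_axes <- min(length(g_levels) - 1L, ncol(coords))
  sc <- Re(ev$vectors[, seq_len(n_axes), drop = FALSE])
  # normalise so each axis has unit pooled within-group variance
  for (k in seq_len(ncol(sc))) {
    s <- sqrt(drop(t(sc[, k]) %*% Wr %*% sc[, k]))
    sc[, k] <- sc[, k] / s
  }
  sc
}

dapc_coords <- function(x, n_pc) {
  if (inherits(x, "pheno_pca")) {
    keep <- if (is.null(n_pc)) x$n_pc else min(as.integer(n_pc), x$n_pc)
    return(list(coords = x$coords[, seq_len(keep), drop = FALSE],
                n_pc = keep, var_explained = sum(x$explained[seq_len(keep)])))
  }
  if (is_tibble(x) || is.data.frame(x)) {
    pca <- pca_embed(x)
    keep <- if (is.null(n_pc)) pcs_for_variance(pca) else
      min(as.integer(n_pc), pca$n_pc)
    return(list(coords = pca$coords[, seq_len(keep), drop = FALSE],
                n_pc = keep, var_explained = sum(pca$explained[seq_len(keep)])))
  }
  mat <- as.matrix(x)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("i", seq_len(nrow(mat)))
  keep <- if (is.null(n_pc)) ncol(mat) else min(as.integer(n_pc), ncol(mat))
  list(coords = mat[, seq_len(keep), drop = FALSE], n_pc = keep,
       var_explained = NA_real_)
}

#' @export
print.dapc <- function(x, ...) {
  cat(sprintf("DAPC: %d PCs retained (%.1f%% of variance), %d groups, %d individuals\n",
              x$n_pc, 100 * x$var_explained, length(x$group_levels),
              nrow(x$membership)))
  wa <- mean(x$assignment$well_assigned)
  cat(sprintf("well-assigned (membership > 0.8): %.1f%%\n", 100 * wa))
  invisible(x)
}

assign_members_impl <- function(membership, threshold) {
  best <- max.col(membership, ties.method = "first")
  maxp <- membership[cbind(seq_len(nrow(membership)), best)]
  tibble(
    individual = rownames(membership),
    assigned = colnames(membership)[best],
    max_membership = maxp,
    well_assigned = maxp >= threshold,
    admixed = maxp < threshold
  )
}

#' Hard assignments and admixture flags from a DAPC fit
#'
#' The hard label is the membership argmax; an individual whose maximum
#' membership falls below `threshold` (default 0.8) is flagged admixed
#' rather than well assigned.
#'
#' @param result A `dapc` object.
#' @param threshold Membership probability cutoff in (0, 1].
#' @return Tibble: `individual`, `assigned`, `max_membership`,
#'   `well_assigned`, `admixed`.
#' @export
assign_members <- function(result, threshold = 0.8) {
  stopifnot(inherits(result, "dapc"))
  assert_scalar_prop(threshold, "threshold")
  assign_members_impl(result$membership, threshold)
}

#' a-score selection of the number of retained PCs
#'
#' Retaining too many PCs overfits the discriminant step (perfect
#' reassignment even for random labels). The a-score corrects observed
#' reassignment success by its permutation expectation:
#' \deqn{a(n_{pc}) = \mathrm{obs.\ reassignment} -
#'       \overline{\mathrm{reassignment\ under\ label\ permutation}},}
#' and the candidate maximising it is kept (ties to fewer PCs).
#'
#' @param x A `pheno_tbl` or `pheno_pca`.
#' @param groups Group labels.
#' @param candidates Integer vector of candidate `n_pc` values.
#' @param n_perm Label permutations per candidate (>= 1).
#' @param seed Integer seed.
#' @return An `a_score` object: `scores` tibble (`n_pc`, `observed`,
#'   `perm_mean`, `a_score`), `best_n_pc`.
#' @export
a_score_select <- function(x, groups, candidates, n_perm = 10, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (any(candidates < 1)) abort("n_pc = 0 has no discriminant space")
  pca <- if (inherits(x, "pheno_pca")) x else pca_embed(x)
  candidates <- sort(unique(pmin(as.integer(candidates), pca$n_pc)))
  groups <- align_groups(groups, rownames(pca$coords))
  reassign <- function(g, npc) {
    fit <- fit_dapc(pca, g, n_pc = npc)
    mean(fit$assignment$assigned == g)
  }
  scores <- with_seed(seed, {
    purrr::map(candidates, function(npc) {
      obs <- reassign(groups, npc)
      perm <- vapply(seq_len(n_perm), function(b) reassign(sample(groups), npc),
                     numeric(1))
      tibble(n_pc = npc, observed = obs, perm_mean = mean(perm),
             a_score = obs - mean(perm))
    })
  })
  scores <- bind_rows(scores)
  best <- scores$n_pc[which.max(scores$a_score)]  # first max = fewest PCs
  structure(list(scores = scores, best_n_pc = best), class = "a_score")
}

#' @export
print.a_score <- function(x, ...) {
  cat(sprintf("a-score selection: best n_pc = %d\n", x$best_n_pc))
  print(x$scores)
  invisible(x)
}
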