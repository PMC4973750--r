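#' Two-level distance-based AMOVA with PhiPT
#'
#' Partitions molecular variance among and within groups directly from a
#' squared-distance decomposition, the formulation used for dominant/binary
#' data where allele frequencies are unavailable. With \eqn{N} individuals in
#' \eqn{G} groups and squared distances \eqn{d^2_{ij}}:
#' \deqn{SS_{total} = \frac{1}{N}\sum_{i<j} d^2_{ij}, \qquad
#'       SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij},}
#' \eqn{SS_{among} = SS_{total} - SS_{within}}; degrees of freedom are
#' \eqn{G-1} and \eqn{N-G}. The within variance component is
#' \eqn{\sigma^2_W = MS_W} and the among component
#' \eqn{\sigma^2_A = (MS_A - MS_W)/n_0} with
#' \eqn{n_0 = (N - \sum_g n_g^2/N)/(G-1)}; a negative among component is
#' clamped to zero (the usual convention). PhiPT, the Fst analogue for
#' binary data, is \eqn{\sigma^2_A / (\sigma^2_A + \sigma^2_W)}. Its
#' significance is assessed by permuting individuals across groups; the
#' p-value uses the add-one estimator \eqn{(b+1)/(m+1)} so it can never be
#' exactly zero.
#'
#' @param dd A `dice_dist` (or a symmetric numeric matrix with dimnames).
#' @param groups Group labels: a named vector/factor over individuals, or an
#'   unnamed vector in matrix order.
#' @param n_perm Number of label permutations (conventionally 1000).
#' @param seed Integer seed for the permutations.
#' @return An `amova` object with fields `table` (df/SS/MS tibble),
#'   `sigma2_among`, `sigma2_within`, `percent_among`, `percent_within`,
#'   `phipt`, `p_value`, `n_perm`, `seed`, `n`, `groups`.
#' @export
amova <- function(dd, groups, n_perm = 1000, seed = NULL) {
  d <- distance_matrix_of(dd)
  groups <- align_groups(groups, rownames(d))
  sizes <- table(groups)
  if (any(sizes < 2)) {
    abort(sprintf("group(s) with fewer than 2 individuals: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  if (anyNA(d)) abort("distance matrix contains incomparable (NA) pairs")
  d2 <- d^2
  obs <- amova_components(d2, groups)
  perm_phipt <- numeric(0)
  if (n_perm >= 1) {
    perm_phipt <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        amova_components(d2, sample(groups))$phipt
      }, numeric(1))
    })
  }
  p <- (sum(perm_phipt >= obs$phipt) + 1) / (length(perm_phipt) + 1)
  structure(
    c(obs, list(p_value = p, n_perm = as.integer(n_perm), seed = seed,
                n = length(groups), groups = groups)),
    class = "amova"
  )
}

# core SS decomposition; d2 = squared distances, groups aligned to rows
amova_components <- function(d2, groups) {
  n <- nrow(d2)
  g_levels <- unique(as.character(groups))
  g <- length(g_levels)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  sizes <- numeric(g)
  for (k in seq_len(g)) {
    idx <- which(groups == g_levels[k])
    sizes[k] <- length(idx)
    block <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(block[upper.tri(block)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  df_a <- g - 1L
  df_w <- n - g
  ms_a <- ss_among / df_a
  ms_w <- ss_within / df_w
  n0 <- (n - sum(sizes^2) / n) / df_a
  sigma2_w <- ms_w
  sigma2_a <- max((ms_a - ms_w) / n0, 0)
  total_var <- sigma2_a + sigma2_w
  phipt <- if (total_var > 0) sigma2_a / total_var else 0
  list(
    table = tibble(
      source = c("among groups", "within groups", "total"),
      df = c(df_a, df_w, n - 1L),
      ss = c(ss_among, ss_within, ss_total),
      ms = c(ms_a, ms_w, NA_real_)
    ),
    sigma2_among = sigma2_a,
    sigma2_within = sigma2_w,
    percent_among = if (total_var > 0) 100 * sigma2_a / total_var else 0,
    percent_within = if (total_var > 0) 100 * sigma2_w / total_var else 100,
    phipt = phipt
  )
}

distance_matrix_of <- function(dd) {
  d <- if (inherits(dd, "dice_dist")) dd$d else as.matrix(dd)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("i", seq_len(nrow(d)))
  if (nrow(d) != ncol(d)) abort("distance matrix must be square")
  d
}

align_groups <- function(groups, ids) {
  g <- as.character(if (is.factor(groups)) as.character(groups) else groups)
  if (!is.null(names(groups))) {
    idx <- match(ids, names(groups))
    if (anyNA(idx)) {
      abort(sprintf("no group label for individual(s): %s",
                    paste(ids[is.na(idx)], collapse = ", ")))
    }
    g <- g[idx]
  } else if (length(g) != length(ids)) {
    abort("unnamed `groups` must match the distance matrix order and length")
  }
  if (anyNA(g)) abort("group labels must not be NA")
  g
}

#' @export
print.amova <- function(x, ...) {
  cat(sprintf("AMOVA over %d individuals in %d groups\n",
              x$n, length(unique(x$groups))))
  print(x$table)
  cat(sprintf("PhiPT = %.4f  (%% among = %.1f, %% within = %.1f), p = %.4g [%d permutations]\n",
              x$phipt, x$percent_among, x$percent_within, x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise PhiPT between all group pairs
#'
#' Each group pair is analysed in isolation (only its members' distances
#' enter) and permutations shuffle labels within the two groups concerned
#' only. Raw p-values are reported; significance stars follow the
#' two-threshold convention often used for these matrices (`**` for p <=
#' 0.002, `*` for p <= 0.005 by default). An optional Bonferroni adjustment
#' over the pairs is available but off by default.
#'
#' @inheritParams amova
#' @param star_thresholds Two descending p cutoffs for `**` and `*`.
#' @param bonferroni Adjust p-values for the number of pairs.
#' @return A `pairwise_phipt` object: tibble with `group_1`, `group_2`,
#'   `phipt`, `p_value`, `stars`, plus `phipt_matrix` and `p_matrix`
#'   attributes (symmetric, groups in first-appearance order).
#' @export
pairwise_phipt <- function(dd, groups, n_perm = 1000, seed = NULL,
                           star_thresholds = c(0.002, 0.005),
                           bonferroni = FALSE) {
  d <- distance_matrix_of(dd)
  groups <- align_groups(groups, rownames(d))
  g_levels <- unique(groups)
  if (length(g_levels) < 2L) abort("need at least two groups")
  pairs <- utils::combn(g_levels, 2L, simplify = FALSE)
  rows <- purrr::map(seq_along(pairs), function(pi) {
    pr <- pairs[[pi]]
    idx <- which(groups %in% pr)
    sub_seed <- if (is.null(seed)) NULL else (as.integer(seed) + pi) %% 2147483629L
    fit <- amova(d[idx, idx, drop = FALSE], groups[idx],
                 n_perm = n_perm, seed = sub_seed)
    tibble(group_1 = pr[1], group_2 = pr[2],
           phipt = fit$phipt, p_value = fit$p_value)
  })
  out <- bind_rows(rows)
  if (bonferroni) out$p_value <- pmin(out$p_value * nrow(out), 1)
  out$stars <- dplyr::case_when(
    out$p_value <= star_thresholds[1] ~ "**",
    out$p_value <= star_thresholds[2] ~ "*",
    TRUE ~ ""
  )
  pm <- matrix(0, length(g_levels), length(g_levels),
               dimnames = list(g_levels, g_levels))
  pv <- pm
  diag(pv) <- NA_real_
  for (r in seq_len(nrow(out))) {
    pm[out$group_1[r], out$group_2[r]] <- pm[out$group_2[r], out$group_1[r]] <- out$phipt[r]
    pv[out$group_1[r], out$group_2[r]] <- pv[out$group_2[r], out$group_1[r]] <- out$p_value[r]
  }
  attr(out, "phipt_matrix") <- pm
  attr(out, "p_matrix") <- pv
  class(out) <- c("pairwise_phipt", class(out))
  out
}

#' Mean pairwise differentiation (MPD) per group
#'
#' A group's MPD is the mean of its pairwise PhiPT values against all other
#' groups — its differentiation relative to the rest of the collection —
#' reported with the standard deviation over those pairs.
#'
#' @param pw A `pairwise_phipt` result.
#' @return Tibble: `group`, `mpd`, `sd`, `n_other`.
#' @export
mpd <- function(pw) {
  pm <- attr(pw, "phipt_matrix")
  if (is.null(pm)) abort("`pw` must come from pairwise_phipt()")
  gl <- rownames(pm)
  rows <- purrr::map(seq_along(gl), function(k) {
    vals <- pm[k, -k]
    tibble(group = gl[k], mpd = mean(vals),
           sd = if (length(vals) > 1) sd(vals) else NA_real_,
           n_other = length(vals))
  })
  bind_rows(rows)
}

#' Normalised within-group sum of squares (nSSWG)
#'
#' Within-group sum of squares (from squared distances) divided by the group
#' size: an index of intragroup variability comparable across groups of
#' different sizes. Singleton groups score 0.
#'
#' @inheritParams amova
#' @return Tibble: `group`, `n`, `nsswg`.
#' @export
nsswg <- function(dd, groups) {
  d <- distance_matrix_of(dd)
  groups <- align_groups(groups, rownames(d))
  d2 <- d^2
  g_levels <- unique(groups)
  rows <- purrr::map(g_levels, function(g) {
    idx <- which(groups == g)
    block <- d2[idx, idx, drop = FALSE]
    ssw <- sum(block[upper.tri(block)]) / length(idx)
    tibble(group = g, n = length(idx), nsswg = ssw / length(idx))
  })
  bind_rows(rows)
}

#' Pearson's chi-square test of independence between two labelings
#'
#' Cross-tabulates two categorical labelings of the same individuals
#' (pairwise-complete: rows where either label is unknown are dropped) and
#' applies the standard Pearson test without continuity correction — the
#' device used to ask whether inferred genetic groups are linked to
#' collection covariates (ploidy, origin, breeding period, ...).
#'
#' @param labels_a,labels_b Equal-length label vectors; `NA` = unknown.
#' @return Tibble: `statistic`, `df`, `p_value`, `n_used`.
#' @export
chi2_independence <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("labelings must cover the same individuals")
  }
  keep <- !is.na(labels_a) & !is.na(labels_b)
  tab <- table(labels_a[keep], labels_b[keep])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort("contingency table is degenerate (fewer than 2 levels on one side)")
  }
  fit <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = unname(fit$p.value), n_used = sum(keep))
}
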