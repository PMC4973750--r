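# broom-style tidiers for the package's result objects

#' Tidy a Dice distance matrix into a pairwise tibble
#'
#' @param x A `dice_dist`.
#' @param ... Unused.
#' @return Tibble: `individual_1`, `individual_2`, `distance`, `loci_used`,
#'   and bootstrap `support_mean`/`support_sd` when present.
#' @export
tidy.dice_dist <- function(x, ...) {
  n <- length(x$individuals)
  ut <- which(upper.tri(x$d), arr.ind = TRUE)
  out <- tibble(
    individual_1 = x$individuals[ut[, 1]],
    individual_2 = x$individuals[ut[, 2]],
    distance = x$d[ut],
    loci_used = x$loci_used[ut]
  )
  if (!is.null(x$boot)) {
    out$support_mean <- x$boot$mean[ut]
    out$support_sd <- x$boot$sd[ut]
  }
  out
}

#' @rdname tidy.dice_dist
#' @export
glance.dice_dist <- function(x, ...) {
  vals <- x$d[upper.tri(x$d)]
  tibble(n_individuals = length(x$individuals),
         n_pairs = length(vals),
         mean_distance = mean(vals, na.rm = TRUE),
         max_distance = max(vals, na.rm = TRUE),
         n_incomparable = nrow(x$incomparable))
}

#' Tidy an AMOVA variance partition
#'
#' @param x An `amova`.
#' @param ... Unused.
#' @return The df/SS/MS table with variance components and percentages.
#' @export
tidy.amova <- function(x, ...) {
  x$table %>%
    mutate(
      sigma2 = c(x$sigma2_among, x$sigma2_within, NA_real_),
      percent = c(x$percent_among, x$percent_within, NA_real_)
    )
}

#' @rdname tidy.amova
#' @export
glance.amova <- function(x, ...) {
  tibble(phipt = x$phipt, p_value = x$p_value,
         percent_among = x$percent_among, percent_within = x$percent_within,
         n = x$n, n_groups = length(unique(x$groups)), n_perm = x$n_perm)
}

#' Tidy a K-means/BIC scan
#'
#' @param x A `kscan`.
#' @param ... Unused.
#' @return Per-run, per-K BIC values.
#' @export
tidy.kscan <- function(x, ...) x$runs

#' @rdname tidy.kscan
#' @export
glance.kscan <- function(x, ...) {
  tibble(modal_k = x$modal_k, n_runs = x$n_runs,
         k_min = min(x$k_range), k_max = max(x$k_range))
}

#' Tidy a DAPC fit into long membership probabilities
#'
#' @param x A `dapc`.
#' @param ... Unused.
#' @return Tibble: `individual`, `group`, `membership`.
#' @export
tidy.dapc <- function(x, ...) {
  m <- x$membership
  tibble(
    individual = rep(rownames(m), times = ncol(m)),
    group = rep(colnames(m), each = nrow(m)),
    membership = as.vector(m)
  )
}

#' @rdname tidy.dapc
#' @export
glance.dapc <- function(x, ...) {
  tibble(n_pc = x$n_pc, var_explained = x$var_explained,
         n_groups = length(x$group_levels),
         n = nrow(x$membership),
         fraction_well_assigned = mean(x$assignment$well_assigned))
}
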