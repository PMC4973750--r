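# ggplot2 visualisations for the main result types

#' Plot a K-means/BIC scan
#'
#' Per-run BIC curves (thin lines) with the across-run mean highlighted and
#' the modal K marked — the visual that backs the choice of the number of
#' genetic groups.
#'
#' @param object A `kscan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kscan <- function(object, ...) {
  mean_bic <- object$runs %>%
    group_by(k = .data$k) %>%
    summarise(bic = mean(.data$bic), .groups = "drop")
  ggplot2::ggplot(object$runs, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$run), alpha = 0.15) +
    ggplot2::geom_line(data = mean_bic, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$modal_k, linetype = "dashed") +
    ggplot2::labs(x = "K (number of groups)", y = "BIC",
                  title = sprintf("K-means/BIC scan (modal K = %d over %d runs)",
                                  object$modal_k, object$n_runs)) +
    ggplot2::theme_minimal()
}

#' Plot the first two discriminant axes of a DAPC fit
#'
#' Individuals on discriminant axes 1--2, coloured by group; well-assigned
#' individuals (membership above the threshold) are filled, admixed ones
#' hollow.
#'
#' @param object A `dapc`.
#' @param threshold Membership cutoff used for the fill.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dapc <- function(object, threshold = 0.8, ...) {
  asg <- assign_members(object, threshold)
  df <- tibble(
    individual = rownames(object$axes),
    LD1 = object$axes[, 1],
    LD2 = if (ncol(object$axes) >= 2) object$axes[, 2] else 0,
    group = object$groups[rownames(object$axes)],
    well_assigned = asg$well_assigned[match(rownames(object$axes),
                                            asg$individual)]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$LD1, y = .data$LD2,
                                   colour = .data$group,
                                   shape = .data$well_assigned)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "Discriminant axis 1", y = "Discriminant axis 2",
                  shape = sprintf("membership > %.2g", threshold)) +
    ggplot2::theme_minimal()
}

#' Plot allele-frequency trajectories across classes
#'
#' Boxplots of per-allele carriage frequencies by class — the display used
#' to visualise the progressive rise (or fall) of pool-specific alleles
#' over breeding periods.
#'
#' @param object A `trajectories` tibble from [frequency_trajectories()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectories <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$frequency)),
                  ggplot2::aes(x = .data$class, y = .data$frequency)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "carriage frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
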