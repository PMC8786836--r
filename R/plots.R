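# ggplot2 visualisations for the main result types.

#' @describeIn apply_cell_filters Waterfall plot of cells removed per rule.
#' @param object A `qc_ledger`.
#' @param ... Unused.
#' @export
autoplot.qc_ledger <- function(object, ...) {
  df <- as_tibble(object)
  df$rule <- factor(df$rule, levels = rev(df$rule))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$removed, y = .data$rule)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cells removed", y = NULL,
                  title = sprintf("QC ledger: %d → %d cells",
                                  attr(object, "starting_count"),
                                  attr(object, "final_count"))) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_pca_mp Scree plot with the Marchenko-Pastur bound.
#' @param object A `pca_mp`.
#' @export
autoplot.pca_mp <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue,
                                   colour = .data$retained)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$mp_bound, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey50")) +
    ggplot2::labs(x = "component", y = "eigenvalue",
                  title = sprintf("%d component(s) above MP bound %.3g",
                                  object$retained, object$mp_bound)) +
    ggplot2::theme_minimal()
}

#' @describeIn abundance_ci Forest plot of per-cluster log fold changes.
#' @param object An `abundance_estimate` tibble.
#' @param ... Unused.
#' @export
autoplot.abundance_estimate <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$cluster,
                                   colour = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "grey60")) +
    ggplot2::labs(x = "log fold change (KO vs control)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn stage_correlate Correlation-by-bin profile per genotype.
#' @param object A `stage_assignment` tibble.
#' @param ... Unused.
#' @export
autoplot.stage_assignment <- function(object, ...) {
  df <- as_tibble(object)
  df$bin_num <- as.numeric(factor(df$bin, levels = unique(df$bin)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_num, y = .data$correlation,
                                   colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$top2), size = 2.5) +
    ggplot2::labs(x = "pseudotime bin", y = "rank correlation") +
    ggplot2::theme_minimal()
}

#' Histogram of cluster-specificity (tau) by peak annotation
#'
#' @param tau Tibble from [tau_index()].
#' @param annotation Optional per-feature annotation factor (e.g. promoter /
#'   distal) to facet by.
#' @return A ggplot object.
#' @export
plot_tau_distribution <- function(tau, annotation = NULL) {
  df <- as_tibble(tau)
  if (!is.null(annotation)) df$annotation <- annotation
  p <- ggplot2::ggplot(dplyr::filter(df, !is.na(.data$tau)),
                       ggplot2::aes(x = .data$tau)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
    ggplot2::labs(x = expression(tau), y = "peaks") +
    ggplot2::theme_minimal()
  if (!is.null(annotation)) p <- p + ggplot2::facet_wrap(~annotation, scales = "free_y")
  p
}
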