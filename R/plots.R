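#' Plot per-cell X:A expressed-gene ratios across cell types
#'
#' @param stats Output of [cell_xa_stats()].
#' @param metric Column to plot (`expressed_ratio` or `cpm_xa_ratio`).
#' @return A ggplot.
#' @export
plot_xa_ratio <- function(stats, metric = "expressed_ratio") {
  ggplot2::ggplot(stats, ggplot2::aes(
    x = factor(.data$cell_type, levels = unique(.data$cell_type)),
    y = .data[[metric]], colour = .data$genotype
  )) +
    ggplot2::geom_jitter(width = 0.25, size = 0.4, alpha = 0.4) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.dosage_result <- function(object, ...) {
  ggplot2::ggplot(object$per_gene, ggplot2::aes(
    x = factor(.data$cell_type, levels = unique(.data$cell_type)),
    y = .data$log2_xa, fill = .data$genotype
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = -1, linetype = 3) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = "log2(X:A)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}

#' Volcano plot of differential-expression results
#'
#' @param de Tibble from [de_analysis()].
#' @return A ggplot.
#' @export
plot_de_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(
    x = .data$log2fc, y = -log10(pmax(.data$fdr, 1e-300)),
    colour = .data$direction
  )) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::labs(x = "log2 fold change (SR vs ST)", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.resampling_null <- function(object, ...) {
  ggplot2::ggplot(object$percents, ggplot2::aes(
    x = .data$chrom_class, y = .data$percent_de
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "% genes differentially expressed",
                  title = object$design) +
    ggplot2::theme_minimal()
}

#' Plot ploidy calls per cell type
#'
#' @param calls Output of [classify_ploidy()] joined to cell metadata
#'   (needs a `cell_type` column).
#' @return A ggplot.
#' @export
plot_ploidy <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$cell_type,
                                      fill = .data$call)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = NULL, y = "cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
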