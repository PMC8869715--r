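#' Volcano plot of a differential-expression result
#'
#' @param de A `de_fit` or tidy DE table (classified).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_volcano <- function(de, ...) {
  tab <- de_table(de)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2FC,
                                    y = -log10(.data$p_value),
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' MA plot of a differential-expression result
#'
#' @inheritParams plot_volcano
#' @export
plot_ma <- function(de, ...) {
  tab <- de_table(de)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean_expression, y = .data$log2FC,
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey70")) +
    ggplot2::labs(x = "mean expression (log2)", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.de_fit <- function(object, ...) plot_volcano(object, ...)

#' Scatter plot of paired log2 fold changes
#'
#' @param paired Output of [compare_log2fc()].
#' @param lfc_cutoff Position of the dotted fold-change guide lines
#'   (default 1).
#' @return A ggplot.
#' @export
plot_log2fc_comparison <- function(paired, lfc_cutoff = 1) {
  ggplot2::ggplot(paired, ggplot2::aes(x = .data$log2FC_a, y = .data$log2FC_b,
                                       colour = .data$concordance)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = c(-lfc_cutoff, lfc_cutoff), linetype = 3) +
    ggplot2::geom_vline(xintercept = c(-lfc_cutoff, lfc_cutoff), linetype = 3) +
    ggplot2::scale_colour_manual(values = c(concordant_up = "firebrick",
                                            concordant_down = "steelblue",
                                            discordant = "darkorange",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2FC (matrix A)", y = "log2FC (matrix B)") +
    ggplot2::theme_minimal()
}
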