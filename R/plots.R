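# ggplot2 helpers for the main result types.

#' Volcano plot of a contrast table
#'
#' @param contrasts A `tmt_contrasts` tibble (one or more contrasts; facets
#'   when several).
#' @param alpha Significance cutoff drawn from `rule`.
#' @param rule `"q"` or `"p"`.
#' @return A ggplot object.
#' @export
plot_volcano <- function(contrasts, alpha = 0.05, rule = c("q", "p")) {
  rule <- match.arg(rule)
  crit <- if (rule == "q") contrasts$q else contrasts$p
  df <- contrasts |>
    mutate(significant = crit < alpha & .data$log2fc > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                        y = -log10(.data$p),
                                        colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = sprintf("%s < %g & log2FC > 0", rule, alpha)) +
    ggplot2::theme_minimal()
  if (length(unique(df$contrast)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$contrast))
  }
  p
}

#' @export
autoplot.qc_mds <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mds1, y = .data$mds2,
                                       colour = .data$condition,
                                       label = .data$sample)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "leading log2FC dim 1", y = "leading log2FC dim 2") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qc_cv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$condition, y = .data$cv)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "%CV of log2 abundance") +
    ggplot2::theme_minimal()
}

#' Heatmap-style tile plot of pairwise replicate correlations
#' @param object A `qc_correlation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_correlation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample_x,
                                       y = .data$sample_y,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
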