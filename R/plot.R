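# ggplot2 views of the result types. These are thin layers over the exactly
# specified data tables in report.R; tests target the tables, not the plots.

#' Volcano plot of a differential-expression result
#'
#' @param object An `nrx_dge` tibble.
#' @param ... Passed to [volcano_table()] (e.g. `fdr_threshold`).
#' @return A ggplot object.
#' @export
autoplot.nrx_dge <- function(object, ...) {
  tab <- volcano_table(object, ...)
  tab$status <- ifelse(tab$significant, tab$direction, "ns")
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2fc, .data$neg_log10_p,
                                    colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "red", down = "blue", ns = "grey60"),
                                 na.value = "grey60") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = unique(object$contrast)) +
    ggplot2::theme_minimal()
}

#' Ranked scatter of log10 cumulative ranks
#'
#' @param object An `nrx_cumrank` tibble.
#' @param top_n Number of top genes to label.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.nrx_cumrank <- function(object, top_n = 10, ...) {
  df <- object
  df$index <- seq_len(nrow(df))
  lab <- df[seq_len(min(top_n, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$log10_cumulative_rank)) +
    ggplot2::geom_point(size = 0.5, colour = "grey40") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$gene_id),
                       hjust = -0.15, size = 2.8) +
    ggplot2::labs(x = "genes (sorted)", y = "log10 cumulative rank") +
    ggplot2::theme_minimal()
}

#' Heatmap of expression values with the hybrid colour scale
#'
#' Rows are ordered by [sort_rows_by_angle()] and colours use the
#' linear-within-central-interval, ordinal-in-the-tails mapping of
#' [heatmap_scale()].
#'
#' @param expr Tibble (`gene_id` + samples) of values to plot (e.g. log-CPM).
#' @param central_fraction Passed to [heatmap_scale()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(expr, central_fraction = 0.98) {
  m <- count_matrix(expr, require_integer = FALSE, arg = "expr")
  ord <- sort_rows_by_angle(m)
  sc <- heatmap_scale(as.numeric(m), central_fraction = central_fraction)
  df <- tidyr::pivot_longer(as_count_tbl(m[ord, , drop = FALSE]),
                            -"gene_id", names_to = "sample_id",
                            values_to = "value")
  df$gene_id <- factor(df$gene_id, levels = rev(rownames(m)[ord]))
  df$colour_pos <- sc$map(df$value)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$gene_id,
                                   fill = .data$colour_pos)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled\nvalue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
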