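#' Plot the ranked relative fold changes of a screen report
#'
#' Bar chart of the cross-line mean RFC on the log2 scale, up-regulated
#' microRNAs to the right and down-regulated to the left.
#'
#' @param object A `screen_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_report <- function(object, ...) {
  d <- object$cross_line
  if (nrow(d) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no responsive microRNAs") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$log2_mean_rfc,
    y = stats::reorder(.data$mirna_id, .data$log2_mean_rfc),
    fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(object$criteria$fc_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 mean relative fold change", y = NULL,
                  fill = NULL, title = "Treatment-responsive microRNAs") +
    ggplot2::theme_minimal()
}

#' Plot a cell-cycle histogram with its fitted mixture
#'
#' @param object A `cellcycle_fit`.
#' @param ... Unused.
#' @return A ggplot object overlaying observed bin counts and the fitted
#'   G1/S/G2M mixture.
#' @export
autoplot.cellcycle_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dna_content)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "firebrick") +
    ggplot2::labs(x = "DNA content", y = "events",
                  title = sprintf("G1 %.0f%% / S %.0f%% / G2M %.0f%%",
                                  100 * object$fractions["g1"],
                                  100 * object$fractions["s"],
                                  100 * object$fractions["g2m"])) +
    ggplot2::theme_minimal()
}

#' Expression or fold-change heatmap with clustered samples
#'
#' Tile heatmap of log2 values with columns ordered by the correlation
#' dendrogram from [cluster_profiles()].
#'
#' @param norm Normalized long tibble from [normalize_log2()].
#' @param mirnas Optional subset of `mirna_id`s to display.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(norm, mirnas = NULL) {
  if (!is.null(mirnas)) norm <- dplyr::filter(norm, .data$mirna_id %in% mirnas)
  cl <- cluster_profiles(norm, input = "expression")
  norm$sample_id <- factor(norm$sample_id, levels = cl$leaf_order)
  ggplot2::ggplot(norm, ggplot2::aes(x = .data$sample_id, y = .data$mirna_id,
                                     fill = .data$log2_intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "green4", mid = "black", high = "red",
                                  midpoint = stats::median(norm$log2_intensity)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}
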