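#' Heatmap of a score matrix
#'
#' @param object A `dss_score_matrix`.
#' @param ... Unused.
#' @return A ggplot object (samples on rows, drugs on columns, tile fill =
#'   score).
#' @export
autoplot.dss_score_matrix <- function(object, ...) {
  long <- score_matrix_long(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$drug_id, y = .data$sample_id,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  midpoint = 0, na.value = "grey85",
                                  name = score_metric(object)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Waterfall plot of one sample's differential scores
#'
#' Drugs ordered by decreasing score for a given sample; positive bars are
#' cancer-selective responses, negative ones responses weaker than in the
#' control samples.
#'
#' @param x A `dss_score_matrix` (typically dDSS).
#' @param sample_id Which sample row to plot.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(x, sample_id) {
  stopifnot(inherits(x, score_matrix_class), sample_id %in% x$sample_id)
  long <- score_matrix_long(x)
  long <- long[long$sample_id == sample_id & !is.na(long$score), ]
  long$drug_id <- stats::reorder(long$drug_id, -long$score)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$drug_id, y = .data$score,
                                     fill = .data$score > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "navy")) +
    ggplot2::labs(x = NULL, y = score_metric(x), title = sample_id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
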