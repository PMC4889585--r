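#' @method autoplot size_distribution
#' @export
autoplot.size_distribution <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$proportion)),
                  ggplot2::aes(x = factor(.data$length), y = .data$proportion,
                               fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "read length (nt)", y = "proportion of window reads",
                  fill = "library") +
    ggplot2::theme_minimal()
}

#' Heatmap of a sample correlation matrix
#'
#' @param r Correlation matrix from [sample_correlation()].
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(r) {
  df <- tibble::as_tibble(as.data.frame.table(r, responseName = "r"))
  names(df)[1:2] <- c("sample_a", "sample_b")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0, limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "correlation") +
    ggplot2::theme_minimal()
}
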