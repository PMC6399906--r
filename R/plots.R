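#' Plot the distribution of pairwise similarity scores
#'
#' Bar plot of the binned upper-triangle scores, with the qualitative band
#' boundaries (0.1, 0.4, 0.7) marked.
#'
#' @param dist A tibble from [score_distribution()].
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$bin_left, y = .data$count)) +
    ggplot2::geom_col(
      width = dist$bin_right[1] - dist$bin_left[1],
      just = 0, fill = "steelblue"
    ) +
    ggplot2::geom_vline(
      xintercept = c(0.1, 0.4, 0.7),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "Lin similarity", y = "cell-type pairs",
      title = "Distribution of pairwise cell-type similarities"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a similarity matrix in clustered order
#'
#' @param matrix A `sim_matrix`.
#' @param clustering Optional `cell_clustering`; rows and columns are shown
#'   in its leaf order (computed with average linkage if omitted).
#' @return A ggplot object.
#' @export
plot_similarity_heatmap <- function(matrix, clustering = NULL) {
  if (is.null(clustering) && nrow(matrix) >= 2) {
    clustering <- cluster_cells(matrix)
  }
  ord <- if (is.null(clustering)) rownames(matrix) else clustering$order
  long <- tibble::as_tibble(as.data.frame(unclass(matrix)), rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "score") |>
    dplyr::mutate(
      row = factor(.data$row, levels = ord),
      col = factor(.data$col, levels = ord)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Lin sim") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Radar chart of prediction overlap ratios
#'
#' Polar plot of the two series from [radar_series()]: the network-side
#' ratios ("net map") and query-side ratios ("gene list map") over the
#' top-ranked candidate cell types.
#'
#' @param series A tibble from [radar_series()].
#' @return A ggplot object.
#' @export
plot_radar <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(
    x = .data$cell_id, y = .data$value,
    group = .data$series, colour = .data$series, fill = .data$series
  )) +
    ggplot2::geom_polygon(alpha = 0.2) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "overlap ratio") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sim_matrix <- function(object, ...) {
  plot_similarity_heatmap(object)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cell_prediction <- function(object, top_n = min(10, nrow(object)), ...) {
  plot_radar(radar_series(object, top_n = max(3, top_n)))
}
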