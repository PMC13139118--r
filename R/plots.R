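#' Plot trajectories
#'
#' Draws track polylines in image coordinates (y axis reversed to match
#' pixel row order), colored by track id.
#'
#' @param tracks Tibble with `track_id`, `frame`, `x`, `y`.
#' @param image_size Optional `c(height, width)` to fix the panel limits.
#'
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, image_size = NULL) {
  p <- ggplot(tracks, aes(x = .data$x, y = .data$y,
                          group = factor(.data$track_id),
                          color = factor(.data$track_id))) +
    geom_path(linewidth = 0.6) +
    geom_point(size = 0.8) +
    scale_y_reverse() +
    coord_fixed() +
    labs(x = "x (px)", y = "y (px)", color = "track") +
    theme_minimal()
  if (!is.null(image_size)) {
    p <- p + expand_limits(x = c(0, image_size[2] - 1),
                           y = c(0, image_size[1] - 1))
  }
  p
}

#' @rdname plot_tracks
#' @param object A `sim_output` or `tracking_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.sim_output <- function(object, ...) {
  plot_tracks(object$tracks, image_size = dim(object$frames[[1]])) +
    labs(title = "ground-truth trajectories")
}

#' @rdname plot_tracks
#' @param masks Labeled masks used to place the trajectory nodes (see
#'   [attach_positions()]); required for `tracking_result` objects.
#' @exportS3Method ggplot2::autoplot
autoplot.tracking_result <- function(object, masks = NULL, ...) {
  if (is.null(masks)) {
    stop("supply the labeled masks: autoplot(result, masks = masks)",
         call. = FALSE)
  }
  plot_tracks(attach_positions(object, masks)) +
    labs(title = paste("linked trajectories:", object$method))
}

#' Heatmap of one score matrix
#'
#' @param m A score matrix (rows = cells at `t`, columns = cells at
#'   `t + 1`).
#'
#' @return A ggplot object.
#' @export
plot_score_matrix <- function(m) {
  df <- tidyr::expand_grid(from = rownames(m), to = colnames(m))
  df$score <- as.vector(t(m))
  ggplot(df, aes(x = factor(.data$to, levels = colnames(m)),
                 y = factor(.data$from, levels = rev(rownames(m))),
                 fill = .data$score)) +
    geom_tile(color = "grey80") +
    geom_text(aes(label = sprintf("%.2f", .data$score)), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    labs(x = "cell at t + 1", y = "cell at t", fill = "score") +
    theme_minimal()
}

#' Boxplots of per-sequence tracking metrics across methods
#'
#' @param data Tibble with a `method` column and one numeric column per
#'   metric (as consumed by [compare_methods()]).
#' @param metrics Metric columns to show; default all numeric columns.
#'
#' @return A ggplot object (one facet per metric; triangles mark means).
#' @export
plot_method_comparison <- function(data, metrics = NULL) {
  if (is.null(metrics)) {
    metrics <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                       "method")
  }
  long <- tidyr::pivot_longer(data, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$method, y = .data$value)) +
    geom_boxplot(outlier.size = 0.8) +
    stat_summary(fun = mean, geom = "point", shape = 17, color = "darkgreen") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}
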