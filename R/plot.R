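#' Plot cell trajectories
#'
#' Draws each track as a path in µm, y axis flipped to match image
#' orientation. Short, confined trajectories (antigen-arrested cells)
#' contrast visually with long free-diffusion paths.
#'
#' @param tracks Tracks tibble ([track_spots()] output).
#' @param pixel_size_um Pixel size (µm/px).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(tracks, pixel_size_um = 1) {
  ggplot2::ggplot(tracks,
                  ggplot2::aes(x = .data$x_px * pixel_size_um,
                               y = .data$y_px * pixel_size_um,
                               group = .data$track_id,
                               colour = factor(.data$track_id))) +
    ggplot2::geom_path(alpha = 0.8, show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Violin plot of contact-episode durations
#'
#' @param episodes Episodes tibble with `duration_min` and a `condition`
#'   column (added if absent).
#' @return A ggplot object.
#' @export
plot_episode_durations <- function(episodes) {
  if (!"condition" %in% names(episodes)) episodes$condition <- "all"
  ggplot2::ggplot(episodes,
                  ggplot2::aes(x = .data$condition, y = .data$duration_min,
                               fill = .data$condition)) +
    ggplot2::geom_violin(show.legend = FALSE, scale = "width") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8,
                         show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "contact duration (min)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_trajectories
#' @param object A `caf_pipeline_result`.
#' @param ... Unused.
#' @method autoplot caf_pipeline_result
#' @export
autoplot.caf_pipeline_result <- function(object, ...) {
  plot_trajectories(object$tracks, object$pixel_size_um)
}

#' @rdname plot_episode_durations
#' @param object A `caf_simulation`.
#' @param ... Unused.
#' @method autoplot caf_simulation
#' @export
autoplot.caf_simulation <- function(object, ...) {
  ep <- object$truth$episodes
  ep$condition <- object$truth$model$condition
  plot_episode_durations(ep)
}
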