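#' Speed-coded trajectory plot
#'
#' Draws the tracked path with segments colored by instantaneous speed, the
#' standard visualization of grooming stroke patterns.
#'
#' @param t A \code{paw_trajectory}.
#' @return A ggplot.
#' @export
plot_trajectory <- function(t) {
  d <- displacements(t)
  seg <- tibble::tibble(
    x = t$x[match(d$frame, t$frame)],
    y = t$y[match(d$frame, t$frame)],
    xend = .subset2(t, "x")[match(d$frame, t$frame) + 1],
    yend = .subset2(t, "y")[match(d$frame, t$frame) + 1],
    speed_mm_s = px_to_mm(d$step_px, .traj_px(t)) * .traj_fps(t)
  )
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                    xend = .data$xend, yend = .data$yend,
                                    color = .data$speed_mm_s)) +
    ggplot2::geom_segment() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_color_viridis_c(name = "speed (mm/s)") +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.paw_trajectory <- function(object, ...) plot_trajectory(object)

#' Occupancy map plot
#'
#' Visit-count raster showing how much time each paw spent over each
#' location of the enclosure.
#'
#' @param t A \code{paw_trajectory}.
#' @param bin_px Spatial bin side, pixels.
#' @return A ggplot.
#' @export
plot_occupancy <- function(t, bin_px = 2) {
  occ <- occupancy_map(t, bin_px)
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$bin_x, y = .data$bin_y,
                                    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "visits") +
    ggplot2::labs(x = sprintf("x (%g px bins)", bin_px),
                  y = sprintf("y (%g px bins)", bin_px)) +
    ggplot2::theme_minimal()
}
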