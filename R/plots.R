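#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline geom_vline labs theme_minimal scale_color_viridis_c
#'   coord_polar annotate scale_x_log10 scale_y_log10
#' @export
ggplot2::autoplot

#' Plot a radial profile as intensity-versus-radius lines
#'
#' One line per channel, mean bin intensity against bin-center radius —
#' the familiar center-to-edge profile view.
#'
#' @param object A `radial_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(radius_um = (.data$bin_start_um + .data$bin_end_um) / 2)
  ylab <- switch(unique(df$normalization),
                 raw = "mean intensity (a.u.)",
                 hoechst_relative = "intensity / Hoechst",
                 "relative intensity (max = 100)")
  ggplot(df, aes(x = .data$radius_um, y = .data$mean_intensity,
                 colour = .data$channel)) +
    geom_line(na.rm = TRUE) +
    labs(x = "distance from colony center (µm)", y = ylab,
         colour = NULL) +
    theme_minimal()
}

#' Plot a colony height profile
#'
#' @param object A `height_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot height_profile
#' @export
autoplot.height_profile <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      radius_um = (.data$bin_start_um +
                                     .data$bin_end_um) / 2)
  ggplot(df, aes(x = .data$radius_um, y = .data$height_um)) +
    geom_line() + geom_point() +
    labs(x = "distance from colony center (µm)",
         y = "colony height (µm)") +
    theme_minimal()
}

#' Density-coloured coexpression scatter with gate quadrants
#'
#' Each dot is one voxel, coloured by local point density; dashed lines
#' mark the gates and the corners are annotated with quadrant
#' percentages.
#'
#' @param pairs Tibble from [voxel_pairs()].
#' @param gate Optional `gate_result` for threshold lines and quadrant
#'   labels.
#' @param subsample Maximum number of dots drawn (default 50000).
#' @return A ggplot object.
#' @export
plot_coexpression <- function(pairs, gate = NULL, subsample = 5e4) {
  ch <- attr(pairs, "channels")
  if (nrow(pairs) > subsample) {
    keep <- unique(round(seq(1, nrow(pairs), length.out = subsample)))
    pairs <- pairs[keep, ]
  }
  p <- ggplot(pairs, aes(x = .data$a + 1, y = .data$b + 1,
                         colour = .data$density)) +
    geom_point(size = 0.3, alpha = 0.6) +
    scale_x_log10() + scale_y_log10() +
    scale_color_viridis_c(trans = "log10") +
    labs(x = paste(ch[["a"]], "(a.u.)"), y = paste(ch[["b"]], "(a.u.)"),
         colour = "voxel density") +
    theme_minimal()
  if (!is.null(gate)) {
    q <- gate$quadrants
    p <- p +
      geom_vline(xintercept = gate$thresholds[["a"]] + 1,
                 linetype = "dashed") +
      geom_hline(yintercept = gate$thresholds[["b"]] + 1,
                 linetype = "dashed") +
      labs(subtitle = paste(
        sprintf("%s %.1f%%", q$quadrant, q$percent), collapse = "  "))
  }
  p
}

#' Average-colony dot plot of positional marker expression
#'
#' Each detected cell is one dot placed at its colony position and
#' coloured by its fluorescence in the chosen channel; pooling cells
#' from multiple colonies reconstructs the average spatial pattern.
#'
#' @param dots Tibble from [dot_summary()].
#' @param channel Channel whose intensity colours the dots.
#' @return A ggplot object.
#' @export
plot_dot_summary <- function(dots, channel) {
  ggplot(dots, aes(x = .data$radius_um * cos(.data$angle_rad),
                   y = .data$radius_um * sin(.data$angle_rad),
                   colour = .data[[channel]])) +
    geom_point(size = 0.8) +
    scale_color_viridis_c() +
    ggplot2::coord_fixed() +
    labs(x = "x (µm)", y = "y (µm)", colour = channel) +
    theme_minimal()
}
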