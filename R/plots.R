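#' Plot a line profile with cutoff and signal peaks
#'
#' Intensity versus sample position for each channel, with the signal
#' cutoff drawn as a horizontal line and supra-cutoff runs shaded — the way
#' contact-site profiles are conventionally presented.
#'
#' @param object A `line_profile` from [extract_line_profile()].
#' @param cutoff Signal cutoff to annotate (8-bit units).
#' @param channels Optional subset of channel names to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.line_profile <- function(object, cutoff = 100, channels = NULL, ...) {
  tb <- as_tibble(object)
  if (!is.null(channels)) tb <- filter(tb, .data$channel %in% channels)
  peaks <- tb |>
    group_by(.data$channel) |>
    dplyr::group_modify(function(d, key) {
      p <- find_signal_peaks(d$intensity[order(d$sample_idx)], cutoff)
      p
    }) |>
    ungroup()
  gg <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$sample_idx,
                                         y = .data$intensity,
                                         colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "sample along line (px)", y = "intensity (8-bit)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(peaks) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = peaks, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = .data$start_idx - 0.5, xmax = .data$end_idx - 0.5,
                   ymin = -Inf, ymax = Inf, fill = .data$channel))
  }
  gg
}

#' Plot per-cell marker-positive percentages of a run
#'
#' One point per cell with the batch mean, against the generator's true
#' fraction when available.
#'
#' @param object A `vesicoloc_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vesicoloc_run <- function(object, ...) {
  cs <- object$cell_summary
  ggplot2::ggplot(cs, ggplot2::aes(x = "batch", y = .data$pct_marker_positive)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3) +
    ggplot2::geom_hline(yintercept = mean(cs$true_pct_marker_positive),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = "marker-positive MVEs (%)",
                  subtitle = "dashed: ground-truth fraction") +
    ggplot2::theme_minimal()
}

#' Display a channel of an image stack
#'
#' Raster view of one plane with optional detection overlay.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index.
#' @param detections Optional tibble with `x`, `y` to overlay.
#' @param z Plane index.
#' @return A ggplot object.
#' @export
plot_channel <- function(stack, channel = 1, detections = NULL, z = 1) {
  m <- get_plane(stack, channel, z)
  tb <- tibble(
    x = rep(0:(ncol(m) - 1), each = nrow(m)),
    y = rep(0:(nrow(m) - 1), times = ncol(m)),
    intensity = as.vector(m)
  )
  gg <- ggplot2::ggplot(tb, ggplot2::aes(.data$x, .data$y,
                                         fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(detections) && nrow(detections) > 0) {
    gg <- gg + ggplot2::geom_point(
      data = detections, inherit.aes = FALSE, shape = 1, colour = "red",
      ggplot2::aes(.data$x, .data$y))
  }
  gg
}
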