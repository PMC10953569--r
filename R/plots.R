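# ggplot2 figure builders. All plots render already-computed tables; none
# recompute statistics.

#' Raster plot of a spike-train set
#'
#' @param spikes an `mea_spikes` object.
#' @return a ggplot; x spans the full recording duration.
#' @export
plot_raster <- function(spikes) {
  ids <- attr(spikes, "channel_ids")
  df <- tibble::as_tibble(spikes)
  if (nrow(df) == 0) warning("empty spike-train set: empty raster", call. = FALSE)
  df$channel <- factor(df$channel, levels = ids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$channel)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::scale_y_discrete(drop = FALSE) +
    ggplot2::xlim(0, attr(spikes, "duration")) +
    ggplot2::labs(x = "time (s)", y = "channel") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mea_spikes <- function(object, ...) plot_raster(object)

#' Spatial firing heatmap
#'
#' @param fmap a [firing_map()] table (columns `x_um`, `y_um` and `value`).
#' @param value name of the value column (default `"rate_hz"`).
#' @return a ggplot with one marker per electrode at its layout coordinates.
#' @export
plot_firing_map <- function(fmap, value = "rate_hz") {
  if (nrow(fmap) == 0) warning("empty firing map", call. = FALSE)
  ggplot2::ggplot(fmap, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                     colour = .data[[value]])) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = value) +
    ggplot2::theme_minimal()
}

#' Box plot from precomputed box summaries
#'
#' @param summaries named list of [box_summary()] objects, one box per entry.
#' @return a ggplot whose glyphs reproduce the summary fields (box Q1-Q3,
#'   median line, 1.5 IQR whiskers clipped to the data, outlier points).
#' @export
plot_box <- function(summaries) {
  if (length(summaries) == 0) warning("no box summaries to plot", call. = FALSE)
  df <- purrr::imap(summaries, function(s, name) {
    tibble::tibble(group = name, median = s$median, q1 = s$q1, q3 = s$q3,
                   lo = s$whisker_low, hi = s$whisker_high)
  }) |> dplyr::bind_rows()
  outs <- purrr::imap(summaries, function(s, name) {
    if (length(s$outliers)) tibble::tibble(group = name, value = s$outliers)
    else NULL
  }) |> purrr::compact() |> dplyr::bind_rows()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$lo, lower = .data$q1, middle = .data$median,
                   upper = .data$q3, ymax = .data$hi),
      stat = "identity", width = 0.5) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
  if (nrow(outs %||% tibble::tibble()) > 0) {
    p <- p + ggplot2::geom_point(data = outs,
                                 ggplot2::aes(x = .data$group, y = .data$value),
                                 shape = 1)
  }
  p
}

#' Channel correlation-matrix heatmap
#'
#' @param corr an `mea_corr` from [correlation_matrix()].
#' @return a ggplot tile map of the pairwise correlations.
#' @export
plot_corr <- function(corr) {
  m <- unclass(corr)
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("channel_a", "channel_b", "r")
  if (nrow(df) == 0) warning("empty correlation matrix", call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel_a, y = .data$channel_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "blue",
                                  mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Overlaid waveform cutouts
#'
#' @param cutouts an `mea_cutouts` object.
#' @param units optional per-event unit labels (e.g. from [sort_spikes()]).
#' @return a ggplot of overlaid snippets against lag from the alignment
#'   extremum.
#' @export
plot_cutouts <- function(cutouts, units = NULL) {
  df <- tidy.mea_cutouts(cutouts)
  if (!is.null(units)) {
    df$unit <- factor(units[df$event])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s * 1000, y = .data$uv,
                                        group = .data$event)) +
    ggplot2::labs(x = "lag (ms)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
  if (is.null(units)) p + ggplot2::geom_line(alpha = 0.3)
  else p + ggplot2::geom_line(ggplot2::aes(colour = .data$unit), alpha = 0.4)
}
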