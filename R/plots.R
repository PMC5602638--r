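# ggplot2 displays for the main result types.

#' Plot a coverage track with called valleys
#'
#' @param track A (smoothed) coverage tibble for one chromosome or region.
#' @param valleys Optional valley-call tibble to overlay.
#' @param xlim Optional bp range to display.
#' @return A ggplot object.
#' @export
plot_valleys <- function(track, valleys = NULL, xlim = NULL) {
  if (!is.null(xlim)) {
    track <- filter(track, .data$pos >= xlim[1], .data$pos <= xlim[2])
    if (!is.null(valleys)) {
      valleys <- filter(valleys, .data$end > xlim[1], .data$start < xlim[2])
    }
  }
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "smoothed signal") +
    ggplot2::theme_minimal()
  if (!is.null(valleys) && nrow(valleys) > 0) {
    p <- p + ggplot2::geom_rect(
      data = valleys,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "darkgreen", alpha = 0.25)
  }
  p
}

#' Plot cluster median expression profiles with interquartile ribbons
#'
#' @param x A `tf_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_clusters <- function(x, ...) {
  ggplot2::ggplot(x$medians,
                  ggplot2::aes(x = .data$time, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$median - .data$iqr / 2,
                                      ymax = .data$median + .data$iqr / 2),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "time (h)", y = "median log2 fold change") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a motif score series against the cluster median expression
#'
#' Mirrors the standard display of a predicted regulator: the cluster-median
#' fold change (left axis) with the motif raw-score series (right axis,
#' rescaled) overlaid.
#'
#' @param series Score series tibble filtered to one motif and cluster.
#' @param medians Cluster medians (`cluster`, `time`, `median`) for the same
#'   cluster.
#' @return A ggplot object.
#' @export
plot_motif_series <- function(series, medians) {
  if (length(unique(series$motif_id)) != 1 ||
      length(unique(series$cluster)) != 1) {
    abort("`series` must contain exactly one motif/cluster combination")
  }
  rng_s <- range(series$raw_score, na.rm = TRUE)
  rng_m <- range(medians$median)
  if (diff(rng_s) == 0) rng_s <- rng_s + c(-0.5, 0.5)
  rescale <- function(v) {
    (v - rng_s[1]) / diff(rng_s) * diff(rng_m) + rng_m[1]
  }
  ggplot2::ggplot(medians, ggplot2::aes(x = .data$time, y = .data$median)) +
    ggplot2::geom_line(color = "blue") +
    ggplot2::geom_line(data = series,
                       ggplot2::aes(y = rescale(.data$raw_score)),
                       color = "red") +
    ggplot2::scale_y_continuous(
      name = "median log2 fold change",
      sec.axis = ggplot2::sec_axis(
        ~ (. - rng_m[1]) / diff(rng_m) * diff(rng_s) + rng_s[1],
        name = "motif raw score")) +
    ggplot2::labs(x = "time (h)",
                  title = sprintf("%s / %s", series$motif_id[1],
                                  series$cluster[1])) +
    ggplot2::theme_minimal()
}
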