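#' Plot decoding performance per source x ROI combination
#'
#' Dot plot of the mean normalized correct-track rank of every combination,
#' with the chance level (0.5) and, when a white-matter null is available,
#' the significance threshold as horizontal reference lines. Lower is
#' better.
#'
#' @param object A `navdecode_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.navdecode_experiment <- function(object, ...) {
  df <- object$report
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$roi, y = .data$mean_normalized_rank,
      colour = .data$source, group = .data$source
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(
      x = "region of interest", y = "mean normalized correct-track rank",
      colour = "information source"
    ) +
    ggplot2::ylim(0, max(0.7, max(df$mean_normalized_rank)))
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::geom_hline(
      yintercept = object$threshold,
      linetype = "dashed", colour = "red"
    )
  }
  p
}

#' Plot the white-matter null distribution
#'
#' Histogram of the normalized correct-track ranks obtained from
#' non-informative decodings, with the fitted normal density and the
#' significance threshold.
#'
#' @param null A [build_null()] result.
#' @param k_sd Threshold multiplier (see [significance_threshold()]).
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(null, k_sd = 2.4) {
  stopifnot(inherits(null, "null_distribution"))
  thr <- significance_threshold(null, k_sd)
  df <- tibble::tibble(value = null$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = 20, fill = "grey70", colour = "grey30"
    ) +
    ggplot2::stat_function(
      fun = stats::dnorm,
      args = list(mean = null$mean, sd = null$sd), colour = "blue"
    ) +
    ggplot2::geom_vline(xintercept = thr, colour = "red", linetype = "dashed") +
    ggplot2::labs(
      x = "normalized correct-track rank (null)",
      y = "density"
    )
}

#' Plot the correct-track rank as time points accumulate
#'
#' @param curve A [timepoint_curve()] tibble.
#' @param n_tracks Pool size (adds the chance-rank reference line).
#' @return A ggplot object.
#' @export
plot_timepoint_curve <- function(curve, n_tracks = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$t, y = .data$mean_rank)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "number of leading time points used",
      y = "mean correct-track rank"
    )
  if (!is.null(n_tracks)) {
    p <- p + ggplot2::geom_hline(
      yintercept = chance_rank(n_tracks),
      linetype = "dotted"
    )
  }
  p
}

#' Display a rendered scene
#'
#' @param object A [scene][render_frame].
#' @param ... Unused.
#' @return A ggplot object (raster of the luminance image).
#' @exportS3Method ggplot2::autoplot
autoplot.scene <- function(object, ...) {
  lum <- object$luminance
  df <- tidyr::expand_grid(row = seq_len(nrow(lum)), col = seq_len(ncol(lum)))
  df$luminance <- lum[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
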