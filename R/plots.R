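#' Plot per-ROI metrics against PEEP
#'
#' Scatter of ASden and ASext versus the applied PEEP for each ROI, with
#' the fitted regression line — the standard way of displaying the
#' deflation response of the two metrics.
#'
#' @param metrics Tidy metrics tibble from [roi_metrics()] or
#'   [simulate_experiment()].
#' @param regressor `"measured"` (default) or `"nominal"` PEEP on the x
#'   axis.
#' @return A ggplot object.
#' @export
plot_roi_metrics <- function(metrics,
                             regressor = c("measured", "nominal")) {
  regressor <- match.arg(regressor)
  xcol <- if (regressor == "measured") "pressure_measured"
          else "pressure_nominal"
  long <- metrics |>
    tidyr::pivot_longer(c("asden", "asext"), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         asden = "ASden (n/mm^3)",
                                         asext = "ASext (voxels)"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data[[xcol]], y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::facet_grid(metric ~ roi, scales = "free_y") +
    ggplot2::labs(x = paste0(regressor, " PEEP (cmH2O)"), y = NULL) +
    ggplot2::theme_bw()
}

#' @rdname plot_roi_metrics
#' @param object An `airspace_report`.
#' @param ... Unused.
#' @export
autoplot.airspace_report <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$pressure_nominal,
                                  y = .data$mean,
                                  colour = .data$roi)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(0.6),
                             fatten = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "nominal PEEP (cmH2O)", y = "mean +/- SD") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Display a slice with its detected airspace labels
#'
#' @param stack A [slice_stack()].
#' @param detection An `airspace_map` from [detect_stack()].
#' @param slice Slice index to show.
#' @return A ggplot object (intensity underlay, label outlines as points
#'   at peak locations).
#' @export
plot_detection <- function(stack, detection, slice = 1L) {
  img <- stack$slices[[slice]]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    value = as.vector(img))
  pk <- detection$airspaces[detection$airspaces$slice == slice, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = pk,
                        ggplot2::aes(x = .data$peak_col,
                                     y = .data$peak_row),
                        colour = "red", size = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
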