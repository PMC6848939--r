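#' Plot a height surface
#'
#' Raster map of the per-pixel plant heights; excluded pixels (holes,
#' grid lines) are blank.
#'
#' @param object A [compute_height_surface()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot height_surface
#' @export
autoplot.height_surface <- function(object, ...) {
  df <- tibble::tibble(
    x = rep(seq_len(ncol(object$heights)) - 1L,
            each = nrow(object$heights)),
    y = rep(seq_len(nrow(object$heights)) - 1L,
            times = ncol(object$heights)),
    height = as.vector(object$heights),
    included = as.vector(object$included)
  )
  df$height[!df$included] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = "height (mm)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("Plant height surface (DAS %s)",
                                  format(object$das))) +
    ggplot2::theme_minimal()
}

#' Tile map of per-cell mean heights
#'
#' @param cells A [cell_stats()] tibble.
#' @return A ggplot.
#' @export
plot_cell_heights <- function(cells) {
  ggplot2::ggplot(cells, ggplot2::aes(.data$cell_col, .data$cell_row,
                                      fill = .data$h_mean_mm)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "mean height (mm)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "cell column", y = "cell row") +
    ggplot2::theme_minimal()
}

#' Plot a predicted-vs-measured comparison report
#'
#' Mean +- SD per side over days, with the Bhattacharyya distance as a
#' secondary series.
#'
#' @param object A [compare_to_ground_truth()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  long <- tibble::tibble(
    das = rep(object$das, 2),
    rack_id = rep(object$rack_id, 2),
    side = rep(c("predicted", "measured"), each = nrow(object)),
    mu = c(object$mu_pred, object$mu_meas),
    sd = c(object$sd_pred, object$sd_meas)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$das, .data$mu,
                                     color = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mu - .data$sd,
                                          ymax = .data$mu + .data$sd)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$rack_id)) +
    ggplot2::labs(x = "day after sowing", y = object$feature[1],
                  title = "Predicted vs manually measured") +
    ggplot2::theme_minimal()
}

#' Pairwise feature scatter by density class
#'
#' @param pairs The `pairs` table of
#'   [density_discrimination_summary()].
#' @return A ggplot.
#' @export
plot_density_pairs <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(.data$x, .data$y,
                                      color = .data$density_class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature_x, .data$feature_y),
                        scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, color = "density") +
    ggplot2::theme_minimal()
}

#' Tidy a comparison report
#'
#' Already tabular; returns the underlying tibble (one row per
#' (rack, DAS) cell).
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "comparison_report")
  out
}

#' @rdname tidy.comparison_report
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  tibble::tibble(feature = x$feature[1],
                 n_cells = nrow(x),
                 mean_DB = mean(x$DB, na.rm = TRUE),
                 max_DB = suppressWarnings(max(x$DB, na.rm = TRUE)))
}
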