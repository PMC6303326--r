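# Figures for units in climate space. Every figure has a data builder so
# the plotted numbers are testable without reading pixels.

bpr_type_palette <- function() {
  c(linear_positive = "#d73027", linear_negative = "#fc8d59",
    concave_negative = "#4575b4", concave_positive = "#91bfdb",
    non_significant = "grey60")
}

#' Data behind the climate-space unit figure
#'
#' @param unit_summaries Tibble from [summarize_units()].
#' @param unit_types Optional tibble with `unit` and `bpr_type`.
#' @param boundary Optional `bpr_boundary`.
#' @return The joined plotting table (one row per unit, plus the boundary
#'   polyline as attribute `"boundary"` when supplied).
#' @export
climate_figure_data <- function(unit_summaries, unit_types = NULL,
                                boundary = NULL) {
  if (nrow(unit_summaries) == 0) abort("Empty unit table.")
  out <- unit_summaries
  if (!is.null(unit_types)) {
    out <- dplyr::left_join(out, unit_types, by = "unit")
  }
  out$radius <- out$log_n
  if (!is.null(boundary)) {
    mat_grid <- seq(min(out$mat_mean), max(out$mat_mean), length.out = 50)
    attr(out, "boundary") <- boundary_line(boundary, mat_grid)
  }
  out
}

#' Climatic units in MAT-TAP space
#'
#' Scatter of unit centroids with circle radius proportional to the log
#' plot count, colored by BPR type (when supplied), shaped by aridity
#' class, with the optional logistic BPR boundary overlaid.
#'
#' @inheritParams climate_figure_data
#' @return A ggplot object.
#' @export
plot_climate_units <- function(unit_summaries, unit_types = NULL,
                               boundary = NULL) {
  dat <- climate_figure_data(unit_summaries, unit_types, boundary)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$mat_mean, y = .data$tap_mean))
  if ("bpr_type" %in% names(dat)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(size = .data$radius, colour = .data$bpr_type,
                   shape = .data$aridity_class), alpha = 0.85) +
      ggplot2::scale_colour_manual(values = bpr_type_palette(),
                                   name = "BPR type")
  } else {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(size = .data$radius, colour = .data$aridity_class),
      alpha = 0.85)
  }
  bl <- attr(dat, "boundary")
  if (!is.null(bl) && !isTRUE(attr(bl, "vertical"))) {
    p <- p + ggplot2::geom_line(data = bl,
                                ggplot2::aes(x = .data$mat, y = .data$tap),
                                linewidth = 0.8)
  }
  p + ggplot2::scale_size_identity() +
    ggplot2::labs(x = "Mean annual temperature (°C)",
                  y = "Total annual precipitation (mm)",
                  shape = "Aridity class") +
    ggplot2::theme_minimal()
}

#' Coefficient map figure across climate space
#'
#' @param map_tbl Tibble from [coefficient_map()].
#' @param coefficient Label used for the title.
#' @return A ggplot object.
#' @export
plot_coefficient_map <- function(map_tbl, coefficient = "") {
  if (nrow(map_tbl) == 0) abort("Empty coefficient map.")
  ggplot2::ggplot(map_tbl, ggplot2::aes(x = .data$mat_mean, y = .data$tap_mean)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$log_n,
                                     colour = .data$estimate,
                                     alpha = .data$significant)) +
    ggplot2::scale_colour_gradient2(low = "#4575b4", mid = "grey85",
                                    high = "#d73027", midpoint = 0) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25)) +
    ggplot2::scale_size_identity() +
    ggplot2::labs(title = coefficient,
                  x = "Mean annual temperature (°C)",
                  y = "Total annual precipitation (mm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bpr_boundary <- function(object, ...) {
  dat <- object$data
  mat_grid <- seq(min(dat$mat_mean), max(dat$mat_mean), length.out = 50)
  bl <- boundary_line(object, mat_grid)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$mat_mean, y = .data$tap_mean,
                                         colour = .data$bpr_type)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = bpr_type_palette(), name = "BPR type")
  if (!isTRUE(attr(bl, "vertical"))) {
    p <- p + ggplot2::geom_line(data = bl,
                                ggplot2::aes(x = .data$mat, y = .data$tap),
                                inherit.aes = FALSE, linewidth = 0.8)
  }
  p + ggplot2::labs(x = "Mean annual temperature (°C)",
                    y = "Total annual precipitation (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
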