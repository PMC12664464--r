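# ggplot2 displays for the result types. Maps use a fixed fill scale of
# [0.8, 2.5] so resolution and g maps from different methods are directly
# comparable side by side.

map_df <- function(m, value_name) {
  d <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d[[value_name]] <- as.vector(m)
  d
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a resolution map
#'
#' @param object a `resolution_map`.
#' @param limits fill limits (default `c(0.8, 2.5)`).
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot resolution_map
#' @export
autoplot.resolution_map <- function(object, limits = c(0.8, 2.5), ...) {
  d <- map_df(object$widths, "width")
  ggplot2::ggplot(d, ggplot2::aes(x = col, y = row,
                                  fill = width)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = limits, oob = scales_squish,
                                  na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Resolution map (%s)", object$axis),
                  fill = "w [px]", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a g-factor map
#' @param object a `gfactor_map`.
#' @inheritParams autoplot.resolution_map
#' @method autoplot gfactor_map
#' @export
autoplot.gfactor_map <- function(object, limits = c(0.8, 2.5), ...) {
  d <- map_df(object$g, "g")
  ggplot2::ggplot(d, ggplot2::aes(x = col, y = row,
                                  fill = g)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = limits, oob = scales_squish,
                                  na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("g-factor map (R = %.1f)", object$R),
                  fill = "g", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a percentile curve
#' @param object a `percentile_curve`.
#' @param ... ignored.
#' @method autoplot percentile_curve
#' @export
autoplot.percentile_curve <- function(object, ...) {
  ggplot2::ggplot(as.data.frame(object),
                  ggplot2::aes(x = percent, y = value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "percent of pixels", y = "percentile value",
                  title = "Cumulative frequency analysis") +
    ggplot2::theme_minimal()
}

# clamp out-of-range values to the scale limits instead of dropping them
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  fin <- if (only.finite) is.finite(x) else TRUE
  x[fin & x < range[1]] <- range[1]
  x[fin & x > range[2]] <- range[2]
  x
}

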