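#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' types: point patterns in their window, MSD curves, length-histogram fits
#' on the log scale, regularity-index time series of simulations, and ATP
#' fields as rasters.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_raster
#'   coord_fixed labs scale_fill_viridis_c geom_abline expand_limits
#' @export
autoplot.point_pattern <- function(object, ...) {
  w <- attr(object, "window")
  ggplot(as_tibble(object), aes(x = .data$x_um, y = .data$y_um)) +
    geom_point(size = 1) +
    expand_limits(x = w[c(1, 3)], y = w[c(2, 4)]) +
    coord_fixed() +
    labs(x = "x (µm)", y = "y (µm)")
}

#' @rdname autoplot-methods
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$lag_min, y = .data$msd_um2)) +
    geom_point() + geom_line() +
    labs(x = "lag (min)", y = expression(MSD ~ (mu * m^2)))
}

#' @rdname autoplot-methods
#' @export
autoplot.length_slope_fit <- function(object, ...) {
  ggplot(object$bins, aes(x = .data$mid_um, y = .data$log_count)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = -object$slope,
                linetype = 2) +
    labs(x = "process length (µm)", y = "log count")
}

#' @rdname autoplot-methods
#' @export
autoplot.microglia_sim <- function(object, ...) {
  ggplot(object$hsi_series, aes(x = .data$t_min, y = .data$hsi)) +
    geom_line() + geom_point() +
    expand_limits(y = c(0, 1)) +
    labs(x = "time (min)", y = "Hopkins-Skellam index")
}

#' @rdname autoplot-methods
#' @export
autoplot.atp_field <- function(object, ...) {
  nx <- nrow(object$a); ny <- ncol(object$a)
  df <- tibble(
    x_um = rep((seq_len(nx) - 0.5) * object$dx, times = ny),
    y_um = rep((seq_len(ny) - 0.5) * object$dx, each = nx),
    atp_uM = as.vector(object$a))
  ggplot(df, aes(x = .data$x_um, y = .data$y_um, fill = .data$atp_uM)) +
    geom_raster() + coord_fixed() + scale_fill_viridis_c() +
    labs(x = "x (µm)", y = "y (µm)", fill = "ATP (µM)")
}
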