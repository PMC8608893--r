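#' Planar point patterns of cell somata
#'
#' A point pattern is a tibble with columns `x_um` and `y_um` (coordinates in
#' micrometres) carrying a rectangular observation window as the `window`
#' attribute, `c(xmin, ymin, xmax, ymax)`. All spatial statistics in the
#' package (e.g. [hsi()], [nnd()]) consume this representation.
#'
#' @param points A data frame with numeric columns `x_um` and `y_um`.
#' @param window Numeric length-4 vector `c(xmin, ymin, xmax, ymax)` in
#'   micrometres. The window must have positive area and contain all points.
#' @return A tibble of class `point_pattern` with columns `x_um`, `y_um` and a
#'   `window` attribute.
#' @examples
#' pp <- point_pattern(data.frame(x_um = c(0, 3), y_um = c(0, 4)),
#'                     window = c(0, 0, 10, 10))
#' nnd(pp)
#' @export
point_pattern <- function(points, window) {
  points <- as.data.frame(points)
  if (!all(c("x_um", "y_um") %in% names(points))) {
    abort("`points` must have columns `x_um` and `y_um`.")
  }
  if (!is.numeric(points$x_um) || !is.numeric(points$y_um)) {
    abort("`x_um` and `y_um` must be numeric.")
  }
  if (anyNA(points$x_um) || anyNA(points$y_um)) {
    abort("point coordinates contain missing values.")
  }
  window <- check_window(window)
  out <- tibble(x_um = as.numeric(points$x_um), y_um = as.numeric(points$y_um))
  if (nrow(out) > 0) {
    inside <- out$x_um >= window[1] & out$x_um <= window[3] &
      out$y_um >= window[2] & out$y_um <= window[4]
    if (!all(inside)) {
      abort(sprintf("%d point(s) fall outside the observation window.",
                    sum(!inside)))
    }
  }
  structure(out, window = window,
            class = c("point_pattern", class(out)))
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 4 || anyNA(window)) {
    abort("`window` must be numeric c(xmin, ymin, xmax, ymax).")
  }
  window <- as.numeric(window)
  if (window[3] <= window[1] || window[4] <= window[2]) {
    abort("`window` must have positive area.")
  }
  window
}

#' @export
#' @rdname point_pattern
#' @param x An object to convert or print.
#' @param ... Unused.
as_point_pattern <- function(x, window = attr(x, "window"), ...) {
  point_pattern(x, window)
}

pattern_window <- function(pattern, window = NULL) {
  if (is.null(window)) window <- attr(pattern, "window")
  if (is.null(window)) {
    abort("no observation window: supply `window` or use a `point_pattern`.")
  }
  check_window(window)
}

window_area <- function(window) {
  (window[3] - window[1]) * (window[4] - window[2])
}

#' @export
print.point_pattern <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("<point_pattern> %d points in [%g, %g] x [%g, %g] um\n",
              nrow(x), w[1], w[3], w[2], w[4]))
  NextMethod()
}
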