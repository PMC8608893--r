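#' Synthetic point patterns: random, hard-core and clustered
#'
#' Seed-deterministic generators for the three reference pattern families
#' used to calibrate the Hopkins-Skellam index: complete spatial randomness
#' (binomial process), a Matern-II-style hard-core process (regular), and a
#' Thomas cluster process (aggregated).
#'
#' @param n Number of points.
#' @param window Observation window `c(xmin, ymin, xmax, ymax)` in um.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return A [point_pattern()].
#' @examples
#' csr_points(50, c(0, 0, 400, 400), seed = 1)
#' @export
csr_points <- function(n, window, seed = 1L) {
  window <- check_window(window)
  n <- as.integer(n)
  if (n < 0) abort("`n` must be nonnegative.")
  xy <- with_seed(seed, {
    cbind(runif(n, window[1], window[3]), runif(n, window[2], window[4]))
  })
  point_pattern(data.frame(x_um = xy[, 1], y_um = xy[, 2]), window)
}

#' @rdname csr_points
#' @param n_target Number of points requested; generation fails if the
#'   hard-core constraint makes the request infeasible.
#' @param r_min Hard-core distance in um: no two points closer than this.
#' @param max_tries Dart-throwing attempts per point before giving up.
#' @export
hardcore_points <- function(n_target, window, r_min, seed = 1L,
                            max_tries = 2000L) {
  window <- check_window(window)
  n_target <- as.integer(n_target)
  if (r_min < 0) abort("`r_min` must be nonnegative.")
  if (n_target * pi * r_min^2 / 4 >= window_area(window)) {
    abort("infeasible packing: n_target * pi * r_min^2 / 4 exceeds the window area.")
  }
  xy <- with_seed(seed, {
    pts <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n_target)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- c(runif(1, window[1], window[3]), runif(1, window[2], window[4]))
        if (nrow(pts) == 0 ||
            min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= r_min^2) {
          pts <- rbind(pts, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) abort(sprintf(
        "could not place point %d of %d at r_min = %g um; relax the request.",
        i, n_target, r_min))
    }
    pts
  })
  point_pattern(data.frame(x_um = xy[, 1], y_um = xy[, 2]), window)
}

#' @rdname csr_points
#' @param n_parents Number of Poisson cluster centres (uniform in window).
#' @param mean_children Mean number of offspring per parent (Poisson).
#' @param cluster_sd Gaussian dispersion of offspring around parents, um.
#'   Offspring falling outside the window are wrapped back in (toroidal),
#'   keeping the requested intensity.
#' @export
cluster_points <- function(n_parents, mean_children, cluster_sd, window,
                           seed = 1L) {
  window <- check_window(window)
  xy <- with_seed(seed, {
    px <- runif(n_parents, window[1], window[3])
    py <- runif(n_parents, window[2], window[4])
    counts <- stats::rpois(n_parents, mean_children)
    ox <- rep(px, counts) + stats::rnorm(sum(counts), 0, cluster_sd)
    oy <- rep(py, counts) + stats::rnorm(sum(counts), 0, cluster_sd)
    wx <- window[3] - window[1]; wy <- window[4] - window[2]
    ox <- window[1] + (ox - window[1]) %% wx
    oy <- window[2] + (oy - window[2]) %% wy
    cbind(ox, oy)
  })
  point_pattern(data.frame(x_um = xy[, 1], y_um = xy[, 2]), window)
}
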