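#' Hopkins-Skellam index of spatial regularity
#'
#' Quantifies departure of a planar point pattern from complete spatial
#' randomness as the ratio
#' \deqn{HSI = \frac{\sum_{i=1}^{N} r_{1i}^2}{\sum_{i=1}^{N} r_{2i}^2},}
#' where \eqn{r_1} are distances from random origins (uniform over the
#' observation window) to their nearest pattern point and \eqn{r_2} are
#' distances from pattern points to their nearest other pattern point.
#' HSI < 1 indicates a regular (over-dispersed) pattern, HSI = 1 a random
#' one, and HSI > 1 an aggregated one. No edge correction is applied.
#'
#' When `n_sample` equals the pattern size (the default), every pattern point
#' is used once for the \eqn{r_2} sample, which removes the sampling noise of
#' that term; when `n_sample` is smaller, points are sampled without
#' replacement, otherwise with replacement.
#'
#' @param pattern A [point_pattern()] (or data frame with `x_um`, `y_um`)
#'   with at least 2 points.
#' @param n_sample Number of random origins (and of sampled pattern points).
#'   Defaults to the number of pattern points.
#' @param seed Integer seed for the random origins; the global RNG state is
#'   left untouched.
#' @param window Observation window, defaulting to the pattern's own.
#' @param origins Optional n x 2 matrix of fixed origins overriding the
#'   random draw (for reproducing worked examples); `seed` is then ignored.
#' @return A one-row tibble with columns `hsi`, `n_pattern`, `n_sample`,
#'   `seed`.
#' @examples
#' pp <- csr_points(100, window = c(0, 0, 400, 400), seed = 1)
#' hsi(pp, seed = 1)
#' @export
hsi <- function(pattern, n_sample = NULL, seed = 1L, window = NULL,
                origins = NULL) {
  window <- pattern_window(pattern, window)
  xy <- cbind(pattern$x_um, pattern$y_um)
  n <- nrow(xy)
  if (is.null(n) || n < 2) abort("degenerate pattern: need at least 2 points.")
  if (is.null(n_sample)) n_sample <- n
  n_sample <- as.integer(n_sample)
  if (n_sample < 1) abort("`n_sample` must be at least 1.")

  if (is.null(origins)) {
    # scramble the user seed so that origins never coincide with a pattern
    # that was itself generated by runif() under the same seed
    sub_seed <- with_seed(seed, sample.int(2147483646L, 2L))
    origins <- with_seed(sub_seed[1], {
      u <- runif(n_sample); v <- runif(n_sample)
      cbind(window[1] + u * (window[3] - window[1]),
            window[2] + v * (window[4] - window[2]))
    })
    idx <- with_seed(sub_seed[2], {
      if (n_sample == n) seq_len(n)
      else if (n_sample < n) sample.int(n, n_sample, replace = FALSE)
      else sample.int(n, n_sample, replace = TRUE)
    })
  } else {
    origins <- as.matrix(origins)
    if (ncol(origins) != 2) abort("`origins` must be an n x 2 matrix.")
    n_sample <- nrow(origins)
    idx <- if (n_sample == n) seq_len(n) else
      with_seed(seed + 1L, sample.int(n, n_sample, replace = n_sample > n))
  }

  r1sq <- nn_dist_sq_cross(origins, xy)
  r2sq <- nn_dist_sq_self(xy)[idx]
  tibble(hsi = sum(r1sq) / sum(r2sq), n_pattern = n,
         n_sample = n_sample, seed = as.integer(seed))
}

# squared distance from each row of `from` to its nearest row of `to`
nn_dist_sq_cross <- function(from, to) {
  d2 <- outer(from[, 1], to[, 1], "-")^2 + outer(from[, 2], to[, 2], "-")^2
  apply(d2, 1, min)
}

# squared distance from each point to its nearest *other* point
nn_dist_sq_self <- function(xy) {
  d2 <- outer(xy[, 1], xy[, 1], "-")^2 + outer(xy[, 2], xy[, 2], "-")^2
  diag(d2) <- Inf
  apply(d2, 1, min)
}

#' Nearest-neighbour distances of a point pattern
#'
#' Euclidean distance from each point to its nearest other point. Duplicate
#' locations yield zero distances and raise a warning, since they distort the
#' distance distribution.
#'
#' @inheritParams hsi
#' @return A tibble with one row per point: `x_um`, `y_um`, `nnd_um`.
#' @seealso [nnd_summary()] for the min/mean summary.
#' @export
nnd <- function(pattern) {
  xy <- cbind(pattern$x_um, pattern$y_um)
  if (nrow(xy) < 2) abort("degenerate pattern: need at least 2 points.")
  d <- sqrt(nn_dist_sq_self(xy))
  if (any(d == 0)) {
    warn("pattern contains duplicate points; zero nearest-neighbour distances reported.")
  }
  tibble(x_um = xy[, 1], y_um = xy[, 2], nnd_um = d)
}

#' @rdname nnd
#' @return For `nnd_summary()`, a one-row tibble with `n`, `min_um`,
#'   `mean_um`, `has_duplicates`.
#' @export
nnd_summary <- function(pattern) {
  d <- suppressWarnings(nnd(pattern))$nnd_um
  tibble(n = length(d), min_um = min(d), mean_um = mean(d),
         has_duplicates = any(d == 0))
}
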