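#' Mean squared displacement of cell tracks
#'
#' Computes the time-averaged MSD within each eligible track over all
#' overlapping frame pairs at each lag, then averages across tracks
#' (unweighted by default, the convention used throughout the package;
#' `average = "pairs"` pools all pairs instead, weighting tracks by their
#' number of pairs).
#'
#' @param tracks A [track_set()] (or data frame with `track_id`, `frame`,
#'   `x_um`, `y_um`).
#' @param max_lag Largest lag to evaluate, in min. Defaults to half the
#'   longest track duration.
#' @param min_track_frames Minimum number of frames for a track to enter the
#'   average (the tracking analysis used 50 frames = 100 min).
#' @param frame_interval Frame interval in min; defaults to the track set's
#'   attribute.
#' @param average `"tracks"` (mean of per-track MSDs) or `"pairs"`
#'   (pair-weighted pooling).
#' @return A tibble of class `msd_curve` with columns `lag_min`, `msd_um2`,
#'   `n_pairs` (pairs pooled at that lag) and `n_tracks` (tracks
#'   contributing), including the trivial `lag = 0` row.
#' @export
msd <- function(tracks, max_lag = NULL, min_track_frames = 2L,
                frame_interval = attr(tracks, "frame_interval"),
                average = c("tracks", "pairs")) {
  average <- match.arg(average)
  if (is.null(frame_interval)) {
    abort("supply `frame_interval` or use a `track_set`.")
  }
  parts <- split(tracks[c("frame", "x_um", "y_um")], tracks$track_id)
  parts <- Filter(function(tr) nrow(tr) >= min_track_frames, parts)
  if (length(parts) == 0) abort("no track has at least `min_track_frames` frames.")
  max_frames <- max(vapply(parts, nrow, integer(1)))
  max_lag_frames <- if (is.null(max_lag)) {
    max(1L, (max_frames - 1L) %/% 2L)
  } else {
    max(1L, as.integer(floor(max_lag / frame_interval)))
  }
  lags <- seq_len(max_lag_frames)
  per_track <- lapply(parts, function(tr) {
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    vapply(lags, function(L) {
      if (L >= n) return(c(NA_real_, 0))
      i <- seq_len(n - L)
      sq <- (tr$x_um[i + L] - tr$x_um[i])^2 + (tr$y_um[i + L] - tr$y_um[i])^2
      c(mean(sq), length(sq))
    }, numeric(2))
  })
  msd_mat <- vapply(per_track, function(m) m[1, ], numeric(length(lags)))
  npair_mat <- vapply(per_track, function(m) m[2, ], numeric(length(lags)))
  msd_mat <- matrix(msd_mat, nrow = length(lags))
  npair_mat <- matrix(npair_mat, nrow = length(lags))
  msd_val <- if (average == "tracks") {
    rowMeans(msd_mat, na.rm = TRUE)
  } else {
    rowSums(msd_mat * npair_mat, na.rm = TRUE) / rowSums(npair_mat)
  }
  out <- tibble(
    lag_min = c(0, lags * frame_interval),
    msd_um2 = c(0, msd_val),
    n_pairs = c(sum(vapply(parts, nrow, integer(1))), rowSums(npair_mat)),
    n_tracks = c(length(parts), rowSums(!is.na(msd_mat)))
  )
  out <- out[!is.nan(out$msd_um2), ]
  structure(out, frame_interval = frame_interval,
            class = c("msd_curve", class(out)))
}

#' Persistent-random-walk parameters from an MSD curve
#'
#' Estimates the diffusion coefficient `d_u` (um^2/min) as the least-squares
#' slope of MSD against lag over the linear range, and the speed `v`
#' (um/min) from the first nonzero lag as `sqrt(msd(lag1)) / lag1`. For a
#' persistent random walk the MSD in its linear regime is
#' `d_u * (t - (1 - exp(-lambda t)) / lambda)`, i.e. linear with a negative
#' intercept, so the default fit estimates the slope with a free intercept;
#' `intercept = "zero"` forces the regression through the origin (the raw
#' MSD/time reading), which underestimates `d_u` when the fitting window is
#' not far beyond the persistence time.
#'
#' @param curve An [msd()] curve.
#' @param linear_range Length-2 numeric, the lag window (min) treated as the
#'   linear regime. Default 10-40 min (before the observed 40-min plateau).
#' @param intercept `"free"` (default) or `"zero"`.
#' @return A one-row tibble with `d_u_um2_min`, `v_um_min` and
#'   `msd_monotone` (FALSE flags a non-monotone MSD in the fitted range,
#'   e.g. confined motion).
#' @export
estimate_du_v <- function(curve, linear_range = c(10, 40),
                          intercept = c("free", "zero")) {
  intercept <- match.arg(intercept)
  stopifnot(length(linear_range) == 2)
  pos <- curve[curve$lag_min > 0, ]
  if (nrow(pos) == 0) abort("MSD curve has no nonzero lag.")
  sel <- pos[pos$lag_min >= linear_range[1] & pos$lag_min <= linear_range[2], ]
  if (nrow(sel) < 2) abort("`linear_range` must contain at least 2 lags.")
  fit <- if (intercept == "free") {
    lm(msd_um2 ~ lag_min, data = sel)
  } else {
    lm(msd_um2 ~ lag_min + 0, data = sel)
  }
  d_u <- unname(coef(fit)[["lag_min"]])
  lag1 <- pos$lag_min[1]
  msd1 <- pos$msd_um2[1]
  if (msd1 == 0 && any(pos$msd_um2 > 0)) {
    warn("msd at the first lag is zero; reporting v = 0.")
  }
  v <- sqrt(max(msd1, 0)) / lag1
  mono <- !is.unsorted(sel$msd_um2)
  if (!mono) warn("MSD is non-monotone in the fitted range; check for confinement.")
  tibble(d_u_um2_min = d_u, v_um_min = v, msd_monotone = mono)
}

#' Operational persistence time of a persistent random walk
#'
#' The persistence estimator `tau = d_u / v^2` (min), with `d_u` the
#' diffusion coefficient (MSD/time) and `v` the cell speed.
#'
#' @param d_u Diffusion coefficient, um^2/min.
#' @param v Speed, um/min (> 0).
#' @return Persistence time in min.
#' @examples
#' persistence(6.0, 0.88) # ~7.7 min
#' @export
persistence <- function(d_u, v) {
  if (any(v <= 0)) abort("undefined persistence: v must be positive.")
  d_u / v^2
}
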