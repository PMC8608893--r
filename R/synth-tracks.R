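#' Synthetic run-and-tumble cell tracks
#'
#' Simulates 2-D persistent random walks exactly: each cell moves in a
#' straight line at constant speed `v` and redraws its heading uniformly on
#' the circle at exponentially distributed intervals with rate `2 / tau`
#' (mean run time `tau / 2`). Positions are sampled at the frame interval
#' `dt` with no discretisation error. Under this convention the long-time
#' diffusivity is `d_u = MSD/time = v^2 * tau`, matching the operational
#' persistence estimator `tau = d_u / v^2` used by [persistence()].
#'
#' @param n_tracks Number of independent tracks.
#' @param v Speed in um/min.
#' @param tau Persistence time in min (`tau = d_u / v^2`).
#' @param dt Frame interval in min.
#' @param t_end Track duration in min.
#' @param seed Integer seed; global RNG state untouched.
#' @return A tibble of class `track_set` with columns `track_id`, `frame`,
#'   `x_um`, `y_um` and attribute `frame_interval` (min). Frames are
#'   0-based; all tracks start at the origin.
#' @examples
#' tr <- prw_tracks(5, v = 0.88, tau = 7.7, dt = 2, t_end = 100, seed = 1)
#' msd(tr)
#' @export
prw_tracks <- function(n_tracks, v, tau, dt, t_end, seed = 1L) {
  if (v < 0 || tau <= 0 || dt <= 0 || t_end < dt) {
    abort("need v >= 0, tau > 0, 0 < dt <= t_end.")
  }
  lambda <- 2 / tau
  frame_times <- seq(0, t_end, by = dt)
  nf <- length(frame_times)
  res <- with_seed(seed, {
    out <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      t_now <- 0; x <- 0; y <- 0
      theta <- runif(1, 0, 2 * pi)
      t_tumble <- rexp(1, lambda)
      xs <- numeric(nf); ys <- numeric(nf)
      for (f in seq(2, nf)) {
        target <- frame_times[f]
        while (t_tumble < target) {
          x <- x + v * cos(theta) * (t_tumble - t_now)
          y <- y + v * sin(theta) * (t_tumble - t_now)
          t_now <- t_tumble
          theta <- runif(1, 0, 2 * pi)
          t_tumble <- t_now + rexp(1, lambda)
        }
        x <- x + v * cos(theta) * (target - t_now)
        y <- y + v * sin(theta) * (target - t_now)
        t_now <- target
        xs[f] <- x; ys[f] <- y
      }
      out[[i]] <- tibble(track_id = i, frame = seq_len(nf) - 1L,
                         x_um = xs, y_um = ys)
    }
    dplyr::bind_rows(out)
  })
  track_set(res, frame_interval = dt)
}

#' Cell track sets
#'
#' A track set is a tibble with columns `track_id`, `frame` (0-based,
#' contiguous within each track), `x_um`, `y_um`, and a `frame_interval`
#' attribute in minutes.
#'
#' @param tracks Data frame with the four track columns.
#' @param frame_interval Frame interval in minutes.
#' @return A tibble of class `track_set`.
#' @export
track_set <- function(tracks, frame_interval) {
  tracks <- as_tibble(as.data.frame(tracks))
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    abort("tracks need columns track_id, frame, x_um, y_um.")
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    abort("`frame_interval` must be a positive number of minutes.")
  }
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  split_frames <- split(tracks$frame, tracks$track_id)
  for (id in names(split_frames)) {
    fr <- split_frames[[id]]
    if (anyDuplicated(fr)) {
      abort(sprintf("track %s has duplicate frames.", id))
    }
    if (length(fr) >= 2 && any(diff(fr) != 1)) {
      abort(sprintf("track %s has frame gaps; frames must be contiguous.", id))
    }
  }
  structure(tracks, frame_interval = frame_interval,
            class = c("track_set", class(tracks)))
}
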