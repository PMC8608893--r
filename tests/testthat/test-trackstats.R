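two_track_fixture <- function() {
  track_set(data.frame(
    track_id = c(1L, 1L, 1L, 2L, 2L),
    frame = c(0L, 1L, 2L, 0L, 1L),
    x_um = c(0, 1, 3, 0, 3),
    y_um = c(0, 0, 0, 0, 0)), frame_interval = 1)
}

test_that("msd matches a hand-computed two-track oracle", {
  tr <- two_track_fixture()
  # track 1 lag-1 pairs: 1, 4 -> 2.5 ; lag-2 pair: 9
  # track 2 lag-1 pair: 9
  by_tracks <- msd(tr, max_lag = 2)
  expect_equal(by_tracks$lag_min, c(0, 1, 2))
  expect_equal(by_tracks$msd_um2, c(0, (2.5 + 9) / 2, 9))
  expect_equal(by_tracks$n_pairs[2:3], c(3, 1))
  expect_equal(by_tracks$n_tracks[2:3], c(2, 1))
  by_pairs <- msd(tr, max_lag = 2, average = "pairs")
  expect_equal(by_pairs$msd_um2, c(0, (1 + 4 + 9) / 3, 9))
})

test_that("msd of a stationary cell is zero and of ballistic motion quadratic", {
  still <- track_set(data.frame(track_id = 1L, frame = 0:10,
                                x_um = 2, y_um = -1), frame_interval = 2)
  out <- msd(still, max_lag = 6)
  expect_true(all(out$msd_um2 == 0))

  v <- 0.7
  ball <- track_set(data.frame(track_id = 1L, frame = 0:20,
                               x_um = v * (0:20) * 2, y_um = 0),
                    frame_interval = 2)
  out <- msd(ball, max_lag = 20)
  expect_equal(out$msd_um2, (v * out$lag_min)^2)
})

test_that("msd scales quadratically with coordinates and respects the frame interval", {
  tr <- prw_tracks(12, v = 1, tau = 5, dt = 2, t_end = 40, seed = 8)
  base <- msd(tr)
  scaled <- tr
  scaled$x_um <- scaled$x_um * 3
  scaled$y_um <- scaled$y_um * 3
  expect_equal(msd(scaled)$msd_um2, base$msd_um2 * 9)

  # halving the declared frame interval halves the lag axis only
  faster <- track_set(as.data.frame(tr), frame_interval = 1)
  out <- msd(faster)
  expect_equal(out$msd_um2, base$msd_um2)
  expect_equal(out$lag_min, base$lag_min / 2)
})

test_that("min_track_frames filters short tracks from the average", {
  tr <- two_track_fixture()
  only_long <- msd(tr, max_lag = 1, min_track_frames = 3)
  expect_equal(only_long$msd_um2[2], 2.5)
  expect_error(msd(tr, min_track_frames = 10), "min_track_frames")
})

test_that("estimate_du_v recovers slope and speed from an exact linear curve", {
  lag <- seq(0, 50, by = 2)
  curve <- structure(
    tibble::tibble(lag_min = lag, msd_um2 = 6 * lag,
                   n_pairs = 100, n_tracks = 10),
    frame_interval = 2, class = c("msd_curve", "tbl_df", "tbl", "data.frame"))
  est <- estimate_du_v(curve)
  expect_equal(est$d_u_um2_min, 6, tolerance = 1e-10)
  expect_equal(est$v_um_min, sqrt(12) / 2)
  expect_true(est$msd_monotone)
  # through-origin variant agrees on a proportional curve
  expect_equal(estimate_du_v(curve, intercept = "zero")$d_u_um2_min, 6,
               tolerance = 1e-10)
})

test_that("estimate_du_v flags non-monotone (confined) MSD", {
  lag <- seq(0, 50, by = 2)
  plateau <- 30 * (1 - exp(-lag / 5)) + c(0, rep_len(c(0.5, -0.5), length(lag) - 1))
  curve <- structure(
    tibble::tibble(lag_min = lag, msd_um2 = pmax(plateau, 0),
                   n_pairs = 100, n_tracks = 10),
    frame_interval = 2, class = c("msd_curve", "tbl_df", "tbl", "data.frame"))
  expect_warning(est <- estimate_du_v(curve), "non-monotone")
  expect_false(est$msd_monotone)
})

test_that("prw_tracks + msd round-trips the PRW diffusivity", {
  v <- 0.88; tau <- 7.7
  tr <- prw_tracks(150, v = v, tau = tau, dt = 2, t_end = 100, seed = 31)
  est <- estimate_du_v(msd(tr))
  d_true <- v^2 * tau
  expect_lt(abs(est$d_u_um2_min - d_true) / d_true, 0.25)
  expect_lt(abs(est$v_um_min - v) / v, 0.25)
})

test_that("persistence matches its defining arithmetic and rejects v <= 0", {
  expect_equal(persistence(6.0, 0.88), 6 / 0.88^2)
  expect_equal(signif(persistence(6.0, 0.88), 2), 7.7)
  expect_error(persistence(6, 0), "positive")
})

test_that("track_set validates frames", {
  base <- data.frame(track_id = 1L, frame = c(0L, 1L, 3L),
                     x_um = 1:3, y_um = 0)
  expect_error(track_set(base, 2), "gaps")
  dup <- data.frame(track_id = 1L, frame = c(0L, 1L, 1L),
                    x_um = 1:3, y_um = 0)
  expect_error(track_set(dup, 2), "duplicate")
  expect_error(track_set(base[, -1], 2), "columns")
  shuffled <- data.frame(track_id = c(1L, 1L, 1L), frame = c(2L, 0L, 1L),
                         x_um = c(3, 1, 2), y_um = 0)
  ts <- track_set(shuffled, 2)
  expect_equal(ts$frame, 0:2)
  expect_equal(ts$x_um, 1:3)
})
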