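bar_image <- function(value = 120, nrows = 40, ncols = 40) {
  m <- matrix(0, nrows, ncols)
  m[18:22, 11:30] <- value  # 5 px wide, 20 px long horizontal bar
  gray_image(m, 1)
}

test_that("skeleton and distance map of a bar behave like a medial axis", {
  b <- binarize(bar_image(), 60)
  out <- skeleton_and_distance(b)
  expect_identical(dim(out$skeleton), dim(out$distmap))
  # the skeleton is a single horizontal line on the bar's centre row
  idx <- which(out$skeleton, arr.ind = TRUE)
  expect_true(all(idx[, 1] == 20))
  # thinning erodes roughly half the bar width from each end
  expect_gte(nrow(idx), 20 - 5)
  expect_lte(nrow(idx), 20)
  # centre-row distance to background is (width + 1) / 2 = 3
  expect_equal(mean_thickness(out$skeleton, out$distmap), 3)
  expect_equal(skeleton_length(bar_image(), 60), nrow(idx) - 1)
})

test_that("skeletonization preserves connectivity of the structure", {
  b <- binarize(bar_image(), 60)
  sk <- skeleton_and_distance(b)$skeleton
  lab <- microspacing:::.cpp_label8((sk * 1L))
  expect_equal(max(lab), 1L)
})

test_that("skeleton length and counts are invariant under transposition", {
  img <- bar_image()
  timg <- gray_image(t(unclass(img)), 1)
  expect_equal(skeleton_length(timg, 60), skeleton_length(img, 60))
})

test_that("distance map of a disk peaks at roughly the radius", {
  xs <- matrix(rep(1:40, each = 40), 40)
  m <- matrix(0, 40, 40)
  m[(xs - 20.5)^2 + (t(xs) - 20.5)^2 <= 100] <- 120
  out <- skeleton_and_distance(binarize(gray_image(m, 1), 60))
  expect_lt(abs(max(out$distmap) - 10), 1.5)
})

test_that("mean thickness increases with structure width", {
  widths <- c(3, 5, 9)
  th <- vapply(widths, function(w) {
    m <- matrix(0, 40, 40)
    m[20 + seq_len(w) - ceiling(w / 2), 6:35] <- 120
    s <- skeleton_and_distance(binarize(gray_image(m, 1), 60))
    mean_thickness(s$skeleton, s$distmap)
  }, numeric(1))
  expect_true(all(diff(th) > 0))
})

test_that("select_threshold finds the knee between noise floor and signal", {
  set.seed(4)
  nz <- matrix(runif(1600, 0, 30), 40, 40)
  nz[18:22, 11:30] <- 120
  img <- gray_image(nz, 1)
  th <- select_threshold(img, seq(10, 130, by = 10))
  expect_gt(th, 30)   # above the noise ceiling
  expect_lte(th, 120) # at or below the signal level
  expect_warning(select_threshold(gray_image(nz * 0 + 120, 1), c(60, 80)),
                 "no skeleton-length explosion")
  expect_error(select_threshold(img, 50), "at least 2")
})

test_that("empty structures raise informative errors", {
  b <- binarize(bar_image(), 200)  # nothing above threshold
  out <- skeleton_and_distance(b)
  expect_false(any(out$skeleton))
  expect_error(mean_thickness(out$skeleton, out$distmap, 1), "empty")
  expect_error(extract_processes(out$skeleton, out$distmap, b,
                                 pixel_size = 1), "empty")
})

test_that("extract_processes recovers a small rendered cell population", {
  pp <- hardcore_points(5, c(0, 0, 200, 200), r_min = 70, seed = 2)
  im <- microglia_image(pp, process_lengths = 12, seed = 1)
  bin <- binarize(im$image, 60)
  s <- skeleton_and_distance(bin)
  ex <- extract_processes(s$skeleton, s$distmap, bin, soma_min_radius = 3)
  # soma count exact, centroids within 1.5 px of the truth
  expect_equal(nrow(ex$somata), 5L)
  d <- sqrt(outer(ex$somata$x_um, pp$x_um, "-")^2 +
              outer(ex$somata$y_um, pp$y_um, "-")^2)
  expect_lt(max(apply(d, 1, min)), 1.5)
  # 6 processes of 12 um per cell; soma masking and tip merging cost some
  expect_true(all(ex$per_cell$n_processes >= 3 & ex$per_cell$n_processes <= 6))
  expect_gte(sum(ex$per_cell$n_processes), 20)
  expect_lt(abs(stats::median(ex$processes$length_um) - 12), 3)
  expect_true(all(ex$processes$length_um <= 18))
  expect_equal(ex$per_cell$total_length_um,
               vapply(1:5, function(i)
                 sum(ex$processes$length_um[ex$processes$soma_id == i]),
                 numeric(1)))
})

test_that("the full chain with automatic threshold recovers a noisy image", {
  pp <- hardcore_points(12, c(0, 0, 400, 400), r_min = 70, seed = 4)
  im <- microglia_image(pp, process_lengths = 15, bg_noise_max = 8,
                        salt_frac = 0.002, seed = 10)
  mm <- morphology_metrics(im$image, soma_min_radius = 4, pixel_size = 1)
  expect_gt(mm$threshold, 8)    # above the raw noise ceiling
  expect_lt(mm$threshold, 120)  # below the signal
  expect_lte(abs(mm$n_cells - 12), 1)
  expect_equal(mm$density_cells_mm2, mm$n_cells / 0.16)
  expect_true(mm$processes_per_cell >= 4 && mm$processes_per_cell <= 6)
  expect_true(mm$avg_process_length_um > 6 && mm$avg_process_length_um < 15)
  expect_true(mm$soma_hsi < 1)  # hardcore pattern reads as regular
})

test_that("morphology_metrics respects a fixed threshold and pixel size", {
  pp <- hardcore_points(5, c(0, 0, 200, 200), r_min = 70, seed = 2)
  im <- microglia_image(pp, process_lengths = 12, seed = 1)
  mm <- morphology_metrics(im$image, threshold = 60, preprocess = FALSE,
                           pixel_size = 1)
  expect_equal(mm$threshold, 60)
  expect_equal(mm$n_cells, 5L)
  # physical results are unchanged when the same scene is rendered at
  # 0.5 um/px (up to resampling error)
  im2 <- microglia_image(pp, process_lengths = 12, pixel_size = 0.5,
                         seed = 1)
  mm2 <- morphology_metrics(im2$image, threshold = 60, preprocess = FALSE)
  expect_equal(mm2$n_cells, 5L)
  expect_lt(abs(mm2$avg_process_length_um - mm$avg_process_length_um), 3)
})
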