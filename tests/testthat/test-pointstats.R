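test_that("hsi reproduces a hand-worked fixture with fixed origins", {
  # four points on the corners of a 4 x 4 window; nearest-other-point
  # distance is 4 for every point, so sum r2^2 = 4 * 16 = 64. Origins at
  # the four cell centres (1,1),(3,1),(1,3),(3,3) are sqrt(2) from their
  # nearest corner, so sum r1^2 = 4 * 2 = 8 and HSI = 8/64 = 0.125.
  pp <- point_pattern(
    data.frame(x_um = c(0, 4, 0, 4), y_um = c(0, 0, 4, 4)),
    window = c(0, 0, 4, 4))
  origins <- cbind(c(1, 3, 1, 3), c(1, 1, 3, 3))
  out <- hsi(pp, origins = origins)
  expect_equal(out$hsi, 0.125)
  expect_equal(out$n_pattern, 4L)
  expect_equal(out$n_sample, 4L)
})

test_that("hsi is deterministic in the seed and sensitive to it", {
  pp <- csr_points(150, c(0, 0, 400, 400), seed = 42)
  a <- hsi(pp, seed = 7)
  b <- hsi(pp, seed = 7)
  c_ <- hsi(pp, seed = 8)
  expect_identical(a, b)
  expect_false(a$hsi == c_$hsi)
})

test_that("hsi does not collapse when pattern and index share a seed", {
  # csr_points(seed = s) and hsi(seed = s) must not draw identical uniforms
  pp <- csr_points(200, c(0, 0, 1000, 1000), seed = 1)
  expect_gt(hsi(pp, seed = 1)$hsi, 0.5)
})

test_that("hsi is invariant under translation and scaling", {
  pp <- csr_points(120, c(0, 0, 300, 300), seed = 3)
  shifted <- point_pattern(
    data.frame(x_um = pp$x_um + 1000, y_um = pp$y_um - 50),
    window = c(1000, -50, 1300, 250))
  scaled <- point_pattern(
    data.frame(x_um = pp$x_um * 10, y_um = pp$y_um * 10),
    window = c(0, 0, 3000, 3000))
  expect_equal(hsi(shifted, seed = 5)$hsi, hsi(pp, seed = 5)$hsi)
  expect_equal(hsi(scaled, seed = 5)$hsi, hsi(pp, seed = 5)$hsi)
})

test_that("hsi orders hardcore < CSR < clustered patterns", {
  w <- c(0, 0, 400, 400)
  vals <- vapply(1:25, function(s) {
    hc <- hardcore_points(100, w, r_min = 20, seed = s)
    cs <- csr_points(100, w, seed = s)
    cl <- cluster_points(10, 10, 10, w, seed = s)
    c(hsi(hc, seed = s + 1000)$hsi,
      hsi(cs, seed = s + 1000)$hsi,
      hsi(cl, seed = s + 1000)$hsi)
  }, numeric(3))
  m <- rowMeans(vals)
  expect_lt(m[1], m[2])   # regular below random
  expect_lt(m[2], m[3])   # random below aggregated
  expect_lt(m[1], 0.9)
  expect_gt(m[3], 1.2)
})

test_that("hsi subsampling and oversampling paths work", {
  pp <- csr_points(100, c(0, 0, 400, 400), seed = 2)
  small <- hsi(pp, n_sample = 40, seed = 3)
  big <- hsi(pp, n_sample = 250, seed = 3)
  expect_equal(small$n_sample, 40L)
  expect_equal(big$n_sample, 250L)
  expect_true(is.finite(small$hsi) && small$hsi > 0)
  expect_true(is.finite(big$hsi) && big$hsi > 0)
})

test_that("nnd matches a hand-computed oracle and a brute-force check", {
  pp <- point_pattern(
    data.frame(x_um = c(0, 1, 5), y_um = c(0, 0, 0)),
    window = c(0, 0, 6, 1))
  out <- nnd(pp)
  expect_equal(out$nnd_um, c(1, 1, 4))
  s <- nnd_summary(pp)
  expect_equal(s$n, 3L)
  expect_equal(s$min_um, 1)
  expect_equal(s$mean_um, 2)
  expect_false(s$has_duplicates)

  # brute force on a random pattern
  pp2 <- csr_points(60, c(0, 0, 100, 100), seed = 9)
  d <- as.matrix(stats::dist(cbind(pp2$x_um, pp2$y_um)))
  diag(d) <- Inf
  expect_equal(nnd(pp2)$nnd_um, unname(apply(d, 1, min)))
})

test_that("nnd warns on duplicate points and errors on degenerate input", {
  pp <- point_pattern(
    data.frame(x_um = c(1, 1, 3), y_um = c(2, 2, 2)),
    window = c(0, 0, 5, 5))
  expect_warning(out <- nnd(pp), "duplicate")
  expect_true(any(out$nnd_um == 0))
  expect_true(nnd_summary(pp)$has_duplicates)

  one <- point_pattern(data.frame(x_um = 1, y_um = 1), c(0, 0, 2, 2))
  expect_error(nnd(one), "at least 2")
  expect_error(hsi(one), "at least 2")
})

test_that("point_pattern validates its window", {
  expect_error(
    point_pattern(data.frame(x_um = 5, y_um = 1), c(0, 0, 4, 4)),
    "window")
  expect_error(point_pattern(data.frame(x_um = 1, y_um = 1), c(0, 0, 0, 4)))
  pp <- point_pattern(data.frame(x_um = 0, y_um = 4), c(0, 0, 4, 4))
  expect_s3_class(pp, "point_pattern")
  expect_equal(attr(pp, "window"), c(0, 0, 4, 4))
})
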