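test_that("repulsion_force matches the piecewise-linear definition", {
  p <- model_params()  # k = 0.1, sigma = 45
  expect_equal(repulsion_force(c(0, 25, 45, 60), p), c(4.5, 2.0, 0, 0))
  expect_equal(repulsion_force(10, model_params(k = 0)), 0)
  expect_error(repulsion_force(-1, p), "nonnegative")
})

test_that("gradient_at is exact for uniform and linear fields", {
  cfg <- numerics_config(domain = c(200, 200), dx = 5)
  p <- model_params()
  f0 <- steady_atp_field(p, cfg)
  g0 <- gradient_at(f0, cbind(c(20, 100, 180), c(50, 100, 150)))
  expect_equal(g0, matrix(0, 3, 2))

  # a = 0.01 x: central differences are exact for linear fields away from
  # the edges under the no-flux convention
  nx <- 40; ny <- 40
  xc <- (seq_len(nx) - 0.5) * 5
  lin <- atp_field(matrix(0.01 * xc, nx, ny), 5)
  pts <- cbind(c(60, 100.5, 143.2), c(70, 99, 120))
  g <- gradient_at(lin, pts, boundary = "no-flux")
  expect_equal(g[, 1], rep(0.01, 3), tolerance = 1e-12)
  expect_equal(g[, 2], rep(0, 3), tolerance = 1e-12)
  expect_error(gradient_at(lin, cbind(500, 50), boundary = "no-flux"),
               "outside")
})

test_that("the uniform balance p/h is a fixed point of the ATP step", {
  p <- model_params()
  cfg <- numerics_config(domain = c(200, 200), dx = 5)
  f <- steady_atp_field(p, cfg)
  level <- p$p_atp / p$h
  cells <- matrix(numeric(0), 0, 2)
  for (i in 1:200) f <- atp_step(f, cells, p, dt = 0.02)
  expect_lt(max(abs(f$a - level)) / level, 1e-10)
})

test_that("uniform decay follows the scalar ODE solution", {
  p <- model_params(b = 0)
  cfg <- numerics_config(domain = c(100, 100), dx = 5)
  a0 <- 1
  f <- atp_field(matrix(a0, 20, 20), 5)
  dt <- 0.01; nsteps <- 1000  # t = 10 min
  cells <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nsteps)) f <- atp_step(f, cells, p, dt = dt)
  target <- p$p_atp / p$h
  exact <- target + (a0 - target) * exp(-p$h * dt * nsteps)
  expect_lt(max(abs(f$a - exact)) / exact, 0.01)
})

test_that("pure diffusion of a Gaussian matches the heat kernel", {
  p <- model_params(p_atp = 0, h = 0, b = 0)
  dx <- 5; n <- 80; L <- n * dx
  xc <- (seq_len(n) - 0.5) * dx
  s0sq <- 200
  blob <- function(ssq) {
    outer(xc, xc, function(x, y)
      exp(-((x - L / 2)^2 + (y - L / 2)^2) / (2 * ssq))) * s0sq / ssq
  }
  f <- atp_field(blob(s0sq), dx)
  dt <- 0.8 * dx^2 / (4 * p$d_a)
  nsteps <- 400
  cells <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nsteps)) f <- atp_step(f, cells, p, dt = dt)
  expected <- blob(s0sq + 2 * p$d_a * dt * nsteps)
  expect_lt(max(abs(f$a - expected)) / max(expected), 0.02)
})

test_that("atp_step enforces the diffusion stability bound", {
  p <- model_params()
  cfg <- numerics_config(domain = c(100, 100), dx = 5)
  f <- steady_atp_field(p, cfg)
  expect_error(atp_step(f, matrix(numeric(0), 0, 2), p, dt = 0.1),
               "stability")
})

test_that("two repelling cells follow d(t) = sigma - (sigma - d0) exp(-2kt)", {
  p <- model_params(c = 0, v = 0)  # repulsion only
  cfg <- numerics_config(domain = c(400, 400), dx = 5)
  f <- steady_atp_field(p, cfg)     # uniform: zero gradient
  d0 <- 40
  withr::with_seed(1, {
    cells <- cell_state(rbind(c(200 - d0 / 2, 200), c(200 + d0 / 2, 200)),
                        tau = p$tau)
    dt <- 0.01; nsteps <- 1000      # t = 10 min
    for (i in seq_len(nsteps)) {
      cells <- cell_step(cells, f, p, dt, t_now = (i - 1) * dt)
    }
  })
  d_num <- sqrt(sum((cells$positions[1, ] - cells$positions[2, ])^2))
  d_exact <- p$sigma - (p$sigma - d0) * exp(-2 * p$k * dt * nsteps)
  expect_lt(abs(d_num - d_exact) / d_exact, 0.01)
})

test_that("cells with all motility terms off do not move", {
  p <- model_params(c = 0, v = 0, k = 0)
  cfg <- numerics_config(domain = c(200, 200), dx = 5)
  f <- steady_atp_field(p, cfg)
  withr::with_seed(2, {
    cells <- cell_state(cbind(runif(10, 0, 200), runif(10, 0, 200)))
    pos0 <- cells$positions
    for (i in 1:50) cells <- cell_step(cells, f, p, 0.05, t_now = (i - 1) * 0.05)
  })
  expect_equal(cells$positions, pos0)
})

test_that("cells stay inside the domain under reflecting boundaries", {
  p <- model_params(c = 0, k = 0, v = 2)
  cfg <- numerics_config(domain = c(100, 100), dx = 5, boundary = "no-flux")
  f <- steady_atp_field(p, cfg)
  withr::with_seed(3, {
    cells <- cell_state(cbind(runif(20, 0, 100), runif(20, 0, 100)))
    for (i in 1:400) {
      cells <- cell_step(cells, f, p, 0.1, boundary = "no-flux",
                         t_now = (i - 1) * 0.1)
    }
  })
  expect_true(all(cells$positions >= 0 & cells$positions <= 100))
})

test_that("run_simulation is bit-reproducible and keeps the field sane", {
  cfg <- numerics_config(t_end = 60, seed = 99, record_every = 30)
  s1 <- run_simulation(model_params(), cfg)
  s2 <- run_simulation(model_params(), cfg)
  expect_identical(s1$snapshots, s2$snapshots)
  expect_identical(s1$hsi_series, s2$hsi_series)
  expect_true(all(is.finite(s1$field$a)))
  expect_true(all(s1$field$a >= 0))
  expect_true(all(s1$snapshots$x_um >= 0 & s1$snapshots$x_um <= 400))
  g <- glance(s1)
  expect_equal(g$n_cells, 65L)
  expect_equal(g$hsi_final, dplyr::last(s1$hsi_series$hsi))
})

test_that("stronger repulsion spaces cells farther apart", {
  min_nnd <- vapply(c(20, 45, 70), function(sg) {
    p <- model_params(c = 0, v = 0, sigma = sg)
    s <- run_simulation(p, numerics_config(t_end = 120, seed = 17,
                                           record_every = 120))
    nnd_summary(s$final_pattern)$min_um
  }, numeric(1))
  expect_true(all(diff(min_nnd) > 0))
})

test_that("the wound boundary imposes the clamped edge and ~30 um decay length", {
  p <- model_params()
  dx <- 5; nx <- 80
  f <- steady_atp_field(p, numerics_config(domain = c(400, 400), dx = dx))
  cells <- matrix(numeric(0), 0, 2)
  dt <- 0.8 * dx^2 / (4 * p$d_a)
  for (i in seq_len(ceiling(100 / dt))) {
    f <- atp_step(f, cells, p, dt, boundary = "wound")
  }
  expect_equal(f$a[nx, ], rep(p$a_w, nx))
  # excess over baseline decays as exp(-x / sqrt(d_a / h)), L = 30 um
  base <- p$p_atp / p$h
  mid <- nx / 2
  e1 <- f$a[nx - 7, mid] - base   # 35 um from the clamped column
  e2 <- f$a[nx - 13, mid] - base  # 65 um
  L_fit <- 30 / log(e1 / e2)      # node spacing is 30 um
  expect_lt(abs(L_fit - sqrt(p$d_a / p$h)) / sqrt(p$d_a / p$h), 0.15)
})

test_that("parameter constructors validate their arguments", {
  expect_error(model_params(tau = 0), "tau")
  expect_error(model_params(k = -1), "nonnegative")
  expect_error(numerics_config(domain = c(-1, 100)), "domain")
  expect_error(numerics_config(dx = 200), "dx")
  expect_error(numerics_config(t_end = 0), "positive")
  cfg <- numerics_config()
  expect_equal(cfg$n_cells, 65L)  # 409 cells/mm^2 over 0.16 mm^2
})
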