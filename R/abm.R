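#' Gridded extracellular ATP field
#'
#' @param a Numeric matrix of concentrations (uM); entry `[ix, iy]` sits at
#'   `((ix - 0.5) dx, (iy - 0.5) dx)` (cell-centred nodes).
#' @param dx Grid spacing, um.
#' @return A list of class `atp_field` with elements `a` and `dx`.
#' @export
atp_field <- function(a, dx) {
  if (!is.matrix(a) || !is.numeric(a)) abort("`a` must be a numeric matrix.")
  if (any(!is.finite(a)) || any(a < 0)) abort("ATP field must be finite and nonnegative.")
  if (dx <= 0) abort("`dx` must be positive.")
  structure(list(a = a, dx = dx), class = "atp_field")
}

#' Uniform field at the production/decay balance `p_atp / h`
#' @inheritParams atp_field
#' @param params A [model_params()].
#' @param config A [numerics_config()].
#' @return An [atp_field()] at the spatially uniform steady state.
#' @export
steady_atp_field <- function(params, config) {
  nx <- round(config$domain[1] / config$dx)
  ny <- round(config$domain[2] / config$dx)
  level <- if (params$h > 0) params$p_atp / params$h else 0
  atp_field(matrix(level, nx, ny), config$dx)
}

#' Cell state of the simulator
#'
#' @param positions n x 2 matrix of (x, y) in um.
#' @param headings n x 2 matrix of unit heading vectors; defaults to random
#'   directions drawn from the current RNG stream.
#' @param next_tumble Next heading-resampling time per cell (min); defaults
#'   to exponential draws at rate `2 / tau`.
#' @param tau Persistence used for the default tumble schedule.
#' @return A list of class `cell_state`.
#' @export
cell_state <- function(positions, headings = NULL, next_tumble = NULL,
                       tau = 7.7) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) abort("`positions` must be an n x 2 matrix.")
  n <- nrow(positions)
  if (is.null(headings)) {
    th <- runif(n, 0, 2 * pi)
    headings <- cbind(cos(th), sin(th))
  }
  if (is.null(next_tumble)) next_tumble <- rexp(n, 2 / tau)
  structure(list(positions = positions, headings = as.matrix(headings),
                 next_tumble = as.numeric(next_tumble)),
            class = "cell_state")
}

#' Pairwise contact-repulsion force magnitude
#'
#' The piecewise-linear repulsion `f(r) = k (sigma - r)` for `r < sigma` and
#' zero beyond, in um/min, directed from the neighbour towards the focal
#' cell.
#'
#' @param r Centre-to-centre distance(s), um.
#' @param params A [model_params()] supplying `k` and `sigma`.
#' @return Force magnitude(s), um/min.
#' @examples
#' repulsion_force(c(0, 25, 45, 60), model_params())
#' @export
repulsion_force <- function(r, params = model_params()) {
  if (any(r < 0)) abort("`r` must be nonnegative.")
  ifelse(r < params$sigma, params$k * (params$sigma - r), 0)
}

#' ATP gradient at off-grid positions
#'
#' Central-difference gradient at the grid nodes, bilinearly interpolated to
#' the query positions, respecting the boundary convention.
#'
#' @param field An [atp_field()].
#' @param pos n x 2 matrix (or data frame / length-2 vector) of positions, um.
#' @param boundary `"periodic"`, `"no-flux"` or `"wound"`.
#' @return An n x 2 matrix of (da/dx, da/dy) in uM/um.
#' @export
gradient_at <- function(field, pos, boundary = "periodic") {
  pos <- pos_matrix(pos)
  Lx <- nrow(field$a) * field$dx
  Ly <- ncol(field$a) * field$dx
  if (boundary != "periodic" &&
      (any(pos[, 1] < 0) || any(pos[, 1] > Lx) ||
       any(pos[, 2] < 0) || any(pos[, 2] > Ly))) {
    abort("position outside the domain under a non-periodic boundary.")
  }
  .cpp_gradient_at(field$a, field$dx, pos, boundary_code(boundary))
}

pos_matrix <- function(pos) {
  if (is.data.frame(pos)) pos <- cbind(pos$x_um, pos$y_um)
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2)
  storage.mode(pos) <- "double"
  pos
}

#' One explicit step of the ATP reaction-diffusion field
#'
#' Production `p_atp`, decay `h a`, diffusion (5-point Laplacian) and the
#' per-cell sink (`- b delta(r_i)`, with `b` deposited entirely in the grid
#' cell containing each microglia as a concentration drop per minute),
#' clamped at zero. Under the `"wound"` boundary the
#' `x = Lx` edge column is then reset to `a_w`.
#'
#' @inheritParams gradient_at
#' @param cells A [cell_state()] (or n x 2 position matrix); may have zero
#'   rows for a cell-free field.
#' @param params A [model_params()].
#' @param dt Time step, min; checked against the stability bound.
#' @return A new [atp_field()].
#' @export
atp_step <- function(field, cells, params, dt, boundary = "periodic") {
  pos <- if (inherits(cells, "cell_state")) cells$positions else pos_matrix(cells)
  bound <- field$dx^2 / (4 * params$d_a)
  if (dt > bound + 1e-12) {
    abort(sprintf("dt = %.4g violates the stability bound dx^2/(4 d_a) = %.4g.",
                  dt, bound))
  }
  a <- field$a + 0 # force a copy; the kernel updates in place
  .cpp_atp_step(a, field$dx, pos, params$p_atp, params$h, params$b,
                params$d_a, dt, boundary_code(boundary), params$a_w)
  atp_field(a, field$dx)
}

#' One forward-Euler step of the cell equations
#'
#' Drift is chemotaxis `c grad a` plus summed contact repulsion plus
#' `v * heading`; headings are resampled uniformly on the circle when a
#' cell's scheduled tumble time has passed (Poisson rate `2 / tau`).
#' Under the periodic boundary, repulsion uses minimum-image distances and
#' positions wrap; otherwise cells reflect at the domain edges.
#'
#' @inheritParams atp_step
#' @param t_now Current simulation time, min (drives the tumble schedule).
#' @return A new [cell_state()].
#' @export
cell_step <- function(cells, field, params, dt, boundary = "periodic",
                      t_now = 0) {
  if (!inherits(cells, "cell_state")) abort("`cells` must be a cell_state.")
  pos <- cells$positions + 0
  hd <- cells$headings + 0
  nt <- cells$next_tumble + 0
  Lx <- nrow(field$a) * field$dx
  Ly <- ncol(field$a) * field$dx
  .cpp_cell_step(pos, hd, nt, t_now, field$a, field$dx,
                 params$c, params$v, params$tau, params$sigma, params$k,
                 dt, boundary_code(boundary), Lx, Ly)
  structure(list(positions = pos, headings = hd, next_tumble = nt),
            class = "cell_state")
}

#' Run the coupled microglia / ATP simulation
#'
#' Initialises `n_cells` at uniformly random positions (complete spatial
#' randomness), the ATP field at its uniform balance `p_atp / h`, and
#' alternates field and cell steps (operator splitting) to `t_end`,
#' recording cell snapshots and the Hopkins-Skellam index of the
#' configuration every `record_every` minutes. The run is bit-reproducible
#' given `config$seed`.
#'
#' @param params A [model_params()].
#' @param config A [numerics_config()].
#' @return An object of class `microglia_sim`: a list with `snapshots`
#'   (tibble `t_min`, `cell_id`, `x_um`, `y_um`), `hsi_series` (tibble
#'   `t_min`, `hsi`), `final_pattern` (a [point_pattern()]), `field` (the
#'   final [atp_field()]), plus `params`, `config` and (for wound runs)
#'   `wound_fraction`. See [tidy.microglia_sim()] and
#'   [autoplot.microglia_sim()].
#' @examples
#' \donttest{
#' sim <- run_simulation(model_params(),
#'                       numerics_config(t_end = 120, seed = 1))
#' glance(sim)
#' }
#' @export
run_simulation <- function(params = model_params(),
                           config = numerics_config()) {
  simulate_run(params, config, wound_depth_um = NULL)
}

#' Wound scenario: ATP source strip at one domain edge
#'
#' As [run_simulation()] but with the `"wound"` boundary: the ATP
#' concentration on the `x = Lx` edge column is clamped at `a_w`
#' (25 uM, about 1/300 of the intracellular ATP concentration), other edges
#' are no-flux and cells reflect. Additionally records the fraction of cells
#' within `wound_depth_um` of the wound edge over time.
#'
#' @inheritParams run_simulation
#' @param wound_depth_um Distance from the wound edge within which cells
#'   count as wound-proximal (default 50 um).
#' @return A `microglia_sim` whose `wound_fraction` element is a tibble
#'   (`t_min`, `fraction`).
#' @export
wound_scenario <- function(params = model_params(),
                           config = numerics_config(boundary = "wound"),
                           wound_depth_um = 50) {
  if (config$boundary != "wound") {
    config$boundary <- "wound"
  }
  simulate_run(params, config, wound_depth_um = wound_depth_um)
}

simulate_run <- function(params, config, wound_depth_um) {
  dt <- if (is.null(config$dt)) default_dt(params, config) else
    check_dt(config$dt, params, config)
  Lx <- config$domain[1]; Ly <- config$domain[2]
  window <- c(0, 0, Lx, Ly)
  bcode <- boundary_code(config$boundary)
  n_rec <- max(1L, ceiling(config$t_end / config$record_every))
  rec_times <- seq_len(n_rec) * config$record_every
  rec_times[n_rec] <- config$t_end

  withr::local_seed(config$seed)
  pattern0 <- csr_points(config$n_cells, window,
                         seed = sample.int(.Machine$integer.max, 1))
  pos <- cbind(pattern0$x_um, pattern0$y_um)
  th <- runif(config$n_cells, 0, 2 * pi)
  hd <- cbind(cos(th), sin(th))
  nt <- rexp(config$n_cells, 2 / params$tau)
  field <- steady_atp_field(params, config)
  a <- field$a + 0

  hsi_seed_base <- (config$seed %% 1000000L) * 1000L
  snap <- function(t, pos) tibble(t_min = t, cell_id = seq_len(nrow(pos)),
                                  x_um = pos[, 1], y_um = pos[, 2])
  hsi_at <- function(t, pos, i) {
    if (nrow(pos) < 2) return(NA_real_)
    pat <- point_pattern(data.frame(x_um = pos[, 1], y_um = pos[, 2]), window)
    hsi(pat, seed = hsi_seed_base + i)$hsi
  }
  snapshots <- list(snap(0, pos))
  hsis <- c(hsi_at(0, pos, 0L))
  fractions <- if (!is.null(wound_depth_um)) {
    mean(pos[, 1] >= Lx - wound_depth_um)
  } else NULL

  t_now <- 0
  for (i in seq_along(rec_times)) {
    target <- rec_times[i]
    nsteps <- max(0L, round((target - t_now) / dt))
    if (nsteps > 0) {
      t_now <- .cpp_advance(a, pos, hd, nt, t_now, nsteps, dt,
                            config$dx, params$c, params$v, params$tau,
                            params$sigma, params$k, params$p_atp, params$h,
                            params$b, params$d_a, bcode, params$a_w, Lx, Ly)
    }
    snapshots[[i + 1]] <- snap(t_now, pos)
    hsis <- c(hsis, hsi_at(t_now, pos, i))
    if (!is.null(wound_depth_um)) {
      fractions <- c(fractions, mean(pos[, 1] >= Lx - wound_depth_um))
    }
  }

  final_pattern <- point_pattern(
    data.frame(x_um = pos[, 1], y_um = pos[, 2]), window)
  out <- list(
    snapshots = dplyr::bind_rows(snapshots),
    hsi_series = tibble(t_min = c(0, rec_times), hsi = hsis),
    final_pattern = final_pattern,
    field = atp_field(a, config$dx),
    params = params, config = config, dt = dt)
  if (!is.null(wound_depth_um)) {
    out$wound_fraction <- tibble(t_min = c(0, rec_times),
                                 fraction = fractions)
    out$wound_depth_um <- wound_depth_um
  }
  structure(out, class = "microglia_sim")
}

#' @export
print.microglia_sim <- function(x, ...) {
  cat(sprintf(
    "<microglia_sim> %d cells, %g x %g um (%s), t_end = %g min, dt = %.4g min\n",
    x$config$n_cells, x$config$domain[1], x$config$domain[2],
    x$config$boundary, x$config$t_end, x$dt))
  cat(sprintf("  final HSI: %.3f\n", dplyr::last(x$hsi_series$hsi)))
  invisible(x)
}

#' Tidiers for simulation results
#'
#' `tidy()` returns the recorded regularity-index series (and wound-proximal
#' fraction when present); `glance()` a one-row run summary.
#'
#' @param x A `microglia_sim`.
#' @param ... Unused.
#' @export
tidy.microglia_sim <- function(x, ...) {
  out <- x$hsi_series
  if (!is.null(x$wound_fraction)) {
    out <- dplyr::left_join(out, x$wound_fraction, by = "t_min")
  }
  out
}

#' @rdname tidy.microglia_sim
#' @export
glance.microglia_sim <- function(x, ...) {
  tibble(n_cells = x$config$n_cells, t_end_min = x$config$t_end,
         dt_min = x$dt, boundary = x$config$boundary,
         seed = x$config$seed,
         hsi_final = dplyr::last(x$hsi_series$hsi),
         min_nnd_um = if (x$config$n_cells >= 2)
           nnd_summary(x$final_pattern)$min_um else NA_real_,
         atp_min_uM = min(x$field$a), atp_max_uM = max(x$field$a))
}
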