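#' Model parameters of the microglia spacing simulator
#'
#' Biophysical parameters of the coupled cell / ATP-field model. Cells obey
#' \deqn{dr_i/dt = c \nabla a + \sum_{j \ne i} f(|r_j - r_i|)\,\hat u_{ij} + v\,e_i,}
#' with piecewise-linear contact repulsion \eqn{f(r) = k(\sigma - r)} for
#' \eqn{r < \sigma} (zero beyond), run-and-tumble headings \eqn{e_i}
#' (resampled at rate \eqn{2/\tau}), and the extracellular ATP field
#' \deqn{\partial a/\partial t = p - h a - b \sum_i \delta(r_i) + d_a \Delta a,}
#' where each cell's uptake `b` is deposited entirely in the grid cell
#' containing it, as a concentration drop per minute. The defaults are the
#' measured/literature values used for the quantitative simulations.
#'
#' @param c Chemotactic coefficient, um^2 uM^-1 min^-1 (default 18).
#' @param tau Persistence of the random walk, min (default 7.7).
#' @param v Cell speed, um/min (default 0.88).
#' @param p_atp ATP production rate, uM/min (default 1.7e-3).
#' @param h ATP decay rate, /min (default 0.2).
#' @param b ATP uptake per microglia, uM/min dropped in the grid cell
#'   containing the cell (default 9.5e-4).
#' @param d_a ATP diffusion coefficient, um^2/min (default 180).
#' @param sigma Repulsive radius, um (default 45).
#' @param k Repulsive strength, /min (default 0.1).
#' @param a_w ATP concentration clamped at the wound strip, uM (default 25).
#' @return A list of class `model_params`.
#' @examples
#' model_params()               # baseline
#' model_params(k = 0)          # repulsion off
#' @export
model_params <- function(c = 18, tau = 7.7, v = 0.88, p_atp = 1.7e-3,
                         h = 0.2, b = 9.5e-4, d_a = 180, sigma = 45,
                         k = 0.1, a_w = 25) {
  p <- list(c = c, tau = tau, v = v, p_atp = p_atp, h = h, b = b,
            d_a = d_a, sigma = sigma, k = k, a_w = a_w)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                            is.finite(x) && x >= 0, logical(1))]
  if (length(bad)) abort(paste("nonnegative scalar required for:",
                               paste(bad, collapse = ", ")))
  if (p$sigma <= 0) abort("`sigma` must be positive.")
  if (p$tau <= 0) abort("`tau` must be positive.")
  structure(p, class = "model_params")
}

#' Numerical configuration of the simulator
#'
#' @param domain Domain size `c(Lx, Ly)` in um (default 400 x 400, the size
#'   of the observation fields the spacing statistics are computed on).
#' @param dx Field grid spacing, um (default 5; keep `dx <= sigma / 4`).
#' @param dt Time step, min, or `NULL` (default) to choose
#'   `min(0.8 dx^2 / (4 d_a), 0.01 / k, tau / 50)` at run time. Explicit
#'   values violating the diffusion stability bound `dx^2 / (4 d_a)` are
#'   rejected when stepping.
#' @param boundary `"periodic"` (default), `"no-flux"`, or `"wound"`
#'   (Dirichlet ATP strip `a = a_w` on the `x = Lx` edge, no-flux elsewhere;
#'   cells reflect at non-periodic edges).
#' @param t_end Simulated time, min (default 720 = 12 h, the organ-culture
#'   observation span).
#' @param seed Integer seed for the whole run.
#' @param n_cells Number of cells; default rounds the avascular retinal
#'   density of 409 cells/mm^2 over the domain (65 cells at 400 x 400 um).
#' @param record_every Interval (min) at which snapshots and the regularity
#'   index are recorded (default 60).
#' @return A list of class `numerics_config`.
#' @export
numerics_config <- function(domain = c(400, 400), dx = 5, dt = NULL,
                            boundary = c("periodic", "no-flux", "wound"),
                            t_end = 720, seed = 1L, n_cells = NULL,
                            record_every = 60) {
  boundary <- match.arg(boundary)
  if (length(domain) != 2 || any(domain <= 0)) abort("`domain` must be positive c(Lx, Ly).")
  if (dx <= 0 || dx > min(domain) / 4) abort("`dx` must be in (0, min(domain)/4].")
  if (is.null(n_cells)) n_cells <- round(409e-6 * domain[1] * domain[2])
  if (n_cells < 0) abort("`n_cells` must be nonnegative.")
  if (t_end <= 0 || record_every <= 0) abort("`t_end` and `record_every` must be positive.")
  structure(list(domain = as.numeric(domain), dx = dx, dt = dt,
                 boundary = boundary, t_end = t_end, seed = as.integer(seed),
                 n_cells = as.integer(n_cells), record_every = record_every),
            class = "numerics_config")
}

boundary_code <- function(boundary) {
  match(boundary, c("periodic", "no-flux", "wound")) - 1L
}

# default stable step given params/config; 0.8 safety factor on the explicit
# diffusion bound, plus repulsion and tumbling resolution constraints
default_dt <- function(params, config) {
  dt <- 0.8 * config$dx^2 / (4 * params$d_a)
  if (params$k > 0) dt <- min(dt, 0.01 / params$k)
  dt <- min(dt, params$tau / 50)
  dt
}

check_dt <- function(dt, params, config) {
  bound <- config$dx^2 / (4 * params$d_a)
  if (dt > bound + 1e-12) {
    abort(sprintf(
      "dt = %.4g violates the diffusion stability bound dx^2/(4 d_a) = %.4g.",
      dt, bound))
  }
  dt
}
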