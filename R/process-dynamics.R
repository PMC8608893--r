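#' Growth-collapse model of microglial process length
#'
#' Microglial processes elongate at a constant velocity `g` (um/min) and
#' collapse back to zero length with a uniform hazard `p_collapse` (/min).
#' The stationary length distribution of this advection-with-uniform-death
#' process (a McKendrick-von Foerster equation with constant death rate) is
#' exponential with rate `p_collapse / g` per um, so a histogram of lengths
#' is log-linear with slope `-p_collapse / g`.
#'
#' `expected_slope()` returns that predicted decay rate.
#'
#' @param g Growth velocity, um/min (> 0).
#' @param p_collapse Collapse probability per minute (>= 0).
#' @return Decay rate of the stationary length distribution, per um.
#' @examples
#' expected_slope(g = 0.36, p_collapse = 0.046) # ~0.13 per um
#' @export
expected_slope <- function(g, p_collapse) {
  if (any(g <= 0)) abort("`g` must be positive.")
  if (any(p_collapse < 0)) abort("`p_collapse` must be nonnegative.")
  p_collapse / g
}

#' @rdname expected_slope
#' @param n Number of independent processes.
#' @param t_end Simulated time, min. Defaults to `10 / p_collapse` (ample
#'   burn-in to stationarity); must be well beyond `1 / p_collapse`.
#' @param dt Time step, min. The guard `dt * p_collapse < 0.1` is enforced;
#'   the default 0.1 min keeps both the collapse-probability error and the
#'   length discretisation (lattice `g * dt`) negligible.
#' @param seed Integer seed; global RNG state untouched.
#' @return For `simulate_processes()`, a tibble with column `length_um` (one
#'   row per process at `t_end`).
#' @export
simulate_processes <- function(g, p_collapse, n, t_end = NULL, dt = 0.1,
                               seed = 1L) {
  if (g <= 0) abort("`g` must be positive.")
  if (p_collapse < 0) abort("`p_collapse` must be nonnegative.")
  if (is.null(t_end)) {
    t_end <- if (p_collapse > 0) 10 / p_collapse else 100
  }
  if (dt * p_collapse >= 0.1) {
    abort(sprintf(
      "unstable collapse step: dt * p_collapse = %.3g >= 0.1; use dt <= %.3g.",
      dt * p_collapse, 0.099 / p_collapse))
  }
  nsteps <- max(1L, round(t_end / dt))
  lengths <- with_seed(seed, {
    len <- numeric(n)
    grow <- g * dt
    pc <- p_collapse * dt
    for (s in seq_len(nsteps)) {
      collapsed <- runif(n) < pc
      len <- ifelse(collapsed, 0, len + grow)
    }
    len
  })
  tibble(length_um = lengths)
}

#' Log-linear slope of a process-length histogram
#'
#' Bins lengths at `bin_width` um and fits `log(count)` against bin centres
#' by least squares over nonempty bins; the decay rate is reported as a
#' positive number (the negated regression slope). By default bins are
#' weighted by their counts, the delta-method precision weighting for log
#' Poisson counts (`var(log N) ~ 1/N`), which keeps the near-empty tail
#' bins from flattening the fit; `weights = "none"` gives each nonempty bin
#' equal weight.
#'
#' @param lengths Numeric vector of process lengths (um), or a data frame
#'   with a `length_um` column (e.g. from [simulate_processes()]).
#' @param bin_width Histogram bin width in um (default 1).
#' @param weights `"count"` (default) or `"none"`.
#' @return An object of class `length_slope_fit`; see [tidy()] / [glance()],
#'   or access `$slope`, `$intercept`, `$r2`, `$bins`.
#' @examples
#' x <- simulate_processes(0.36, 0.046, n = 2000, seed = 1)
#' fit_length_slope(x)
#' @export
fit_length_slope <- function(lengths, bin_width = 1,
                             weights = c("count", "none")) {
  weights <- match.arg(weights)
  if (is.data.frame(lengths)) lengths <- lengths$length_um
  if (!is.numeric(lengths) || anyNA(lengths)) {
    abort("`lengths` must be numeric without missing values.")
  }
  if (any(lengths < 0)) abort("process lengths must be nonnegative.")
  breaks <- seq(0, max(lengths) + bin_width, by = bin_width)
  h <- graphics::hist(lengths, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0
  if (sum(keep) < 3) abort("need at least 3 nonempty bins for the log-linear fit.")
  bins <- tibble(mid_um = h$mids[keep], count = h$counts[keep],
                 log_count = log(h$counts[keep]))
  w <- if (weights == "count") bins$count else rep(1, nrow(bins))
  fit <- lm(log_count ~ mid_um, data = bins, weights = w)
  r2 <- summary(fit)$r.squared
  structure(
    list(slope = -unname(coef(fit)[["mid_um"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r2 = min(max(r2, 0), 1),
         bin_width = bin_width, weights = weights,
         n = length(lengths), bins = bins, fit = fit),
    class = "length_slope_fit")
}

#' @export
print.length_slope_fit <- function(x, ...) {
  cat(sprintf(
    "<length_slope_fit> log(count) = %.3g - %.4g * length; R^2 = %.3f (%d lengths, %d bins)\n",
    x$intercept, x$slope, x$r2, x$n, nrow(x$bins)))
  invisible(x)
}

#' Tidiers for length-slope fits
#'
#' @param x A `length_slope_fit`.
#' @param ... Unused.
#' @return `tidy()` returns one row per fitted quantity; `glance()` a
#'   one-row model summary.
#' @export
tidy.length_slope_fit <- function(x, ...) {
  tibble(term = c("slope_per_um", "intercept_log_count"),
         estimate = c(x$slope, x$intercept))
}

#' @rdname tidy.length_slope_fit
#' @export
glance.length_slope_fit <- function(x, ...) {
  tibble(slope_per_um = x$slope, intercept = x$intercept, r.squared = x$r2,
         n_lengths = x$n, n_bins = nrow(x$bins), bin_width_um = x$bin_width)
}
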