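#' Render a synthetic microglia-like image with ground truth
#'
#' Draws disk somata at the locations of `pattern` with straight processes
#' radiating outward (evenly spaced angles with a random phase and optional
#' jitter, which keeps processes of one cell from merging, as in ramified
#' microglia). Process lengths are exponential with rate `length_rate_per_um`
#' unless fixed via `process_lengths`; a process of length L extends L um
#' beyond the soma edge. Optional uniform background noise and salt
#' (impulse) noise exercise the despeckle/threshold steps. Everything is
#' seed-deterministic and the returned ground truth suffices to score any
#' downstream morphometry estimate.
#'
#' @param pattern A [point_pattern()] of soma centres; its window defines
#'   the image extent.
#' @param soma_radius_um Soma radius, um (default 4).
#' @param processes_per_cell Processes per cell (default 6).
#' @param length_rate_per_um Rate of the exponential length distribution,
#'   per um (default 0.13, the measured retinal value); lengths are
#'   truncated at `max_length_um`.
#' @param process_width_um Full process width, um (default 1.5).
#' @param pixel_size Pixel size, um/px (default 1).
#' @param fg_intensity Foreground intensity (default 120).
#' @param bg_noise_max Background noise amplitude: each background pixel gets
#'   a uniform intensity on `[0, bg_noise_max]` (default 0).
#' @param salt_frac Fraction of pixels replaced by salt impulses at
#'   `fg_intensity` (default 0).
#' @param process_lengths Optional fixed length(s) in um, recycled across
#'   processes, overriding the exponential draw.
#' @param angle_jitter Uniform jitter (radians) added to each evenly spaced
#'   process angle (default 0).
#' @param max_length_um Truncation of drawn lengths (default 40).
#' @param seed Integer seed; global RNG state untouched.
#' @return A list with `image` (a [gray_image()]) and `truth` (list:
#'   `pattern`, `soma_radius_um`, `process_width_um`, `processes` tibble of
#'   `cell`, `angle`, `length_um`, and `seed`).
#' @examples
#' pp <- hardcore_points(5, c(0, 0, 120, 120), r_min = 40, seed = 2)
#' img <- microglia_image(pp, process_lengths = 12, seed = 1)
#' @export
microglia_image <- function(pattern, soma_radius_um = 4,
                            processes_per_cell = 6,
                            length_rate_per_um = 0.13,
                            process_width_um = 1.5, pixel_size = 1,
                            fg_intensity = 120, bg_noise_max = 0,
                            salt_frac = 0, process_lengths = NULL,
                            angle_jitter = 0, max_length_um = 40,
                            seed = 1L) {
  window <- pattern_window(pattern)
  ps <- pixel_size
  n_cells <- nrow(pattern)
  ncols <- ceiling((window[3] - window[1]) / ps)
  nrows <- ceiling((window[4] - window[2]) / ps)
  cx <- pattern$x_um - window[1]
  cy <- pattern$y_um - window[2]

  dat <- with_seed(seed, {
    k <- processes_per_cell
    procs <- NULL
    if (n_cells > 0 && k > 0) {
      phase <- runif(n_cells, 0, 2 * pi)
      angle <- as.vector(outer(2 * pi * (seq_len(k) - 1) / k, phase, "+"))
      if (angle_jitter > 0) {
        angle <- angle + runif(n_cells * k, -angle_jitter, angle_jitter)
      }
      len <- if (is.null(process_lengths)) {
        pmin(rexp(n_cells * k, length_rate_per_um), max_length_um)
      } else {
        rep_len(process_lengths, n_cells * k)
      }
      procs <- tibble(cell = rep(seq_len(n_cells), each = k),
                      angle = angle, length_um = len)
    } else {
      procs <- tibble(cell = integer(0), angle = numeric(0),
                      length_um = numeric(0))
    }
    noise_u <- if (bg_noise_max > 0) runif(nrows * ncols, 0, bg_noise_max) else NULL
    salt <- if (salt_frac > 0) runif(nrows * ncols) < salt_frac else NULL
    list(procs = procs, noise_u = noise_u, salt = salt)
  })
  procs <- dat$procs

  px <- (rep(seq_len(ncols), each = nrows) - 0.5) * ps  # x of every pixel
  py <- (rep(seq_len(nrows), times = ncols) - 0.5) * ps # y of every pixel
  fg <- logical(nrows * ncols)
  for (i in seq_len(n_cells)) {
    fg <- fg | ((px - cx[i])^2 + (py - cy[i])^2 <= soma_radius_um^2)
  }
  half_w <- process_width_um / 2
  for (j in seq_len(nrow(procs))) {
    i <- procs$cell[j]
    ux <- cos(procs$angle[j]); uy <- sin(procs$angle[j])
    x0 <- cx[i] + soma_radius_um * ux; y0 <- cy[i] + soma_radius_um * uy
    L <- procs$length_um[j]
    # distance from pixel to the segment (x0,y0) -> (x0,y0) + L*(ux,uy)
    tproj <- pmin(pmax((px - x0) * ux + (py - y0) * uy, 0), L)
    d2 <- (px - (x0 + tproj * ux))^2 + (py - (y0 + tproj * uy))^2
    fg <- fg | (d2 <= half_w^2)
  }
  img <- matrix(0, nrows, ncols)
  img[fg] <- fg_intensity
  if (!is.null(dat$noise_u)) {
    bg <- !fg
    img[bg] <- pmax(img[bg], dat$noise_u[bg])
  }
  if (!is.null(dat$salt)) img[dat$salt] <- fg_intensity

  list(image = gray_image(img, ps),
       truth = list(pattern = pattern, soma_radius_um = soma_radius_um,
                    process_width_um = process_width_um,
                    processes = procs, seed = as.integer(seed)))
}
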