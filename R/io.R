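#' Read and write point patterns as CSV
#'
#' The on-disk dialect is a header `x_um,y_um` with plain decimal-point
#' numbers; anything unparseable (missing columns, text, locale-style
#' decimal commas) raises an error naming the offending rows. Round-trips
#' are lossless well beyond 6 decimals.
#'
#' @param path CSV file path.
#' @param window Observation window `c(xmin, ymin, xmax, ymax)`; if `NULL`,
#'   the points' bounding box is used (with a warning).
#' @return A [point_pattern()].
#' @export
read_points <- function(path, window = NULL) {
  df <- read_checked_csv(path, c(x_um = "d", y_um = "d"))
  if (is.null(window)) {
    warn("no window supplied; using the bounding box of the points.")
    window <- c(min(df$x_um), min(df$y_um), max(df$x_um), max(df$y_um))
    if (window[3] <= window[1]) window[3] <- window[1] + 1e-6
    if (window[4] <= window[2]) window[4] <- window[2] + 1e-6
  }
  point_pattern(df, window)
}

#' @rdname read_points
#' @param pattern A [point_pattern()] (or data frame with `x_um`, `y_um`).
#' @export
write_points <- function(pattern, path) {
  readr::write_csv(as.data.frame(pattern)[c("x_um", "y_um")], path)
  invisible(path)
}

#' Read and write track sets as CSV
#'
#' Columns `track_id,frame,x_um,y_um`; rows may arrive shuffled and are
#' re-sorted by track and frame. Frames must be contiguous within each track
#' and unique; violations raise an error naming the track.
#'
#' @param path CSV file path.
#' @param frame_interval Frame interval, min.
#' @return A [track_set()].
#' @export
read_tracks <- function(path, frame_interval) {
  df <- read_checked_csv(path, c(track_id = "i", frame = "i",
                                 x_um = "d", y_um = "d"))
  track_set(df, frame_interval)
}

#' @rdname read_tracks
#' @param tracks A [track_set()].
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(as.data.frame(tracks)[c("track_id", "frame", "x_um", "y_um")],
                   path)
  invisible(path)
}

# strict CSV reader: required columns with given readr types, hard errors
# with row numbers on parse problems
read_checked_csv <- function(path, spec) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                            progress = FALSE)
  missing <- setdiff(names(spec), names(header))
  if (length(missing)) {
    abort(sprintf("missing column(s) in %s: %s", path,
                  paste(missing, collapse = ", ")))
  }
  types <- do.call(readr::cols_only, lapply(spec, function(t) {
    if (t == "d") readr::col_double() else readr::col_integer()
  }))
  df <- suppressWarnings(
    readr::read_csv(path, col_types = types, progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("parse error(s) in %s at row(s) %s: expected numeric values.",
                  path, paste(utils::head(unique(probs$row), 5), collapse = ", ")))
  }
  if (nrow(df) == 0) abort(sprintf("no data rows in %s", path))
  if (anyNA(df)) {
    abort(sprintf("missing values in %s at row(s) %s.", path,
                  paste(utils::head(which(rowSums(is.na(df)) > 0), 5),
                        collapse = ", ")))
  }
  df
}

#' Read and write single-channel TIFF images
#'
#' `read_image()` accepts 8/16-bit grayscale TIFFs (returning native
#' integer intensities) and the 32-bit float TIFFs written by
#' `write_image()`. Multi-page z-stacks are reduced by maximum-intensity
#' projection when `project_max = TRUE`, otherwise rejected; RGB input is
#' rejected with a pointer to channel extraction. Because the underlying
#' TIFF writer stores no custom tags, `write_image()` records the pixel
#' size and float intensity scale in a JSON sidecar file
#' (`<path>.meta.json`). The pixel size comes from the `pixel_size`
#' argument, the sidecar, the image description, or the TIFF x-resolution
#' tag (assumed pixels/cm) — in that order; if none is available an error
#' asks for the flag.
#'
#' @param path TIFF file path.
#' @param pixel_size Pixel size in um/px, overriding any file metadata.
#' @param project_max Reduce a multi-page stack by max projection.
#' @return A [gray_image()].
#' @export
read_image <- function(path, pixel_size = NULL, project_max = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # read normalised ([0, 1]) values: `as.is` mangles float TIFFs, so
  # integer counts are reconstructed from bits.per.sample afterwards
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  first <- pages[[1]]
  if (length(dim(first)) == 3) {
    abort("RGB/multi-channel TIFF: extract a single channel before analysis.")
  }
  if (length(pages) > 1 && !project_max) {
    abort(sprintf("%d-page stack: pass project_max = TRUE for a maximum-intensity projection.",
                  length(pages)))
  }
  m <- Reduce(function(a, b) pmax(a, unclass(b)), pages[-1],
              unclass(first))
  bits <- attr(first, "bits.per.sample")
  if (!is.null(bits) && bits %in% c(8L, 16L)) {
    m <- round(m * (2^bits - 1))  # native integer counts
  }
  meta <- read_image_sidecar(path)
  if (is.null(meta$microspacing)) {
    meta <- parse_image_description(attr(first, "description"))
  }
  if (!is.null(meta$scale) && meta$scale != 1) m <- m * meta$scale
  ps <- pixel_size
  if (is.null(ps)) ps <- meta$pixel_size_um
  if (is.null(ps)) {
    xres <- attr(first, "x.resolution")
    if (!is.null(xres) && is.numeric(xres) && xres > 0) ps <- 10000 / xres
  }
  if (is.null(ps)) {
    abort("no pixel size: supply `pixel_size` (um/px); the TIFF has no usable resolution metadata.")
  }
  gray_image(matrix(as.numeric(m), nrow(m), ncol(m)), ps)
}

#' @rdname read_image
#' @param img A [gray_image()] (or numeric matrix with nonnegative values).
#' @param bits Bits per sample: 8 or 16 write integer TIFFs (intensities
#'   must fit the type); 32 writes float with a recorded scale factor.
#' @export
write_image <- function(img, path, bits = 32L) {
  ps <- attr(img, "pixel_size")
  m <- unclass(img)
  if (bits %in% c(8L, 16L)) {
    top <- 2^bits - 1
    if (max(m) > top) abort(sprintf("intensities exceed %d; use bits = 32.", top))
    # the writer truncates rather than rounds, so centre each integer
    # count inside its quantisation bin
    out <- pmin((round(m) + 0.5) / top, 1)
    tiff::writeTIFF(out, path, bits.per.sample = as.integer(bits))
    scale <- 1
  } else if (bits == 32L) {
    scale <- max(m, 1)
    tiff::writeTIFF(m / scale, path, bits.per.sample = 32L)
  } else abort("`bits` must be 8, 16 or 32.")
  jsonlite::write_json(
    list(microspacing = TRUE, scale = scale, pixel_size_um = ps,
         bits = as.integer(bits)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_image_sidecar <- function(path) {
  side <- paste0(path, ".meta.json")
  if (!file.exists(side)) return(list())
  out <- tryCatch(jsonlite::fromJSON(side), error = function(e) NULL)
  if (is.null(out) || is.null(out$microspacing)) return(list())
  out
}

parse_image_description <- function(desc) {
  if (is.null(desc) || !is.character(desc) || !nzchar(desc)) return(list())
  out <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  if (is.null(out) || is.null(out$microspacing)) return(list())
  out
}

#' Write a reproducibility manifest for a computation
#'
#' Records the command name, full parameter set, seed(s), package and R
#' versions, a timestamp, and MD5 hashes of named input/output files —
#' enough to re-run the computation bit-identically.
#'
#' @param path Output JSON path.
#' @param command Short name of the computation.
#' @param params Named list of parameters (must be JSON-serialisable).
#' @param seed Seed(s) used.
#' @param inputs,outputs Character vectors of file paths to hash.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, command, params = list(), seed = NULL,
                           inputs = character(), outputs = character()) {
  hash <- function(files) {
    files <- files[file.exists(files)]
    as.list(tools::md5sum(files))
  }
  manifest <- list(
    command = command, params = params, seed = seed,
    package_version = as.character(utils::packageVersion("microspacing")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_hashes = hash(inputs), output_hashes = hash(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file may contain top-level keys `params` (fields of [model_params()])
#' and `config` (fields of [numerics_config()]); missing fields take the
#' package defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A list with elements `params` and `config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  list(params = do.call(model_params, as.list(raw$params %||% list())),
       config = do.call(numerics_config, as.list(raw$config %||% list())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
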