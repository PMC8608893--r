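#' Grayscale and binary microglia images
#'
#' Images are numeric matrices with rows = y and columns = x; a pixel at
#' `[row, col]` has physical centre `((col - 0.5) * pixel_size,
#' (row - 0.5) * pixel_size)` in um. `gray_image()` attaches the pixel size;
#' `binarize()` thresholds to a logical mask of class `binary_image`.
#'
#' @param pixels Numeric matrix of nonnegative intensities.
#' @param pixel_size Pixel size in um/px (> 0).
#' @return A matrix of class `gray_image` (or `binary_image`) with a
#'   `pixel_size` attribute.
#' @export
gray_image <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) abort("`pixels` must be a numeric matrix.")
  if (any(pixels < 0) || anyNA(pixels)) abort("intensities must be nonnegative and complete.")
  if (!is.numeric(pixel_size) || pixel_size <= 0) abort("`pixel_size` must be positive (um/px).")
  structure(pixels, pixel_size = pixel_size, class = c("gray_image", "matrix", "array"))
}

#' @rdname gray_image
#' @param img A `gray_image`.
#' @param threshold Intensity threshold; pixels `>= threshold` become
#'   foreground.
#' @export
binarize <- function(img, threshold) {
  mask <- unclass(img) >= threshold
  structure(mask, pixel_size = attr(img, "pixel_size"),
            class = c("binary_image", "matrix", "array"))
}

pixel_size_of <- function(img, pixel_size = NULL) {
  ps <- if (!is.null(pixel_size)) pixel_size else attr(img, "pixel_size")
  if (is.null(ps) || ps <= 0) abort("supply a positive `pixel_size` (um/px).")
  ps
}

#' Despeckle and smooth a grayscale image
#'
#' A 3x3 median filter (despeckle) followed by a small Gaussian blur, the
#' standard noise-removal step before thresholding.
#'
#' @param img A [gray_image()] (or numeric matrix).
#' @param median_radius Radius of the median filter (1 = 3x3 window).
#' @param blur_sigma Gaussian blur standard deviation in px; 0 disables.
#' @return A `gray_image` of the same shape and pixel size.
#' @export
preprocess_image <- function(img, median_radius = 1L, blur_sigma = 1) {
  ps <- pixel_size_of(img)
  m <- unclass(img)
  top <- max(m, 1)
  out <- EBImage::medianFilter(m / top, median_radius) * top
  if (blur_sigma > 0) out <- EBImage::gblur(out, sigma = blur_sigma)
  out <- pmax(as.matrix(out), 0)
  gray_image(out, ps)
}

#' Skeleton and Euclidean distance map of a binary image
#'
#' Topology-preserving (Zhang-Suen) thinning plus the Euclidean distance
#' transform to background, the two primitives of the morphometry chain:
#' sampling the distance map along the skeleton gives a per-pixel half-width,
#' and the skeleton itself carries process lengths.
#'
#' @param binary A [binarize()] mask (or logical matrix).
#' @return A list with `skeleton` (logical matrix) and `distmap` (numeric
#'   matrix, distances in px), both with the input's `pixel_size` attribute.
#' @export
skeleton_and_distance <- function(binary) {
  ps <- attr(binary, "pixel_size")
  m <- unclass(binary)
  storage.mode(m) <- "integer"
  if (!any(m != 0)) {
    z <- matrix(0, nrow(m), ncol(m))
    return(list(skeleton = structure(z != 0, pixel_size = ps),
                distmap = structure(z, pixel_size = ps)))
  }
  skel <- .cpp_thin(m) != 0
  dm <- as.matrix(EBImage::distmap(EBImage::Image(m), metric = "euclidean"))
  list(skeleton = structure(skel, pixel_size = ps),
       distmap = structure(dm, pixel_size = ps))
}

# zero-padded shift of a matrix by (dr, dc)
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(vector(typeof(m), 1), nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# number of 8-connected skeleton neighbours at each skeleton pixel
neighbor_count <- function(mask) {
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + shift_mat(mask * 1L, dr, dc)
  }
  acc
}

# Rutovitz crossing number: 0->1 transitions around the 8-neighbour ring.
# 1 at curve ends, 2 along a curve (including staircase corners), >= 3 at
# true branch points -- unlike the raw neighbour count, which misfires on
# corners of diagonal runs.
crossing_number <- function(mask) {
  ring <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nb <- lapply(ring, function(d) shift_mat(mask, d[1], d[2]))
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_along(nb)) {
    j <- if (i == length(nb)) 1L else i + 1L
    acc <- acc + (!nb[[i]] & nb[[j]])
  }
  acc
}

# pixel-step geodesic length of each labelled curve: 1 per axial adjacency,
# sqrt(2) per diagonal adjacency that is not shortcut by a shared axial
# neighbour (the staircase rule)
label_lengths_px <- function(lab) {
  n <- max(lab)
  if (n == 0) return(numeric(0))
  len <- numeric(n)
  add_pairs <- function(dr, dc, w, prune) {
    s <- shift_mat(lab, dr, dc)
    ok <- lab > 0 & s == lab
    if (prune) {
      a1 <- shift_mat(lab, dr, 0) == lab  # shared axial neighbours
      a2 <- shift_mat(lab, 0, dc) == lab
      ok <- ok & !(a1 | a2)
    }
    if (any(ok)) {
      tb <- tabulate(lab[ok], nbins = n)
      len <<- len + w * tb
    }
  }
  add_pairs(1, 0, 1, FALSE)
  add_pairs(0, 1, 1, FALSE)
  add_pairs(1, 1, sqrt(2), TRUE)
  add_pairs(1, -1, sqrt(2), TRUE)
  len
}

#' Total skeleton length of a binary image at a threshold
#'
#' @param img A [gray_image()].
#' @param threshold Intensity threshold.
#' @param pixel_size Pixel size um/px (defaults to the image's).
#' @return Total skeleton length in um (pixel-step geodesic).
#' @export
skeleton_length <- function(img, threshold, pixel_size = NULL) {
  ps <- pixel_size_of(img, pixel_size)
  sk <- skeleton_and_distance(binarize(img, threshold))$skeleton
  lab <- (sk * 1L)
  storage.mode(lab) <- "integer"
  sum(label_lengths_px(lab)) * ps
}

#' Threshold selection by the skeleton-explosion criterion
#'
#' Scans candidate thresholds from high to low, computing the total skeleton
#' length L(T) of the binarised image at each. Lowering the threshold below
#' the true foreground level floods the skeleton with background noise and
#' L(T) jumps; the function locates the smallest T whose next-lower
#' candidate satisfies `L(next) / L(T) > knee_factor` and returns the
#' candidate `step_back` positions above it (the candidate adjacent to the
#' jump already sits on the noise shoulder, so a one-step margin is kept by
#' default).
#'
#' @param img A [gray_image()] (preprocess first; see [preprocess_image()]).
#' @param candidate_thresholds Candidate thresholds; scanned in decreasing
#'   order.
#' @param knee_factor Relative jump in skeleton length that defines the
#'   explosion (default 3: flooding the noise floor at least triples the
#'   skeleton length between adjacent candidates, while gradual recovery of
#'   real structure stays below that).
#' @param step_back How many candidates above the explosion to report
#'   (default 1).
#' @return The selected threshold. If no knee is found, the smallest
#'   candidate is returned with a warning.
#' @export
select_threshold <- function(img, candidate_thresholds, knee_factor = 3,
                             step_back = 1) {
  cand <- sort(unique(candidate_thresholds), decreasing = TRUE)
  if (length(cand) < 2) abort("need at least 2 candidate thresholds.")
  L <- vapply(cand, function(th) skeleton_length(img, th), numeric(1))
  for (i in seq_len(length(cand) - 1)) {
    if (L[i] > 0 && L[i + 1] / L[i] > knee_factor) {
      return(cand[max(i - step_back, 1)])
    }
  }
  warn("no skeleton-length explosion found; returning the smallest candidate.")
  cand[length(cand)]
}

#' Mean structure thickness from skeleton and distance map
#'
#' The mean of the distance-map values sampled on the skeleton, converted to
#' um. The distance map holds distances to the nearest background pixel, so
#' this is a half-width proxy for structure thickness; it is reported as-is,
#' as in the original morphometry chain.
#'
#' @param skeleton Logical skeleton mask (from [skeleton_and_distance()]).
#' @param distmap Distance map in px, same shape.
#' @param pixel_size Pixel size, um/px (defaults to the skeleton's
#'   attribute).
#' @return Mean thickness in um.
#' @export
mean_thickness <- function(skeleton, distmap, pixel_size = NULL) {
  ps <- pixel_size_of(skeleton, pixel_size)
  if (!identical(dim(skeleton), dim(distmap))) abort("shape mismatch.")
  if (!any(skeleton)) abort("empty skeleton: no structures to measure.")
  mean(distmap[skeleton]) * ps
}

#' Soma detection and process decomposition of a skeletonised image
#'
#' Somata are detected as connected regions whose distance-map value reaches
#' `soma_min_radius` (structures at least that thick); the soma body used to
#' mask the skeleton is recovered by a morphological opening with a disc of
#' that radius, which erases thin processes but preserves the soma disks.
#' Skeleton pixels outside the soma bodies are decomposed at junction pixels
#' (Rutovitz crossing number >= 3, i.e. true branch points) into segments;
#' each segment's
#' pixel-step geodesic length is reported in um and the segment is assigned
#' to the nearest soma centroid. Fragments shorter than `min_segment_um`
#' (junction debris and single-pixel spurs produced by thinning) are
#' discarded, the usual pruning step of skeleton morphometry.
#'
#' @inheritParams mean_thickness
#' @param binary The binary mask the skeleton was computed from.
#' @param soma_min_radius Minimum soma half-width in um (default 3).
#' @param min_segment_um Discard segments shorter than this (default 2 um,
#'   about one pixel diagonal at typical resolution); set to 0 to keep all.
#' @return A list with `somata` (a [point_pattern()] of centroids, window =
#'   image extent), `processes` (tibble `segment_id`, `soma_id`,
#'   `length_um`) and `per_cell` (tibble `soma_id`, `x_um`, `y_um`,
#'   `n_processes`, `total_length_um`).
#' @export
extract_processes <- function(skeleton, distmap, binary,
                              soma_min_radius = 3, pixel_size = NULL,
                              min_segment_um = 2) {
  ps <- pixel_size_of(skeleton, pixel_size)
  if (!any(skeleton)) abort("empty skeleton.")
  core <- distmap * ps >= soma_min_radius
  if (!any(core)) abort("no cells: no region reaches soma_min_radius.")
  core_lab <- .cpp_label8(core * 1L)
  n_somata <- max(core_lab)
  cx <- numeric(n_somata); cy <- numeric(n_somata)
  for (s in seq_len(n_somata)) {
    idx <- which(core_lab == s, arr.ind = TRUE)
    cy[s] <- mean(idx[, 1] - 0.5) * ps
    cx[s] <- mean(idx[, 2] - 0.5) * ps
  }
  window <- c(0, 0, ncol(skeleton) * ps, nrow(skeleton) * ps)
  somata <- point_pattern(data.frame(x_um = cx, y_um = cy), window)

  brush_size <- 2 * floor(soma_min_radius / ps) + 1
  body <- if (brush_size >= 3) {
    b <- EBImage::opening(EBImage::Image((unclass(binary) != 0) * 1),
                          EBImage::makeBrush(brush_size, shape = "disc"))
    as.matrix(b) > 0
  } else core
  body <- body | core
  # grow the body by one pixel so skeleton remnants on the soma rim cannot
  # bridge adjacent processes into one segment
  body <- EBImage::dilate(EBImage::Image(body * 1),
                          EBImage::makeBrush(3, shape = "box")) > 0

  proc_skel <- skeleton & !body
  if (!any(proc_skel)) {
    return(list(
      somata = somata,
      processes = tibble(segment_id = integer(0), soma_id = integer(0),
                         length_um = numeric(0)),
      per_cell = tibble(soma_id = seq_len(n_somata), x_um = cx, y_um = cy,
                        n_processes = 0L, total_length_um = 0)))
  }
  junctions <- proc_skel & crossing_number(proc_skel) >= 3
  seg_mask <- proc_skel & !junctions
  seg_lab <- .cpp_label8(seg_mask * 1L)
  lens <- label_lengths_px(seg_lab) * ps
  keep <- which(lens >= min_segment_um)
  relab <- integer(max(seg_lab, 1L))
  relab[keep] <- seq_along(keep)
  seg_lab[] <- ifelse(seg_lab > 0, relab[pmax(seg_lab, 1L)], 0L)
  lens <- lens[keep]
  n_seg <- length(keep)
  if (n_seg == 0) {
    return(list(
      somata = somata,
      processes = tibble(segment_id = integer(0), soma_id = integer(0),
                         length_um = numeric(0)),
      per_cell = tibble(soma_id = seq_len(n_somata), x_um = cx, y_um = cy,
                        n_processes = 0L, total_length_um = 0)))
  }

  soma_id <- integer(n_seg)
  for (s in seq_len(n_seg)) {
    idx <- which(seg_lab == s, arr.ind = TRUE)
    px <- (idx[, 2] - 0.5) * ps
    py <- (idx[, 1] - 0.5) * ps
    d2 <- outer(px, cx, "-")^2 + outer(py, cy, "-")^2
    soma_id[s] <- which.min(apply(d2, 2, min))
  }
  processes <- tibble(segment_id = seq_len(n_seg), soma_id = soma_id,
                      length_um = lens)
  counts <- tabulate(soma_id, nbins = n_somata)
  totals <- vapply(seq_len(n_somata),
                   function(s) sum(lens[soma_id == s]), numeric(1))
  per_cell <- tibble(soma_id = seq_len(n_somata), x_um = cx, y_um = cy,
                     n_processes = as.integer(counts),
                     total_length_um = totals)
  list(somata = somata, processes = processes, per_cell = per_cell)
}

#' Full morphometry chain on one image
#'
#' Runs despeckle/smooth, threshold selection (unless `threshold` is given),
#' skeletonisation and distance transform, thickness, process decomposition,
#' cell density, and the Hopkins-Skellam index of the soma pattern.
#'
#' @param img A [gray_image()].
#' @param threshold Fixed threshold, or `NULL` to select one from
#'   `candidate_thresholds` via [select_threshold()].
#' @param candidate_thresholds Candidates for automatic selection (default:
#'   every integer from the 99.5th intensity percentile down to 1).
#' @param soma_min_radius Minimum soma half-width, um.
#' @param preprocess Apply [preprocess_image()] first (default TRUE).
#' @param hsi_seed Seed for the soma-pattern regularity index.
#' @param pixel_size Pixel size, um/px (defaults to the image's).
#' @return A one-row tibble: `threshold`, `mean_thickness_um`, `n_cells`,
#'   `density_cells_mm2`, `processes_per_cell`, `avg_process_length_um`,
#'   `process_length_per_cell_um`, `soma_hsi`.
#' @export
morphology_metrics <- function(img, threshold = NULL,
                               candidate_thresholds = NULL,
                               soma_min_radius = 3, preprocess = TRUE,
                               hsi_seed = 1L, pixel_size = NULL) {
  ps <- pixel_size_of(img, pixel_size)
  img <- gray_image(unclass(img), ps)
  if (preprocess) img <- preprocess_image(img)
  if (is.null(threshold)) {
    if (is.null(candidate_thresholds)) {
      # ~25 levels: steps coarse enough that dropping into the noise floor
      # at least doubles the skeleton length between adjacent candidates
      top <- stats::quantile(unclass(img), 0.995)
      candidate_thresholds <- unique(round(seq(floor(top), 1,
                                               length.out = 25)))
    }
    threshold <- select_threshold(img, candidate_thresholds)
  }
  bin <- binarize(img, threshold)
  sd_ <- skeleton_and_distance(bin)
  thick <- mean_thickness(sd_$skeleton, sd_$distmap, ps)
  ext <- extract_processes(sd_$skeleton, sd_$distmap, bin,
                           soma_min_radius = soma_min_radius, pixel_size = ps)
  n_cells <- nrow(ext$somata)
  area_mm2 <- window_area(attr(ext$somata, "window")) / 1e6
  soma_hsi <- if (n_cells >= 2) hsi(ext$somata, seed = hsi_seed)$hsi else NA_real_
  tibble(
    threshold = threshold,
    mean_thickness_um = thick,
    n_cells = n_cells,
    density_cells_mm2 = n_cells / area_mm2,
    processes_per_cell = mean(ext$per_cell$n_processes),
    avg_process_length_um = if (nrow(ext$processes)) mean(ext$processes$length_um) else NA_real_,
    process_length_per_cell_um = mean(ext$per_cell$total_length_um),
    soma_hsi = soma_hsi)
}
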