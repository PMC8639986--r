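#' Tile a masked membrane image into square segments
#'
#' Tiles the bounding box of the cell mask into `segment_size` x
#' `segment_size` pixel blocks anchored at the bounding-box origin, keeps
#' only blocks lying fully inside the mask (so every retained segment has the
#' same pixel count and comparable variance estimates), and computes the mean
#' intensity and unbiased (n-1) variance per block.
#'
#' @param image A `photon_image` (see [sim_membrane_image()]) or a numeric
#'   matrix of counts.
#' @param mask Optional logical matrix (required when `image` is a bare
#'   matrix; taken from the object otherwise).
#' @param segment_size Segment edge length in pixels (default 15).
#' @param cell_id Identifier attached to every segment (default 1).
#' @return Tibble of class-free segment statistics: `cell_id`,
#'   `segment_index`, `row0`, `col0` (1-based segment origin), `n_pixels`,
#'   `mean_intensity`, `variance`. Empty (with a warning) when the mask is
#'   smaller than one segment.
#' @examples
#' img <- sim_membrane_image(shape = c(45, 45), seed = 1)
#' segment_cell(img)
#' @export
segment_cell <- function(image, mask = NULL, segment_size = 15, cell_id = 1L) {
  if (inherits(image, "photon_image")) {
    if (is.null(mask)) mask <- image$mask
    counts <- image$counts
  } else {
    counts <- image
    if (is.null(mask)) mask <- matrix(TRUE, nrow(counts), ncol(counts))
  }
  check_count(segment_size, "segment_size", min = 2L)
  if (!is.matrix(mask) || !all(dim(mask) == dim(counts))) {
    abort("`mask` must be a logical matrix with the same shape as the counts.")
  }
  if (!any(mask)) abort("Mask is empty.")
  empty_segments <- function() {
    tibble::tibble(cell_id = integer(0), segment_index = integer(0),
                   row0 = integer(0), col0 = integer(0),
                   n_pixels = integer(0), mean_intensity = double(0),
                   variance = double(0))
  }
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  if (rows[2] - rows[1] + 1 < segment_size ||
      cols[2] - cols[1] + 1 < segment_size) {
    warn("Mask smaller than one segment; returning no segments.")
    return(empty_segments())
  }
  r_starts <- seq(rows[1], rows[2] - segment_size + 1, by = segment_size)
  c_starts <- seq(cols[1], cols[2] - segment_size + 1, by = segment_size)
  grid <- expand.grid(row0 = r_starts, col0 = c_starts)
  segs <- purrr::pmap(grid, function(row0, col0) {
    ri <- row0:(row0 + segment_size - 1)
    ci <- col0:(col0 + segment_size - 1)
    if (!all(mask[ri, ci])) return(NULL)
    block <- counts[ri, ci]
    tibble::tibble(row0 = row0, col0 = col0,
                   n_pixels = length(block),
                   mean_intensity = mean(block),
                   variance = var(as.vector(block)))
  })
  segs <- dplyr::bind_rows(segs)
  if (nrow(segs) == 0) {
    warn("No segment lies fully inside the mask.")
    return(empty_segments())
  }
  dplyr::mutate(segs, cell_id = cell_id,
                segment_index = dplyr::row_number(), .before = 1)
}

#' Molecular brightness per image segment
#'
#' Adds the molecular brightness (photons per molecule per exposure) to a
#' segment table. For a photon-counting detector
#' \eqn{\varepsilon = \sigma^2 / \langle I\rangle - 1} (shot noise carries
#' brightness 0); for an analog detector
#' \eqn{\varepsilon = (\sigma^2 - \sigma_D^2) / \langle I\rangle} where
#' \eqn{\sigma_D^2} is the detector noise variance. Segments with zero mean
#' intensity have undefined brightness and are flagged invalid (excluded
#' from downstream summaries).
#'
#' @param stats Segment table from [segment_cell()].
#' @param detector `"photon_counting"` (default) or `"analog"`.
#' @param detector_var Detector noise variance \eqn{\sigma_D^2} (analog only).
#' @return The segment tibble with columns `brightness`, `valid`, and
#'   `concentration` (intensity / brightness; `NA` for non-positive
#'   brightness).
#' @examples
#' img <- sim_membrane_image(shape = c(60, 60), seed = 2)
#' seg <- segment_brightness(segment_cell(img))
#' median(seg$brightness)
#' @export
segment_brightness <- function(stats,
                               detector = c("photon_counting", "analog"),
                               detector_var = 0) {
  detector <- match.arg(detector)
  check_columns(stats, c("mean_intensity", "variance"), "stats")
  check_number(detector_var, "detector_var", lower = 0)
  eps <- ifelse(
    stats$mean_intensity > 0,
    if (detector == "photon_counting") {
      stats$variance / stats$mean_intensity - 1
    } else {
      (stats$variance - detector_var) / stats$mean_intensity
    },
    NA_real_
  )
  dplyr::mutate(
    stats,
    brightness = eps,
    valid = !is.na(eps),
    concentration = ifelse(!is.na(eps) & eps > 0,
                           .data$mean_intensity / eps, NA_real_)
  )
}

#' Normalized, cell-averaged brightness distribution
#'
#' Histograms segment brightness per cell over shared (by default
#' log-spaced) bins, normalizes each per-cell histogram to unit sum, and
#' averages the normalized curves across cells; the spread across cells gives
#' the standard-error band. Cells are the unit of averaging; segment counts
#' per cell are not equalized.
#'
#' @param segments Segment table from [segment_brightness()] covering one or
#'   more cells (`cell_id` column).
#' @param bins Optional numeric vector of bin edges shared by all cells. By
#'   default, log-spaced bins over the central 99% of the positive
#'   brightness values.
#' @param n_bins Number of bins when `bins` is not given (default 40).
#' @param scale `"log"` (default) or `"linear"` bin spacing; negative
#'   brightness segments (possible from noise) can only be binned on the
#'   linear scale and are otherwise omitted from the histogram.
#' @param min_segments Minimum valid segments required per cell (default 10).
#' @return Object of class `brightness_distribution`: list with `curve`
#'   (tibble: `bin_left`, `bin_right`, `mid`, `mean`, `se`), `per_cell`
#'   (cells x bins matrix of normalized counts), `bin_edges`, `n_cells`,
#'   `cell_medians` (named per-cell median brightness) and
#'   `median_brightness` (pooled over all valid segments).
#' @examples
#' segs <- dplyr::bind_rows(lapply(1:3, function(i)
#'   segment_brightness(segment_cell(sim_membrane_image(seed = i),
#'                                   cell_id = i))))
#' bd <- brightness_distribution(segs)
#' bd$median_brightness
#' @export
brightness_distribution <- function(segments, bins = NULL, n_bins = 40,
                                    scale = c("log", "linear"),
                                    min_segments = 10) {
  scale <- match.arg(scale)
  check_columns(segments, c("cell_id", "brightness", "valid"), "segments")
  segments <- segments[segments$valid, , drop = FALSE]
  counts_per_cell <- table(segments$cell_id)
  keep_cells <- names(counts_per_cell)[counts_per_cell >= min_segments]
  segments <- segments[as.character(segments$cell_id) %in% keep_cells, ,
                       drop = FALSE]
  if (nrow(segments) == 0) abort("No cell has enough valid segments.")
  eps <- segments$brightness
  if (is.null(bins)) {
    if (scale == "log") {
      pos <- eps[eps > 0]
      if (length(pos) < 2) abort("Not enough positive brightness values for log bins.")
      lim <- quantile(pos, c(0.005, 0.995))
      bins <- exp(seq(log(lim[1]), log(lim[2]), length.out = n_bins + 1))
    } else {
      lim <- quantile(eps, c(0.005, 0.995))
      bins <- seq(lim[1], lim[2], length.out = n_bins + 1)
    }
  }
  if (is.unsorted(bins, strictly = TRUE)) {
    abort("`bins` must be strictly increasing edges.")
  }
  cells <- unique(segments$cell_id)
  per_cell <- t(vapply(cells, function(cl) {
    e <- segments$brightness[segments$cell_id == cl]
    e <- e[e >= bins[1] & e <= bins[length(bins)]]
    h <- graphics::hist(e, breaks = bins, plot = FALSE)$counts
    if (sum(h) > 0) h / sum(h) else h * 0
  }, numeric(length(bins) - 1)))
  rownames(per_cell) <- as.character(cells)
  n_cells <- length(cells)
  mean_curve <- colMeans(per_cell)
  se_curve <- if (n_cells > 1) {
    apply(per_cell, 2, sd) / sqrt(n_cells)
  } else {
    rep(0, ncol(per_cell))
  }
  mids <- if (scale == "log") sqrt(head(bins, -1) * tail(bins, -1)) else
    (head(bins, -1) + tail(bins, -1)) / 2
  cell_medians <- vapply(cells, function(cl)
    median(segments$brightness[segments$cell_id == cl]), 0.0)
  names(cell_medians) <- as.character(cells)
  structure(
    list(
      curve = tibble::tibble(bin_left = head(bins, -1),
                             bin_right = tail(bins, -1),
                             mid = mids, mean = mean_curve, se = se_curve),
      per_cell = per_cell, bin_edges = bins, n_cells = n_cells,
      cell_medians = cell_medians,
      median_brightness = median(segments$brightness),
      scale = scale
    ),
    class = "brightness_distribution"
  )
}

#' @export
print.brightness_distribution <- function(x, ...) {
  cat(sprintf(
    "brightness_distribution: %d cells, %d bins (%s scale), median brightness %.3g\n",
    x$n_cells, nrow(x$curve), x$scale, x$median_brightness))
  invisible(x)
}

#' Place a brightness distribution relative to monomer and dimer controls
#'
#' Compares the pooled median brightness of a distribution against monomer
#' and dimer reference distributions computed over the same bins, reporting
#' the median ratios and a three-way classification (below/at monomer,
#' between, at/above dimer).
#'
#' @param dist,monomer_ref,dimer_ref `brightness_distribution` objects with
#'   identical bin edges.
#' @param tol Relative tolerance for calling a median "at" a reference
#'   (default 0.1).
#' @return One-row tibble: `ratio_vs_monomer`, `ratio_vs_dimer`,
#'   `classification`.
#' @export
compare_to_references <- function(dist, monomer_ref, dimer_ref, tol = 0.1) {
  for (obj in list(dist, monomer_ref, dimer_ref)) {
    if (!inherits(obj, "brightness_distribution")) {
      abort("All inputs must be brightness_distribution objects.")
    }
  }
  if (!isTRUE(all.equal(dist$bin_edges, monomer_ref$bin_edges)) ||
      !isTRUE(all.equal(dist$bin_edges, dimer_ref$bin_edges))) {
    abort("Bin edges differ between distributions; re-bin on shared edges.")
  }
  m <- dist$median_brightness
  r_mono <- m / monomer_ref$median_brightness
  r_dim <- m / dimer_ref$median_brightness
  cls <- if (r_mono < 1 - tol) {
    "below monomer"
  } else if (abs(r_mono - 1) <= tol) {
    "at monomer"
  } else if (r_dim > 1 + tol) {
    "above dimer"
  } else if (abs(r_dim - 1) <= tol) {
    "at dimer"
  } else {
    "between"
  }
  tibble::tibble(ratio_vs_monomer = r_mono, ratio_vs_dimer = r_dim,
                 classification = cls)
}
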