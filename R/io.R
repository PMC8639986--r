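#' Write a photon-count image (and mask) to disk
#'
#' Supports 16-bit grayscale TIFF (via the tiff package) and a portable
#' whitespace-separated text grid (one image row per line; `#` header).
#'
#' @param image `photon_image` object or integer matrix.
#' @param path Output path; format chosen by extension (`.tif`/`.tiff` or
#'   anything else for text).
#' @param what `"counts"` (default) or `"mask"`.
#' @export
write_photon_image <- function(image, path, what = c("counts", "mask")) {
  what <- match.arg(what)
  m <- if (inherits(image, "photon_image")) image[[what]] else image
  if (what == "mask") m <- m * 1L
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Package `tiff` is required for TIFF output.")
    }
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# photon image %d x %d", nrow(m), ncol(m)), con)
    utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a photon-count image written by [write_photon_image()]
#'
#' @param path File path (TIFF or text grid).
#' @return Numeric matrix of counts.
#' @export
read_photon_image <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Package `tiff` is required for TIFF input.")
    }
    round(tiff::readTIFF(path) * 65535)
  } else {
    as.matrix(utils::read.table(path, comment.char = "#"))
  }
}

#' Write FRET samples in the documented CSV dialect
#'
#' Columns: `region_id`, `donor_density`, `acceptor_density`, `fret`
#' (total density = donor + acceptor; acceptor fraction =
#' acceptor / total).
#'
#' @param samples Tibble with `region_id`, `total_density`,
#'   `acceptor_fraction`, `fret`.
#' @param path Output CSV path.
#' @export
write_fret_samples <- function(samples, path) {
  check_columns(samples, c("region_id", "total_density", "acceptor_fraction",
                           "fret"), "samples")
  out <- tibble::tibble(
    region_id = samples$region_id,
    donor_density = samples$total_density * (1 - samples$acceptor_fraction),
    acceptor_density = samples$total_density * samples$acceptor_fraction,
    fret = samples$fret
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
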