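# File I/O: float32 TIFF for images and sinograms with JSON sidecars.
# TIFF samples are stored rescaled to [0, 1] (the tiff package clamps values
# outside that range); the sidecar keeps the original range plus any
# acquisition metadata, so round trips are exact to float32 precision.

.sidecar <- function(path) paste0(path, ".json")

#' Write an image as single-page float32 TIFF
#'
#' The pixel values are mapped to \[0, 1\] for storage; the original range
#' (and any `extra` metadata) goes to the sidecar `<path>.json`.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @param extra named list of additional metadata for the sidecar.
#' @export
write_slice_tiff <- function(image, path, extra = list()) {
  lo <- min(image); hi <- max(image)
  scaled <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- c(list(min = lo, max = hi), extra)
  jsonlite::write_json(meta, .sidecar(path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an image written by [write_slice_tiff()]
#' @param path TIFF path.
#' @return numeric matrix (attribute `"meta"` holds any extra sidecar fields).
#' @export
read_slice_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  meta <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
  out <- m * (meta$max - meta$min) + meta$min
  attr(out, "meta") <- meta[setdiff(names(meta), c("min", "max"))]
  out
}

#' Write a sinogram (float32 TIFF + JSON sidecar)
#'
#' The TIFF stores the `n_angles x width` matrix; the sidecar records the
#' value range, angles, detector center and width.
#'
#' @param sino a [sinogram()].
#' @param path TIFF output path.
#' @export
write_sinogram_tiff <- function(sino, path) {
  write_slice_tiff(sino$data, path,
                   extra = list(angles = sino$angles, center = sino$center,
                                width = ncol(sino$data)))
  invisible(path)
}

#' Read a sinogram written by [write_sinogram_tiff()]
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return a [sinogram()].
#' @export
read_sinogram_tiff <- function(path) {
  data <- read_slice_tiff(path)
  meta <- attr(data, "meta")
  attr(data, "meta") <- NULL
  sinogram(data, meta$angles, meta$center)
}

#' Write a simulated local-tomography setup to a directory
#'
#' Writes `phantom.tif`, `sinogram.tif`, `truth_roi.tif` (each with sidecar)
#' and `setup.json` (geometry and known zone) so a setup can be reconstructed
#' later or from the command line.
#'
#' @param setup result of [make_local_setup()].
#' @param dir output directory (created if missing).
#' @export
write_setup <- function(setup, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_slice_tiff(setup$phantom, file.path(dir, "phantom.tif"))
  write_slice_tiff(setup$truth_roi, file.path(dir, "truth_roi.tif"))
  write_sinogram_tiff(setup$sinogram, file.path(dir, "sinogram.tif"))
  g <- setup$geom
  z <- setup$zone
  jsonlite::write_json(
    list(geometry = list(n_roi = g$n_roi, n_ext = g$n_ext, n_full = g$n_full,
                         n_angles = g$n_angles, center = g$center,
                         angles = g$angles),
         known_zone = list(rows = z$rows, cols = z$cols, values = z$values,
                           weight = z$weight)),
    file.path(dir, "setup.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a setup directory written by [write_setup()]
#' @param dir setup directory.
#' @return list with `geom`, `zone`, `sinogram`, `truth_roi`, `phantom`.
#' @export
read_setup <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "setup.json"),
                              simplifyVector = TRUE)
  g <- meta$geometry
  geom <- local_geometry(g$n_roi, g$n_ext, n_full = g$n_full,
                         angles = g$angles, center = g$center)
  z <- meta$known_zone
  zone <- known_zone(z$rows, z$cols, z$values, z$weight)
  strip <- function(x) { attr(x, "meta") <- NULL; x }
  list(geom = geom, zone = zone,
       sinogram = read_sinogram_tiff(file.path(dir, "sinogram.tif")),
       truth_roi = strip(read_slice_tiff(file.path(dir, "truth_roi.tif"))),
       phantom = strip(read_slice_tiff(file.path(dir, "phantom.tif"))))
}
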