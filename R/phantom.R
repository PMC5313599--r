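# Shepp-Logan phantoms, local-tomography geometries and known zones.

# Classical Shepp-Logan ellipse table: additive intensity, semi-axes (a, b),
# center (x0, y0) in the unit disk, rotation phi in degrees.
.shepp_logan_table <- function(variant = c("classical", "modified")) {
  variant <- match.arg(variant)
  tab <- data.frame(
    A   = c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b   = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  )
  if (variant == "modified") {
    tab$A <- c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  }
  tab
}

#' Shepp-Logan head phantom
#'
#' Samples the standard 10-ellipse Shepp-Logan head phantom on a `side^2`
#' pixel grid. The unit disk of the analytical phantom is mapped to the disk
#' inscribed in the grid; the value of a pixel is the sum of the intensities
#' of all ellipses containing its center. Deterministic.
#'
#' @param side grid side in pixels (>= 2).
#' @param variant `"classical"` (original low-contrast intensities, values in
#'   about \[0, 2.04\]) or `"modified"` (high-contrast variant, values in
#'   \[0, 1\], convenient for display).
#' @return a `side x side` numeric matrix.
#' @examples
#' ph <- shepp_logan(64)
#' range(ph)
#' @export
shepp_logan <- function(side, variant = c("classical", "modified")) {
  if (!is.numeric(side) || length(side) != 1 || side < 2) {
    stop("'side' must be a single integer >= 2")
  }
  side <- as.integer(side)
  tab <- .shepp_logan_table(match.arg(variant))
  # normalized coordinates: pixel (i, j) -> (x, y) in [-1, 1]
  c0 <- (side - 1) / 2
  xs <- ((seq_len(side) - 1) - c0) / (side / 2)
  ys <- (c0 - (seq_len(side) - 1)) / (side / 2)  # row 1 is the top (y = +)
  X <- matrix(xs, nrow = side, ncol = side, byrow = TRUE)
  Y <- matrix(ys, nrow = side, ncol = side)
  img <- matrix(0, side, side)
  for (e in seq_len(nrow(tab))) {
    th <- tab$phi[e] * pi / 180
    xr <- (X - tab$x0[e]) * cos(th) + (Y - tab$y0[e]) * sin(th)
    yr <- -(X - tab$x0[e]) * sin(th) + (Y - tab$y0[e]) * cos(th)
    inside <- (xr / tab$a[e])^2 + (yr / tab$b[e])^2 <= 1
    img[inside] <- img[inside] + tab$A[e]
  }
  img
}

#' Local-tomography acquisition geometry
#'
#' Describes a truncated parallel-beam acquisition: detector (ROI) width
#' `n_roi` = N, extended reconstruction width `n_ext` = N2 (the support on
#' which the exterior is estimated), the true object width `n_full` = N0
#' (known for simulations only), and `n_angles` = Np view angles evenly
#' spaced over the half turn \[0, pi).
#'
#' @param n_roi detector width N in pixels.
#' @param n_ext extended width N2 >= N.
#' @param n_angles number of projection angles Np.
#' @param n_full full object width N0 (NA when unknown).
#' @param angles optional explicit angles in radians, strictly increasing in
#'   \[0, pi); default `seq(0, pi, length.out = n_angles + 1)[1:n_angles]`.
#' @param center continuous detector coordinate of the rotation axis on the
#'   extended detector (default `(n_ext - 1) / 2`).
#' @return an object of class `"local_geometry"`.
#' @export
local_geometry <- function(n_roi, n_ext = NULL, n_angles = NULL, n_full = NA,
                           angles = NULL, center = NULL) {
  n_roi <- as.integer(n_roi)
  if (is.null(n_ext)) n_ext <- n_roi
  n_ext <- as.integer(n_ext)
  if (n_ext < n_roi) stop("n_ext must be >= n_roi")
  if (is.null(angles)) {
    if (is.null(n_angles)) stop("give n_angles or angles")
    angles <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  }
  if (any(diff(angles) <= 0) || any(angles < 0) || any(angles >= pi)) {
    stop("angles must be strictly increasing within [0, pi)")
  }
  if (is.null(center)) center <- (n_ext - 1) / 2
  if (center < 0 || center >= n_ext) stop("center must lie within [0, n_ext)")
  structure(list(n_roi = n_roi, n_ext = n_ext, n_full = n_full,
                 n_angles = length(angles), angles = as.numeric(angles),
                 center = center),
            class = "local_geometry")
}

#' @export
print.local_geometry <- function(x, ...) {
  cat(sprintf("local_geometry: N=%d, N2=%d, N0=%s, Np=%d, center=%.2f\n",
              x$n_roi, x$n_ext, ifelse(is.na(x$n_full), "?", x$n_full),
              x$n_angles, x$center))
  invisible(x)
}

#' Known subregion of the ROI
#'
#' The zone Omega where the attenuation values are known a priori (for real
#' scans, e.g. an air pocket where attenuation is zero). Coordinates are
#' 0-based `(row, col)` pixel positions in the N^2 ROI frame.
#'
#' @param rows,cols integer 0-based pixel coordinates inside the ROI disk.
#' @param values known attenuation values at those pixels.
#' @param weight nonnegative penalty weight (beta) for the constraint.
#' @return an object of class `"known_zone"`.
#' @export
known_zone <- function(rows, cols, values, weight = 1) {
  if (length(rows) != length(cols) || length(rows) != length(values)) {
    stop("rows, cols and values must have equal length")
  }
  if (length(rows) < 1) stop("the known zone must contain at least one pixel")
  if (!all(is.finite(values))) stop("known values must be finite")
  if (weight < 0) stop("weight must be nonnegative")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 values = as.numeric(values), weight = weight),
            class = "known_zone")
}

#' @export
print.known_zone <- function(x, ...) {
  cat(sprintf("known_zone: %d pixels, value range [%.4g, %.4g], weight %.3g\n",
              length(x$rows), min(x$values), max(x$values), x$weight))
  invisible(x)
}

#' Simulate a local-tomography acquisition from a phantom
#'
#' Projects the full phantom over `n_angles` angles in \[0, pi), truncates
#' the sinogram to the `roi_diameter` central detector columns, and reads
#' the known-zone values off the phantom inside a disk of radius
#' `known_radius` centered (by default) on the ROI center.
#'
#' @param phantom square matrix, the full object (side N0).
#' @param roi_diameter detector width N (<= N0).
#' @param n_angles number of projections Np.
#' @param known_radius radius of the known disk in pixels
#'   (default `roi_diameter / 10`); must satisfy `known_radius < roi_diameter/2`.
#' @param known_center 0-based `(row, col)` center of the known disk in the
#'   ROI frame (default the ROI center).
#' @param n_ext extended width N2 used downstream (default
#'   `2 * roi_diameter + 28`, roughly a 2.1x extension; any
#'   value >= N is valid). Stored in the returned geometry.
#' @param noise_sd optional additive Gaussian noise (sinogram units) applied
#'   to the truncated sinogram; 0 disables it.
#' @return list with elements `geom` (`local_geometry`), `zone`
#'   (`known_zone`), `sinogram` (truncated, class `"sinogram"`),
#'   `sinogram_full`, `truth_roi` (N^2 ground-truth crop), `phantom`.
#' @export
make_local_setup <- function(phantom, roi_diameter, n_angles,
                             known_radius = NULL, known_center = NULL,
                             n_ext = NULL, noise_sd = 0) {
  n_full <- nrow(phantom)
  if (ncol(phantom) != n_full) stop("phantom must be square")
  n <- as.integer(roi_diameter)
  if (n > n_full) stop("roi_diameter must be <= the phantom side")
  if (is.null(known_radius)) known_radius <- n / 10
  if (known_radius >= n / 2) stop("the known disk must lie strictly inside the ROI")
  if (is.null(n_ext)) n_ext <- min(n_full + 60L, 2L * n + 28L)
  n_ext <- max(as.integer(n_ext), n)

  geom <- local_geometry(n_roi = n, n_ext = n_ext, n_angles = n_angles,
                         n_full = n_full)
  full <- project(phantom, geom)
  trunc <- crop_sinogram(full, n)
  if (noise_sd > 0) trunc$data <- trunc$data + matrix(
    rnorm(length(trunc$data), sd = noise_sd), nrow(trunc$data))

  # known zone: pixels with center strictly within known_radius of its center
  croi <- (n - 1) / 2
  kc <- if (is.null(known_center)) c(croi, croi) else as.numeric(known_center)
  if (sqrt(sum((kc - croi)^2)) + known_radius >= n / 2) {
    stop("the known disk must lie strictly inside the ROI disk")
  }
  grid <- expand.grid(row = 0:(n - 1), col = 0:(n - 1))
  r <- sqrt((grid$row - kc[1])^2 + (grid$col - kc[2])^2)
  keep <- r < known_radius
  if (!any(keep)) stop("known disk contains no pixel center")
  off <- (n_full - n) %/% 2   # ROI frame -> phantom frame offset
  vals <- phantom[cbind(grid$row[keep] + off + 1L, grid$col[keep] + off + 1L)]
  zone <- known_zone(grid$row[keep], grid$col[keep], vals)

  truth <- crop_image(phantom, n)
  list(geom = geom, zone = zone, sinogram = trunc, sinogram_full = full,
       truth_roi = truth, phantom = phantom)
}

#' Mask of the ROI disk
#'
#' Logical mask of the disk inscribed in an `n x n` square (pixel centers at
#' distance <= (n-1)/2 from the center), the support on which ROI metrics
#' are evaluated.
#'
#' @param n side in pixels.
#' @return `n x n` logical matrix.
#' @export
roi_disk_mask <- function(n) {
  c0 <- (n - 1) / 2
  d <- (seq_len(n) - 1) - c0
  outer(d, d, function(a, b) sqrt(a^2 + b^2)) <= (n - 1) / 2
}
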