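# Parallel-beam projection, sinogram padding/cropping and padded FBP.

#' Sinogram container
#'
#' @param data `n_angles x width` matrix of line integrals (rows are angles).
#' @param angles view angles in radians.
#' @param center continuous detector coordinate of the rotation axis.
#' @return object of class `"sinogram"`.
#' @export
sinogram <- function(data, angles, center = (ncol(data) - 1) / 2) {
  if (nrow(data) != length(angles)) stop("rows of data must match angles")
  structure(list(data = data, angles = as.numeric(angles), center = center),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d angles x %d bins, center %.2f\n",
              nrow(x$data), ncol(x$data), x$center))
  invisible(x)
}

.sino_width <- function(s) ncol(s$data)

#' Project an image (parallel beam, Joseph linear interpolation)
#'
#' Line integrals of a square image over the angles of `geom`. The detector
#' width equals the image side: pass an extended (N2^2) image to realize the
#' wide projector, or the full phantom (N0^2) for simulation. Linear in the
#' image; the exact algebraic adjoint is [backproject()].
#'
#' @param image square numeric matrix with side `geom$n_ext` or `geom$n_full`.
#' @param geom a [local_geometry()].
#' @return a [sinogram()] of width equal to the image side.
#' @export
project <- function(image, geom) {
  side <- nrow(image)
  if (ncol(image) != side) stop("image must be square")
  if (!(side %in% c(geom$n_ext, geom$n_full))) {
    stop("image side must equal geom$n_ext (or geom$n_full for simulation)")
  }
  center <- if (side == geom$n_ext) geom$center else (side - 1) / 2
  st <- joseph_project_cpp(image, geom$angles, center, side)
  sinogram(t(st), geom$angles, center)
}

#' Backproject a sinogram (adjoint of [project()])
#'
#' Exact algebraic transpose of the Joseph projector (same ray weights,
#' scattered instead of gathered). This is an unfiltered backprojection; for
#' reconstruction use [padded_fbp()].
#'
#' @param sino a [sinogram()].
#' @param geom a [local_geometry()]; the output side equals the sinogram width.
#' @return square numeric matrix.
#' @export
backproject <- function(sino, geom) {
  if (!identical(length(geom$angles), nrow(sino$data))) {
    stop("sinogram angles do not match the geometry")
  }
  joseph_backproject_cpp(t(sino$data), geom$angles, sino$center,
                         .sino_width(sino))
}

#' Pad sinogram rows by edge replication
#'
#' Widens each row to `new_width` by replicating its first/last value, the
#' standard extrapolation that suppresses truncation (Gibbs) artifacts in
#' local tomography. When the width difference is odd the extra column goes
#' to the right.
#'
#' @param sino a [sinogram()].
#' @param new_width target width (>= current width).
#' @return padded [sinogram()] with the center shifted accordingly.
#' @export
pad_sinogram <- function(sino, new_width) {
  w <- .sino_width(sino)
  if (new_width < w) stop("new_width must be >= the current width")
  if (new_width == w) return(sino)
  left <- (new_width - w) %/% 2
  right <- new_width - w - left
  d <- sino$data
  out <- cbind(matrix(d[, 1], nrow(d), left),
               d,
               matrix(d[, w], nrow(d), right))
  sinogram(out, sino$angles, sino$center + left)
}

#' Crop a sinogram to its central columns (operator C)
#'
#' Keeps the `n_roi` central detector columns of every row, modelling the
#' limited detector field of view. Inverts [pad_sinogram()] on the original
#' width; its adjoint is zero-extension of the columns.
#'
#' @param sino a [sinogram()].
#' @param n_roi target width (<= current width).
#' @return cropped [sinogram()].
#' @export
crop_sinogram <- function(sino, n_roi) {
  w <- .sino_width(sino)
  if (n_roi > w) stop("n_roi must be <= the sinogram width")
  left <- (w - n_roi) %/% 2
  sinogram(sino$data[, (left + 1):(left + n_roi), drop = FALSE],
           sino$angles, sino$center - left)
}

#' Crop an image to its central square (operator C-tilde)
#'
#' @param image square matrix.
#' @param n target side (<= current side).
#' @return `n x n` central square.
#' @export
crop_image <- function(image, n) {
  side <- nrow(image)
  if (n > side) stop("n must be <= the image side")
  left <- (side - n) %/% 2
  image[(left + 1):(left + n), (left + 1):(left + n), drop = FALSE]
}

#' Embed an image centrally in a larger zero image
#'
#' Adjoint of [crop_image()]; realizes the zero-extension x0 -> x0-tilde.
#'
#' @param image square matrix.
#' @param n_ext target side (>= current side).
#' @return `n_ext x n_ext` matrix, zero outside the central square.
#' @export
embed_image <- function(image, n_ext) {
  side <- nrow(image)
  if (n_ext < side) stop("n_ext must be >= the image side")
  left <- (n_ext - side) %/% 2
  out <- matrix(0, n_ext, n_ext)
  out[(left + 1):(left + side), (left + 1):(left + side)] <- image
  out
}

# Discrete ramp (Ram-Lak) filter frequency response of length m, from the
# space-domain impulse response h[0] = 1/4, h[+-k odd] = -1/(pi k)^2
# (band-limited ramp), returned as a real vector ready for FFT filtering.
.ramp_filter <- function(m) {
  h <- numeric(m)
  h[1] <- 0.25
  k <- seq_len(m %/% 2)
  odd <- k[k %% 2 == 1]
  h[1 + odd] <- -1 / (pi * odd)^2
  h[m + 1 - odd] <- -1 / (pi * odd)^2
  2 * Re(fft(h))
}

# Ramp-filter sinogram rows: FFT along the detector axis with zero padding
# to a power of two >= max(2 * width, pad_min), double precision.
.filter_rows <- function(data_t, pad_min = 0) {
  w <- nrow(data_t)
  m <- 2^ceiling(log2(max(2 * w, pad_min, 64)))
  H <- .ramp_filter(m)
  padded <- rbind(data_t, matrix(0, m - w, ncol(data_t)))
  fhat <- mvfft(padded) * H
  Re(mvfft(fhat, inverse = TRUE))[seq_len(w), , drop = FALSE] / m
}

#' Padded filtered backprojection
#'
#' The padded-FBP baseline for local tomography: each truncated sinogram row
#' is extrapolated to the extended width `geom$n_ext` by edge replication,
#' ramp-filtered (band-limited Ram-Lak, FFT with zero padding to the next
#' power of two >= 2 N2), and backprojected with a pixel-driven linear
#' interpolation backprojector scaled by pi / (2 Np). Returns the ROI crop
#' `x0` and its zero-extended embedding `x0_ext` on the N2^2 support (the
#' initial point of the blob correction).
#'
#' @param sino truncated [sinogram()] of width `geom$n_roi` (a full-width
#'   `geom$n_ext` sinogram is accepted and used without padding).
#' @param geom a [local_geometry()].
#' @return list with `x0` (N^2 matrix), `x0_ext` (N2^2 matrix, zeros outside
#'   the central N^2 square), and `fbp_ext` (the raw FBP on N2^2).
#' @export
padded_fbp <- function(sino, geom) {
  w <- .sino_width(sino)
  if (!(w %in% c(geom$n_roi, geom$n_ext))) {
    stop("sinogram width must be geom$n_roi (truncated) or geom$n_ext")
  }
  padded <- pad_sinogram(sino, geom$n_ext)
  filt <- .filter_rows(t(padded$data))
  bp <- fbp_backproject_cpp(filt, geom$angles, padded$center, geom$n_ext)
  fbp_ext <- bp * pi / (2 * length(geom$angles))
  x0 <- crop_image(fbp_ext, geom$n_roi)
  list(x0 = x0, x0_ext = embed_image(x0, geom$n_ext), fbp_ext = fbp_ext)
}
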