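# Multi-resolution Gaussian blob basis: kernel, lattice construction,
# synthesis G, analysis G^T, and the known-zone restriction (G c)|Omega.

#' Truncated 1-D Gaussian blob kernel
#'
#' Samples `exp(-t^2 / (2 sigma^2)) / (sigma sqrt(2 pi))` on integer offsets,
#' truncated at 3 sigma on each side: length `ceiling(6 sigma + 1)`, forced
#' odd so the blob is centered. The 2-D blob is the outer product of this
#' kernel with itself (separability), and the same kernel convolves sinogram
#' rows in the merged projector.
#'
#' @param sigma standard deviation in pixels (> 0).
#' @return numeric vector of odd length with attribute `"sigma"`.
#' @export
gaussian_blob_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("'sigma' must be a single positive number")
  }
  len <- as.integer(ceiling(6 * sigma + 1))
  if (len %% 2L == 0L) len <- len + 1L
  h <- (len - 1L) %/% 2L
  off <- seq.int(-h, h)
  k <- exp(-off^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  attr(k, "sigma") <- sigma
  k
}

#' Build a Gaussian blob basis on the extended support
#'
#' Places blob centers on regular lattices of spacing `s = 0.65 sigma`
#' covering the N2^2 extended support. Single-resolution: one lattice with
#' `ceiling(N2 / s)` centers per axis (so `n_coeffs` is within one row/column
#' of `(N2 / s)^2`). Multi-resolution: centers are classified by distance r
#' to the ROI center into concentric bands with sigma doubling per band
#' (sigma0, 2 sigma0, 4 sigma0, ...) until it reaches the cap (the ROI
#' diameter by default); band j extends out to the dyadic radius
#' `2^(j-1) N/2` plus the band's own 3 sigma support margin, so every blob
#' whose footprint reaches the ROI keeps the ROI's resolution and there is
#' no resolution cliff at the evaluated rim. Each band uses its own, coarser
#' lattice — fewer coefficients overall than the single lattice.
#'
#' @param geom a [local_geometry()].
#' @param sigma0 base standard deviation in pixels.
#' @param multiresolution logical; `FALSE` gives the single s-lattice.
#' @param cap where sigma stops doubling: `"diameter"` (N) or `"radius"` (N/2).
#' @param spacing_factor lattice spacing as a multiple of sigma (default 0.65,
#'   a significant blob overlap, close to a basis).
#' @return an object of class `"blob_basis"`: per-center continuous 0-based
#'   positions, per-center sigma and band, per-band kernels, and `n_coeffs`.
#' @export
build_blob_basis <- function(geom, sigma0, multiresolution = TRUE,
                             cap = c("diameter", "radius"),
                             spacing_factor = 0.65) {
  if (sigma0 <= 0) stop("'sigma0' must be positive")
  cap <- match.arg(cap)
  n2 <- geom$n_ext
  c0 <- (n2 - 1) / 2
  roi_r <- geom$n_roi / 2
  cap_val <- if (cap == "diameter") geom$n_roi else roi_r
  rmax <- sqrt(2) * c0

  lattice <- function(s) {
    n <- as.integer(ceiling(n2 / s))
    if (n < 1) stop("sigma0 too large: no blob center fits the support")
    pos <- c0 + (seq_len(n) - (n + 1) / 2) * s
    pos <- pos[pos >= 0 & pos <= n2 - 1]
    expand.grid(row = pos, col = pos)
  }

  if (!multiresolution) {
    g <- lattice(spacing_factor * sigma0)
    bands <- data.frame(band = 1L, sigma = sigma0, r_lo = -Inf, r_hi = Inf)
    centers <- data.frame(row = g$row, col = g$col, band = 1L, sigma = sigma0)
  } else {
    # Band j uses sigma_j = 2^(j-1) sigma0 (capped) and covers centers out to
    # the dyadic radius 2^(j-1) R plus the band's own 3 sigma support margin,
    # so every blob whose footprint reaches a region is at least as fine as
    # that region requires (no resolution cliff at the ROI rim).
    sig <- sigma0
    dyadic <- roi_r
    lo <- -Inf
    j <- 0L
    bands <- list(); cents <- list()
    repeat {
      hi <- dyadic + 3 * sig
      if (hi >= rmax) hi <- Inf
      g <- lattice(spacing_factor * sig)
      r <- sqrt((g$row - c0)^2 + (g$col - c0)^2)
      keep <- r > lo & r <= hi
      j <- j + 1L
      bands[[j]] <- data.frame(band = j, sigma = sig, r_lo = lo, r_hi = hi)
      if (any(keep)) {
        cents[[j]] <- data.frame(row = g$row[keep], col = g$col[keep],
                                 band = j, sigma = sig)
      }
      if (!is.finite(hi)) break
      lo <- hi
      dyadic <- dyadic * 2
      sig <- min(sig * 2, cap_val)
    }
    bands <- do.call(rbind, bands)
    centers <- do.call(rbind, cents)
    # drop bands that received no center
    used <- sort(unique(centers$band))
    bands <- bands[bands$band %in% used, , drop = FALSE]
    remap <- match(centers$band, used)
    centers$band <- remap
    bands$band <- seq_along(used)
  }
  if (is.null(centers) || nrow(centers) < 1) {
    stop("sigma0 too large: no blob center fits the support")
  }
  rownames(centers) <- rownames(bands) <- NULL
  kernels <- lapply(bands$sigma, gaussian_blob_kernel)

  structure(list(centers = centers, bands = bands, kernels = kernels,
                 spacing_factor = spacing_factor, sigma0 = sigma0,
                 multiresolution = multiresolution, cap = cap,
                 n_ext = n2, n_coeffs = nrow(centers)),
            class = "blob_basis")
}

#' @export
print.blob_basis <- function(x, ...) {
  cat(sprintf("blob_basis: %d coefficients on %d^2, %d band(s), s = %.2f sigma\n",
              x$n_coeffs, x$n_ext, nrow(x$bands), x$spacing_factor))
  for (b in seq_len(nrow(x$bands))) {
    cat(sprintf("  band %d: sigma = %.3g, r in (%.3g, %.3g], %d blobs\n",
                b, x$bands$sigma[b], x$bands$r_lo[b], x$bands$r_hi[b],
                sum(x$centers$band == b)))
  }
  invisible(x)
}

# Linear "same" convolution along the columns of a matrix via FFT, with the
# kernel centered at the origin; zero padding to a power of two >= n + L - 1
# guarantees circular == linear. Self-adjoint for symmetric kernels.
.conv_cols_fft <- function(mat, kernel) {
  n <- nrow(mat)
  len <- length(kernel)
  h <- (len - 1L) %/% 2L
  m <- 2^ceiling(log2(n + len - 1))
  kw <- numeric(m)
  kw[1:(h + 1)] <- kernel[(h + 1):len]
  if (h > 0) kw[(m - h + 1):m] <- kernel[1:h]
  khat <- fft(kw)
  padded <- rbind(mat, matrix(0, m - n, ncol(mat)))
  Re(mvfft(mvfft(padded) * khat, inverse = TRUE))[seq_len(n), , drop = FALSE] / m
}

.conv2_sep <- function(mat, kernel) {
  t(.conv_cols_fft(t(.conv_cols_fft(mat, kernel)), kernel))
}

# Bilinear (sub-pixel) splat of the blob centers onto the pixel grid:
# for each coefficient, up to four corner pixels with bilinear weights.
# Returns 0-based linear indices (column-major) and weights per entry.
.splat_corners <- function(basis) {
  r <- basis$centers$row
  c <- basis$centers$col
  i0 <- floor(r); fr <- r - i0
  j0 <- floor(c); fc <- c - j0
  n2 <- basis$n_ext
  corner <- function(ii, jj, w) {
    data.frame(coeff = seq_len(basis$n_coeffs), band = basis$centers$band,
               idx = ii + jj * n2 + 1, w = w)
  }
  out <- rbind(corner(i0,     j0,     (1 - fr) * (1 - fc)),
               corner(i0 + 1, j0,     fr       * (1 - fc)),
               corner(i0,     j0 + 1, (1 - fr) * fc),
               corner(i0 + 1, j0 + 1, fr       * fc))
  ii <- (out$idx - 1) %% n2
  jj <- (out$idx - 1) %/% n2
  out[out$w > 0 & ii >= 0 & ii < n2 & jj >= 0 & jj < n2, , drop = FALSE]
}

#' Synthesize an image from blob coefficients (operator G)
#'
#' Scatters each coefficient at its continuous center (bilinear sub-pixel
#' splat) and convolves each band's point image with the band's separable
#' truncated Gaussian, summing bands: `G c = sum_j H_sigma_j U_j c_j`.
#' Linear in `c`.
#'
#' @param basis a [build_blob_basis()] object.
#' @param coeffs numeric vector of length `basis$n_coeffs`.
#' @return `n_ext x n_ext` matrix.
#' @export
synthesize <- function(basis, coeffs) {
  if (length(coeffs) != basis$n_coeffs) stop("coefficient length mismatch")
  n2 <- basis$n_ext
  out <- matrix(0, n2, n2)
  sp <- .splat_corners(basis)
  for (b in seq_len(nrow(basis$bands))) {
    sel <- sp$band == b
    if (!any(sel)) next
    pt <- numeric(n2 * n2)
    acc <- rowsum(coeffs[sp$coeff[sel]] * sp$w[sel], sp$idx[sel])
    pt[as.integer(rownames(acc))] <- acc
    out <- out + .conv2_sep(matrix(pt, n2, n2), basis$kernels[[b]])
  }
  out
}

#' Analyze an image into blob coefficients (operator G^T)
#'
#' Exact algebraic adjoint of [synthesize()]: convolves the image with each
#' band's kernel (symmetric, so convolution equals correlation) and gathers
#' at the band's centers with the same bilinear weights.
#'
#' @param basis a [build_blob_basis()] object.
#' @param image `n_ext x n_ext` matrix.
#' @return numeric vector of length `basis$n_coeffs`.
#' @export
analyze <- function(basis, image) {
  if (nrow(image) != basis$n_ext || ncol(image) != basis$n_ext) {
    stop("image side must equal the basis support")
  }
  sp <- .splat_corners(basis)
  out <- numeric(basis$n_coeffs)
  for (b in seq_len(nrow(basis$bands))) {
    sel <- sp$band == b
    if (!any(sel)) next
    conv <- .conv2_sep(image, basis$kernels[[b]])
    acc <- rowsum(conv[sp$idx[sel]] * sp$w[sel], sp$coeff[sel])
    out[as.integer(rownames(acc))] <- acc
  }
  out
}

#' Known-zone sampling matrix
#'
#' Dense `N_Omega x N_g` matrix M with `M c = (G c)|Omega`: entry (p, j) is
#' the value of blob j's separable kernel at known pixel p. Built once per
#' (basis, zone) and reused by the solver; its transpose is the adjoint that
#' scatters zone residuals back to coefficients.
#'
#' @param basis a [build_blob_basis()] object.
#' @param zone a [known_zone()] (coordinates in the N^2 ROI frame).
#' @param geom the [local_geometry()] (supplies the ROI -> extended offset).
#' @return numeric matrix.
#' @export
known_zone_matrix <- function(basis, zone, geom) {
  off <- (geom$n_ext - geom$n_roi) %/% 2
  py <- zone$rows + off
  px <- zone$cols + off
  if (any(py < 0 | py >= geom$n_ext | px < 0 | px >= geom$n_ext)) {
    stop("known zone lies outside the extended support")
  }
  M <- matrix(0, length(py), basis$n_coeffs)
  n2 <- basis$n_ext
  # same bilinear sub-pixel splat model as synthesize(): each blob is the
  # band kernel convolved with the 4-corner splat of its continuous center
  i0 <- floor(basis$centers$row); fr <- basis$centers$row - i0
  j0 <- floor(basis$centers$col); fc <- basis$centers$col - j0
  corners <- list(list(di = 0, dj = 0, w = (1 - fr) * (1 - fc)),
                  list(di = 1, dj = 0, w = fr * (1 - fc)),
                  list(di = 0, dj = 1, w = (1 - fr) * fc),
                  list(di = 1, dj = 1, w = fr * fc))
  for (b in seq_len(nrow(basis$bands))) {
    sel <- which(basis$centers$band == b)
    if (!length(sel)) next
    k <- basis$kernels[[b]]
    h <- (length(k) - 1L) %/% 2L
    lk <- function(d) {       # kernel lookup, zero outside the 3-sigma cut
      i <- d + h + 1L
      v <- numeric(length(i))
      ok <- i >= 1L & i <= length(k)
      v[ok] <- k[i[ok]]
      v
    }
    for (cn in corners) {
      w <- cn$w[sel]
      use <- which(w > 0 & i0[sel] + cn$di >= 0 & i0[sel] + cn$di < n2 &
                     j0[sel] + cn$dj >= 0 & j0[sel] + cn$dj < n2)
      if (!length(use)) next
      dy <- outer(py, i0[sel][use] + cn$di, "-")
      dx <- outer(px, j0[sel][use] + cn$dj, "-")
      M[, sel[use]] <- M[, sel[use]] +
        (matrix(lk(as.vector(dy)), nrow(M)) *
         matrix(lk(as.vector(dx)), nrow(M))) *
        rep(w[use], each = nrow(M))
    }
  }
  M
}

#' Evaluate blob coefficients on the known zone
#'
#' Computes `(G c)|Omega`, the synthesized correction sampled at the known
#' pixels, as used by the known-zone penalty.
#'
#' @inheritParams known_zone_matrix
#' @param coeffs coefficient vector.
#' @param M optional precomputed [known_zone_matrix()].
#' @return numeric vector of length `N_Omega`.
#' @export
restrict_to_known_zone <- function(basis, coeffs, zone, geom, M = NULL) {
  if (is.null(M)) M <- known_zone_matrix(basis, zone, geom)
  as.numeric(M %*% coeffs)
}
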