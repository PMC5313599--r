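# LUT/CSR point-projector for blob centers and the merged operator bundle
# realizing A = C . P-tilde . G (point-project per band, convolve sinogram
# rows with the band's 1-D kernel, sum, crop) and its exact adjoint.

#' Build the look-up-table point-projector
#'
#' For every blob center and every angle, computes the continuous detector
#' coordinate `t = (x - c) cos(theta) + (y - c) sin(theta) + center` of the
#' projected point and records the hit bin(s): mode `"linear"` splats onto
#' `floor(t)` and `floor(t) + 1` with weights `1 - frac` and `frac` (exact
#' transpose-consistent sampling of the continuous projection), mode
#' `"nearest"` records the single nearest bin with weight 1. Entries falling
#' outside the extended detector are dropped. The entries are stored twice:
#' sorted by sinogram index (CSR triple `pos`/`j`/`w`, rows of the sparse
#' matrix are sinogram pixels) and by coefficient index (CSC triple
#' `pos2`/`j2`/`w2`), so both the point-projection and its adjoint are plain
#' sparse matvecs. Sinogram pixels are indexed angle-major:
#' `k = angle * N2 + bin` (0-based).
#'
#' @param basis a [build_blob_basis()] object (rounded centers are used,
#'   matching [synthesize()]).
#' @param geom a [local_geometry()].
#' @param mode `"linear"` (default) or `"nearest"` splat.
#' @return an object of class `"point_lut"` with 0-based index arrays.
#' @export
build_point_lut <- function(basis, geom, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  n2 <- geom$n_ext
  if (basis$n_ext != n2) stop("basis support does not match the geometry")
  np <- geom$n_angles
  c0 <- (n2 - 1) / 2
  x <- basis$centers$col      # detector coordinate uses (x, y) = (col, row)
  y <- basis$centers$row      # continuous (sub-pixel) center positions
  if (any(x < 0 | x >= n2 | y < 0 | y >= n2)) {
    stop("blob center outside the extended support")
  }
  ng <- basis$n_coeffs

  # t[i, a]: continuous detector coordinate of blob i at angle a
  tmat <- outer(x - c0, cos(geom$angles)) + outer(y - c0, sin(geom$angles))
  tmat <- tmat + geom$center
  ang0 <- matrix(rep(0:(np - 1L), each = ng), ng, np)
  ci <- matrix(rep(0:(ng - 1L), np), ng, np)

  if (mode == "nearest") {
    b0 <- floor(tmat + 0.5)
    bin <- as.vector(b0); wt <- rep(1, length(bin))
    coeff <- as.vector(ci); ang <- as.vector(ang0)
  } else {
    b0 <- floor(tmat)
    fr <- tmat - b0
    bin <- c(as.vector(b0), as.vector(b0 + 1))
    wt <- c(as.vector(1 - fr), as.vector(fr))
    coeff <- rep(as.vector(ci), 2L)
    ang <- rep(as.vector(ang0), 2L)
  }
  keep <- bin >= 0 & bin <= n2 - 1 & wt > 0
  bin <- bin[keep]; wt <- wt[keep]; coeff <- coeff[keep]; ang <- ang[keep]
  k <- ang * n2 + bin                      # 0-based sinogram index
  ns <- np * n2

  o <- order(k, coeff)                     # deterministic CSR ordering
  pos <- c(0L, cumsum(tabulate(k + 1L, nbins = ns)))
  o2 <- order(coeff[o], k[o])              # CSC from the sorted entries
  pos2 <- c(0L, cumsum(tabulate(coeff + 1L, nbins = ng)))

  structure(list(pos = as.integer(pos), j = as.integer(coeff[o]),
                 w = wt[o],
                 pos2 = as.integer(pos2), j2 = as.integer(k[o][o2]),
                 w2 = wt[o][o2],
                 n_sino = as.integer(ns), n_coeffs = as.integer(ng),
                 n_ext = as.integer(n2), n_angles = as.integer(np),
                 mode = mode),
            class = "point_lut")
}

#' @export
print.point_lut <- function(x, ...) {
  cat(sprintf("point_lut: %d coeffs -> %d sinogram pixels, %d entries (%s)\n",
              x$n_coeffs, x$n_sino, length(x$w), x$mode))
  invisible(x)
}

#' Point-project blob coefficients (sparse CSR matvec)
#'
#' `sino[k] = sum_j W[j] c[J[j]]` over the CSR row of each sinogram pixel:
#' the projection of the bare coefficient points, before any blob footprint
#' is applied.
#'
#' @param lut a [build_point_lut()] object.
#' @param coeffs numeric vector of length `lut$n_coeffs`.
#' @return `n_angles x n_ext` sinogram matrix.
#' @export
point_project <- function(lut, coeffs) {
  if (length(coeffs) != lut$n_coeffs) stop("coefficient length mismatch")
  v <- csr_matvec_cpp(lut$pos, lut$j, lut$w, as.numeric(coeffs))
  t(matrix(v, lut$n_ext, lut$n_angles))
}

#' Point-backproject a sinogram (transpose CSC matvec)
#'
#' Exact transpose of [point_project()]: accumulates, for each coefficient,
#' the sinogram entries its projections hit.
#'
#' @param lut a [build_point_lut()] object.
#' @param sino `n_angles x n_ext` matrix (or vector of length `n_sino`).
#' @return numeric coefficient vector.
#' @export
point_backproject <- function(lut, sino) {
  v <- if (is.matrix(sino)) as.vector(t(sino)) else as.numeric(sino)
  if (length(v) != lut$n_sino) stop("sinogram size mismatch")
  csr_matvec_cpp(lut$pos2, lut$j2, lut$w2, v)
}

#' Bundle the merged correction operator A = C P G
#'
#' Precomputes everything the solver applies per iteration: the point LUT,
#' per-band kernel FFTs on a shared padded length, the band partition of the
#' coefficient vector, and (optionally) the known-zone matrix M.
#'
#' @param basis a [build_blob_basis()] object.
#' @param geom a [local_geometry()].
#' @param zone optional [known_zone()]; when given, `M` is attached.
#' @param mode splat mode passed to [build_point_lut()].
#' @return an object of class `"blob_operator"`.
#' @export
blob_operator <- function(basis, geom, zone = NULL, mode = "linear") {
  lut <- build_point_lut(basis, geom, mode = mode)
  n2 <- geom$n_ext
  lmax <- max(lengths(basis$kernels))
  m <- 2^ceiling(log2(n2 + lmax - 1))
  khat <- lapply(basis$kernels, function(k) {
    h <- (length(k) - 1L) %/% 2L
    kw <- numeric(m)
    kw[1:(h + 1)] <- k[(h + 1):length(k)]
    if (h > 0) kw[(m - h + 1):m] <- k[1:h]
    Re(fft(kw))           # even sequence: real spectrum
  })
  band_idx <- split(seq_len(basis$n_coeffs), basis$centers$band)
  M <- if (!is.null(zone)) known_zone_matrix(basis, zone, geom) else NULL
  A <- structure(list(basis = basis, geom = geom, lut = lut, khat = khat,
                      band_idx = band_idx, fft_len = m, M = M, zone = zone,
                      norm_A2 = NA_real_, norm_M2 = NA_real_,
                      norm_ratio = NA_real_),
                 class = "blob_operator")
  if (!is.null(M)) {
    # spectral norms by power iteration (deterministic start), used to put
    # the known-zone penalty on a scale commensurate with the data term
    v <- rep(1, basis$n_coeffs)
    nA <- 0
    for (i in 1:10) {
      w <- op_adjoint(A, op_forward(A, v))
      nA <- sqrt(sum(w^2) / sum(v^2))
      v <- w / sqrt(sum(w^2))
    }
    MtM <- crossprod(M)
    v <- rep(1, basis$n_coeffs)
    nM <- 0
    for (i in 1:30) {
      w <- as.numeric(MtM %*% v)
      nM <- sqrt(sum(w^2) / sum(v^2))
      v <- w / sqrt(sum(w^2))
    }
    A$norm_A2 <- nA
    A$norm_M2 <- nM
    A$norm_ratio <- nA / nM
  }
  A
}

#' @export
print.blob_operator <- function(x, ...) {
  cat(sprintf("blob_operator: Ng=%d, sinogram %d x %d -> ROI width %d, %d band(s)\n",
              x$basis$n_coeffs, x$geom$n_angles, x$geom$n_ext, x$geom$n_roi,
              length(x$band_idx)))
  invisible(x)
}

# internal width x n_angles layout helpers
.crop_rows <- function(mat, n) {
  left <- (nrow(mat) - n) %/% 2
  mat[(left + 1):(left + n), , drop = FALSE]
}
.extend_rows <- function(mat, n2) {
  left <- (n2 - nrow(mat)) %/% 2
  out <- matrix(0, n2, ncol(mat))
  out[(left + 1):(left + nrow(mat)), ] <- mat
  out
}

#' Apply the merged forward operator
#'
#' Per band: point-project the band's coefficients, convolve every sinogram
#' row with the band's 1-D Gaussian kernel (shared FFT length, summed in the
#' frequency domain), then crop to the ROI width N. Equals
#' `crop(project(synthesize(c)))` up to the projector's discretization of the
#' blob footprint.
#'
#' @param A a [blob_operator()].
#' @param coeffs coefficient vector.
#' @return `n_angles x n_roi` matrix (residual-sinogram layout).
#' @export
op_forward <- function(A, coeffs) {
  if (length(coeffs) != A$basis$n_coeffs) stop("coefficient length mismatch")
  n2 <- A$geom$n_ext
  m <- A$fft_len
  np <- A$geom$n_angles
  acc <- matrix(0 + 0i, m, np)
  for (b in seq_along(A$band_idx)) {
    cb <- numeric(length(coeffs))
    sel <- A$band_idx[[b]]
    cb[sel] <- coeffs[sel]
    v <- csr_matvec_cpp(A$lut$pos, A$lut$j, A$lut$w, cb)
    pt <- matrix(0, m, np)
    pt[seq_len(n2), ] <- matrix(v, n2, np)
    acc <- acc + mvfft(pt) * A$khat[[b]]
  }
  full <- Re(mvfft(acc, inverse = TRUE))[seq_len(n2), , drop = FALSE] / m
  t(.crop_rows(full, A$geom$n_roi))
}

#' Apply the merged adjoint operator
#'
#' Exact algebraic transpose of [op_forward()]: zero-extend the residual rows
#' to N2, convolve with each band's kernel (symmetric, self-adjoint), and
#' point-backproject into the band's coefficients.
#'
#' @param A a [blob_operator()].
#' @param residual `n_angles x n_roi` matrix.
#' @return coefficient vector.
#' @export
op_adjoint <- function(A, residual) {
  if (ncol(residual) != A$geom$n_roi || nrow(residual) != A$geom$n_angles) {
    stop("residual must be n_angles x n_roi")
  }
  n2 <- A$geom$n_ext
  m <- A$fft_len
  ext <- .extend_rows(t(residual), n2)
  pad <- matrix(0, m, ncol(ext))
  pad[seq_len(n2), ] <- ext
  fhat <- mvfft(pad)
  out <- numeric(A$basis$n_coeffs)
  for (b in seq_along(A$band_idx)) {
    conv <- Re(mvfft(fhat * A$khat[[b]], inverse = TRUE))[seq_len(n2), ,
                                                          drop = FALSE] / m
    cb <- csr_matvec_cpp(A$lut$pos2, A$lut$j2, A$lut$w2, as.vector(conv))
    sel <- A$band_idx[[b]]
    out[sel] <- cb[sel]
  }
  out
}
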