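# Independent brute-force oracles used by the unit tests. These re-derive
# the operators from first principles (plain R loops), sharing only the
# stated discretization conventions with the implementation.

# Sum-of-ellipse-intensities oracle for the Shepp-Logan phantom at one pixel
# (0-based i = row, j = col) of a side^2 grid, classical intensities.
oracle_phantom_value <- function(i, j, side) {
  tab <- data.frame(
    A   = c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b   = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  )
  c0 <- (side - 1) / 2
  x <- (j - c0) / (side / 2)
  y <- (c0 - i) / (side / 2)
  v <- 0
  for (e in seq_len(nrow(tab))) {
    th <- tab$phi[e] * pi / 180
    xr <- (x - tab$x0[e]) * cos(th) + (y - tab$y0[e]) * sin(th)
    yr <- -(x - tab$x0[e]) * sin(th) + (y - tab$y0[e]) * cos(th)
    if ((xr / tab$a[e])^2 + (yr / tab$b[e])^2 <= 1) v <- v + tab$A[e]
  }
  v
}

# Dense Joseph projection matrix ((Np * width) x side^2), assembled row by
# row in plain R with the same ray-sampling convention as the C++ projector.
# Row index k = (a - 1) * width + b (angle-major), column-major image layout.
oracle_dense_projector <- function(side, angles, det_center, width = side) {
  P <- matrix(0, length(angles) * width, side * side)
  c0 <- (side - 1) / 2
  for (a in seq_along(angles)) {
    ct <- cos(angles[a]); st <- sin(angles[a])
    for (b in 0:(width - 1)) {
      tau <- b - det_center
      row <- (a - 1) * width + b + 1
      if (abs(ct) >= abs(st)) {
        for (y in 0:(side - 1)) {
          xx <- c0 + (tau - (y - c0) * st) / ct
          i0 <- floor(xx); f <- xx - i0
          if (i0 >= 0 && i0 < side) {
            P[row, y + i0 * side + 1] <- P[row, y + i0 * side + 1] +
              (1 - f) / abs(ct)
          }
          if (i0 + 1 >= 0 && i0 + 1 < side) {
            P[row, y + (i0 + 1) * side + 1] <- P[row, y + (i0 + 1) * side + 1] +
              f / abs(ct)
          }
        }
      } else {
        for (x in 0:(side - 1)) {
          yy <- c0 + (tau - (x - c0) * ct) / st
          i0 <- floor(yy); f <- yy - i0
          if (i0 >= 0 && i0 < side) {
            P[row, i0 + x * side + 1] <- P[row, i0 + x * side + 1] +
              (1 - f) / abs(st)
          }
          if (i0 + 1 >= 0 && i0 + 1 < side) {
            P[row, i0 + 1 + x * side + 1] <- P[row, i0 + 1 + x * side + 1] +
              f / abs(st)
          }
        }
      }
    }
  }
  P
}

# Direct sum-over-blobs synthesis oracle: bilinear 4-corner splat of each
# continuous center, then the truncated separable kernel around each corner.
oracle_synthesize <- function(basis, coeffs) {
  n2 <- basis$n_ext
  out <- matrix(0, n2, n2)
  for (idx in seq_len(basis$n_coeffs)) {
    k <- basis$kernels[[basis$centers$band[idx]]]
    h <- (length(k) - 1) %/% 2
    r <- basis$centers$row[idx]; cc <- basis$centers$col[idx]
    i0 <- floor(r); fr <- r - i0
    j0 <- floor(cc); fc <- cc - j0
    for (corner in list(c(i0, j0, (1 - fr) * (1 - fc)),
                        c(i0 + 1, j0, fr * (1 - fc)),
                        c(i0, j0 + 1, (1 - fr) * fc),
                        c(i0 + 1, j0 + 1, fr * fc))) {
      ci <- corner[1]; cj <- corner[2]; w <- corner[3]
      if (w <= 0 || ci < 0 || ci >= n2 || cj < 0 || cj >= n2) next
      for (di in -h:h) {
        ii <- ci + di
        if (ii < 0 || ii >= n2) next
        for (dj in -h:h) {
          jj <- cj + dj
          if (jj < 0 || jj >= n2) next
          out[ii + 1, jj + 1] <- out[ii + 1, jj + 1] +
            coeffs[idx] * w * k[di + h + 1] * k[dj + h + 1]
        }
      }
    }
  }
  out
}

# Dense point-projection matrix (n_sino x n_coeffs) from an independent loop
# over (blob, angle) with the linear two-bin splat.
oracle_dense_lut <- function(basis, geom, mode = "linear") {
  n2 <- geom$n_ext
  np <- geom$n_angles
  c0 <- (n2 - 1) / 2
  P <- matrix(0, np * n2, basis$n_coeffs)
  for (idx in seq_len(basis$n_coeffs)) {
    x <- basis$centers$col[idx]
    y <- basis$centers$row[idx]
    for (a in seq_len(np)) {
      t <- (x - c0) * cos(geom$angles[a]) + (y - c0) * sin(geom$angles[a]) +
        geom$center
      if (mode == "nearest") {
        b0 <- floor(t + 0.5)
        if (b0 >= 0 && b0 <= n2 - 1) {
          P[(a - 1) * n2 + b0 + 1, idx] <- P[(a - 1) * n2 + b0 + 1, idx] + 1
        }
      } else {
        b0 <- floor(t); f <- t - b0
        if (b0 >= 0 && b0 <= n2 - 1 && 1 - f > 0) {
          P[(a - 1) * n2 + b0 + 1, idx] <- P[(a - 1) * n2 + b0 + 1, idx] + 1 - f
        }
        if (b0 + 1 >= 0 && b0 + 1 <= n2 - 1 && f > 0) {
          P[(a - 1) * n2 + b0 + 2, idx] <- P[(a - 1) * n2 + b0 + 2, idx] + f
        }
      }
    }
  }
  P
}

# sinogram vector (angle-major, 0-based k = a * width + bin) from a matrix
sino_vec <- function(mat) as.vector(t(mat))

# small deterministic test setup shared by solver-level tests
tiny_setup <- function(side = 128, roi = 64, n_angles = 100, n_ext = 136,
                       known_radius = NULL) {
  ph <- shepp_logan(side)
  make_local_setup(ph, roi, n_angles, known_radius = known_radius,
                   n_ext = n_ext)
}

relerr <- function(a, b) sqrt(sum((a - b)^2) / max(sum(b^2), 1e-300))
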