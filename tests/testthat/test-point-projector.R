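test_that("LUT structure matches a dense per-(blob, angle) oracle", {
  # 5-blob toy geometry, 4 angles
  g <- local_geometry(12, 12, 4)
  b <- build_blob_basis(g, 3.5, multiresolution = FALSE)
  expect_gte(b$n_coeffs, 5)
  for (mode in c("linear", "nearest")) {
    lut <- build_point_lut(b, g, mode = mode)
    D <- oracle_dense_lut(b, g, mode = mode)
    # assemble the sparse matrix back to dense from the CSR triple
    S <- matrix(0, lut$n_sino, lut$n_coeffs)
    for (k in seq_len(lut$n_sino)) {
      jj <- seq_len(lut$pos[k + 1] - lut$pos[k]) + lut$pos[k]
      if (length(jj)) {
        S[k, lut$j[jj] + 1] <- S[k, lut$j[jj] + 1] + lut$w[jj]
      }
    }
    expect_equal(S, D, tolerance = 1e-12)

    # CSR and CSC triples hold identical (sino, coeff, weight) multisets
    csr <- data.frame(k = rep(0:(lut$n_sino - 1),
                              diff(lut$pos)), i = lut$j, w = lut$w)
    csc <- data.frame(k = lut$j2,
                      i = rep(0:(lut$n_coeffs - 1), diff(lut$pos2)),
                      w = lut$w2)
    o1 <- order(csr$k, csr$i, csr$w)
    o2 <- order(csc$k, csc$i, csc$w)
    expect_equal(csr[o1, ], csc[o2, ], ignore_attr = TRUE)
  }

  # nearest mode: each coefficient appears in at most Np transpose rows
  lutn <- build_point_lut(b, g, mode = "nearest")
  expect_lte(max(diff(lutn$pos2)), g$n_angles)
})

test_that("point projection and backprojection are exact transposes", {
  g <- local_geometry(20, 44, 7)
  b <- build_blob_basis(g, 3)
  lut <- build_point_lut(b, g)

  expect_equal(point_project(lut, numeric(b$n_coeffs)),
               matrix(0, 7, 44))

  # random coefficients against the dense oracle
  set.seed(31)
  cvec <- rnorm(b$n_coeffs)
  D <- oracle_dense_lut(b, g)
  want <- D %*% cvec
  got <- sino_vec(point_project(lut, cvec))
  expect_lt(max(abs(got - want)), 1e-5 * max(abs(want)))

  # adjoint identity to machine precision
  y <- matrix(rnorm(7 * 44), 7)
  lhs <- sum(point_project(lut, cvec) * y)
  rhs <- sum(cvec * point_backproject(lut, y))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-12)

  expect_equal(point_backproject(lut, matrix(0, 7, 44)),
               numeric(b$n_coeffs))

  # an impulse at one sinogram pixel reaches exactly the coefficients whose
  # LUT rows contain that index
  kk <- which(diff(lut$pos) > 0)[3]           # a hit sinogram pixel (1-based)
  imp <- numeric(lut$n_sino); imp[kk] <- 1
  bp <- point_backproject(lut, imp)
  members <- lut$j[(lut$pos[kk] + 1):lut$pos[kk + 1]] + 1
  expect_setequal(which(bp != 0), members)
})

test_that("a central blob projects onto the central detector bin", {
  g <- local_geometry(21, 21, 9)
  b <- build_blob_basis(g, 3.2, multiresolution = FALSE)
  mid <- which(abs(b$centers$row - 10) < 1e-9 & abs(b$centers$col - 10) < 1e-9)
  expect_length(mid, 1)
  cvec <- numeric(b$n_coeffs); cvec[mid] <- 1
  lut <- build_point_lut(b, g, mode = "nearest")
  s <- point_project(lut, cvec)
  for (a in seq_len(9)) {
    expect_equal(s[a, 11], 1)               # rotation center is a fixed point
    expect_equal(sum(s[a, -11]), 0)
  }
})

test_that("merged forward operator commutes with project-then-convolve", {
  # single-band 64^2 toy: A c vs crop(project(synthesize(c)))
  g <- local_geometry(48, 64, 40)
  b <- build_blob_basis(g, 4, multiresolution = FALSE)
  A <- blob_operator(b, g)
  set.seed(32)
  cvec <- rnorm(b$n_coeffs)
  # the equivalence holds for blobs whose 3-sigma support lies inside the
  # image; blobs clipped by the support edge project differently by design
  margin <- 3 * b$sigma0
  interior <- b$centers$row > margin & b$centers$row < 64 - 1 - margin &
    b$centers$col > margin & b$centers$col < 64 - 1 - margin
  cvec[!interior] <- 0
  via_lut <- op_forward(A, cvec)
  via_proj <- crop_sinogram(project(synthesize(b, cvec), g), 48)$data
  expect_lt(relerr(via_lut, via_proj), 0.02)

  # linearity and zero
  c2 <- rnorm(b$n_coeffs)
  expect_equal(op_forward(A, cvec + c2),
               op_forward(A, cvec) + op_forward(A, c2), tolerance = 1e-9)
  expect_equal(op_forward(A, numeric(b$n_coeffs)), matrix(0, 40, 48))
})

test_that("merged adjoint is exact and matches the unmerged operator chain", {
  g <- local_geometry(24, 32, 15)
  b <- build_blob_basis(g, 3)
  A <- blob_operator(b, g)
  set.seed(33)
  cvec <- rnorm(b$n_coeffs)
  res <- matrix(rnorm(15 * 24), 15)

  # machine-precision inner-product identity (the property CG depends on)
  lhs <- sum(op_forward(A, cvec) * res)
  rhs <- sum(cvec * op_adjoint(A, res))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-12)

  expect_equal(op_adjoint(A, matrix(0, 15, 24)), numeric(b$n_coeffs))

  # single band: adjoint ~ G^T . backproject . zero-extend on a 32^2 toy
  g1 <- local_geometry(24, 32, 15)
  b1 <- build_blob_basis(g1, 4, multiresolution = FALSE)
  A1 <- blob_operator(b1, g1)
  res1 <- matrix(rnorm(15 * 24), 15)
  got <- op_adjoint(A1, res1)
  ext <- sinogram(cbind(matrix(0, 15, 4), res1, matrix(0, 15, 4)),
                  g1$angles, g1$center)
  want <- analyze(b1, backproject(ext, g1))
  margin <- 3 * b1$sigma0
  interior <- b1$centers$row > margin & b1$centers$row < 32 - 1 - margin &
    b1$centers$col > margin & b1$centers$col < 32 - 1 - margin
  expect_lt(relerr(got[interior], want[interior]), 0.02)
})
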