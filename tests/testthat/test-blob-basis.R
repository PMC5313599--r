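test_that("blob kernel has the documented length, peak and symmetry", {
  k2 <- gaussian_blob_kernel(2)
  expect_length(k2, 13)                       # ceiling(6*2 + 1)
  expect_length(gaussian_blob_kernel(1.5), 11)  # ceiling(10) forced odd
  k1 <- gaussian_blob_kernel(1)
  expect_equal(k1[(length(k1) + 1) / 2], 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(k2, rev(k2), ignore_attr = TRUE)
  expect_error(gaussian_blob_kernel(0), "positive")
  expect_error(gaussian_blob_kernel(-1), "positive")
})

test_that("basis construction follows the spacing rule and band schedule", {
  g <- local_geometry(272, 572, 10)
  # single band, s = 13 => ceiling(572/13)^2 = 44^2 centers
  b1 <- build_blob_basis(g, sigma0 = 13 / 0.65, multiresolution = FALSE)
  expect_equal(b1$n_coeffs, 44^2)
  expect_equal(b1$spacing_factor, 0.65)
  # spacing between adjacent lattice centers is 0.65 sigma
  rows <- sort(unique(b1$centers$row))
  expect_equal(diff(rows)[1], 0.65 * b1$sigma0, tolerance = 1e-9)

  # multi-resolution has strictly fewer coefficients on the same geometry
  bm <- build_blob_basis(g, sigma0 = 13 / 0.65, multiresolution = TRUE)
  expect_lt(bm$n_coeffs, b1$n_coeffs)

  # sigma doubles per band until the cap
  expect_equal(bm$bands$sigma,
               pmin(bm$sigma0 * 2^(seq_len(nrow(bm$bands)) - 1), 272))

  # "radius" cap limits the doubling at N/2
  br <- build_blob_basis(local_geometry(64, 600, 4), 10, cap = "radius")
  expect_lte(max(br$bands$sigma), 32)
  bd <- build_blob_basis(local_geometry(64, 600, 4), 10, cap = "diameter")
  expect_lte(max(bd$bands$sigma), 64)
  expect_gt(max(bd$bands$sigma), 32)

  expect_error(build_blob_basis(g, 0), "positive")
})

test_that("synthesis reproduces blobs and matches the brute-force oracle", {
  g <- local_geometry(33, 33, 4)
  b <- build_blob_basis(g, 3, multiresolution = FALSE)
  # a center exactly at the support middle (odd lattice): unit coefficient
  mid <- which(abs(b$centers$row - 16) < 1e-9 & abs(b$centers$col - 16) < 1e-9)
  expect_length(mid, 1)
  cvec <- numeric(b$n_coeffs); cvec[mid] <- 1
  img <- synthesize(b, cvec)
  k <- b$kernels[[1]]
  h <- (length(k) - 1) %/% 2
  want <- matrix(0, 33, 33)
  want[(16 - h):(16 + h) + 1, (16 - h):(16 + h) + 1] <- outer(k, k)
  expect_equal(img, want, tolerance = 1e-10)

  # linearity
  set.seed(21)
  c1 <- rnorm(b$n_coeffs); c2 <- rnorm(b$n_coeffs)
  expect_equal(synthesize(b, c1 + c2), synthesize(b, c1) + synthesize(b, c2),
               tolerance = 1e-9)

  # brute-force sum-over-blobs oracle (multi-resolution, sub-pixel centers)
  gm <- local_geometry(20, 40, 4)
  bm <- build_blob_basis(gm, 2.4)
  set.seed(22)
  cm <- rnorm(bm$n_coeffs)
  expect_lt(max(abs(synthesize(bm, cm) - oracle_synthesize(bm, cm))), 1e-6)
})

test_that("analyze is the exact adjoint of synthesize", {
  g <- local_geometry(20, 40, 4)
  b <- build_blob_basis(g, 2.4)
  set.seed(23)
  cvec <- rnorm(b$n_coeffs)
  x <- matrix(rnorm(40 * 40), 40)
  lhs <- sum(synthesize(b, cvec) * x)
  rhs <- sum(cvec * analyze(b, x))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)

  expect_equal(analyze(b, matrix(0, 40, 40)), numeric(b$n_coeffs))
  expect_error(analyze(b, matrix(0, 10, 10)), "support")
})

test_that("known-zone restriction equals crop-then-mask of the synthesis", {
  setup <- tiny_setup()
  b <- build_blob_basis(setup$geom, 6)
  z <- setup$zone
  expect_equal(restrict_to_known_zone(b, numeric(b$n_coeffs), z, setup$geom),
               numeric(length(z$rows)))

  set.seed(24)
  cvec <- rnorm(b$n_coeffs)
  got <- restrict_to_known_zone(b, cvec, z, setup$geom)
  img <- crop_image(synthesize(b, cvec), setup$geom$n_roi)
  want <- img[cbind(z$rows + 1, z$cols + 1)]
  expect_equal(got, want, tolerance = 1e-9)

  # adjoint of the masked operator through the explicit matrix
  M <- known_zone_matrix(b, z, setup$geom)
  v <- rnorm(length(z$rows))
  expect_equal(sum((M %*% cvec) * v), sum(cvec * as.numeric(crossprod(M, v))),
               tolerance = 1e-12)
})

test_that("neighboring blobs form a well-conditioned near-basis", {
  # Gram matrix of a 5x5 patch of blobs at spacing 0.65 sigma: positive
  # definite with moderate conditioning (the representation is close to a
  # basis, though heavily overlapping)
  g <- local_geometry(40, 40, 4)
  b <- build_blob_basis(g, 4, multiresolution = FALSE)
  c0 <- (40 - 1) / 2
  d <- sqrt((b$centers$row - c0)^2 + (b$centers$col - c0)^2)
  patch <- order(d)[1:25]
  G <- matrix(0, 25, 25)
  imgs <- lapply(patch, function(j) {
    cv <- numeric(b$n_coeffs); cv[j] <- 1
    synthesize(b, cv)
  })
  for (i in 1:25) for (j in i:25) {
    G[i, j] <- G[j, i] <- sum(imgs[[i]] * imgs[[j]])
  }
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_lt(max(ev) / min(ev), 1e7)
})
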