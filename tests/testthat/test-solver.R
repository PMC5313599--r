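test_that("residual sinogram identities hold", {
  setup <- tiny_setup()
  geom <- setup$geom
  d <- setup$sinogram

  # x0 = 0 gives f = d
  f0 <- residual_sinogram(d, matrix(0, 64, 64), geom)
  expect_equal(f0$data, d$data)

  # dual route: C P x0_ext equals the direct width-N projection of x0
  fbp <- padded_fbp(d, geom)
  via_ext <- crop_sinogram(project(fbp$x0_ext, geom), 64)$data
  gN <- local_geometry(64, 64, geom$n_angles, angles = geom$angles)
  via_direct <- project(fbp$x0, gN)$data
  expect_lt(relerr(via_ext, via_direct), 1e-6)

  # full (non-truncated) data: reprojection residual of the FBP is small
  gf <- local_geometry(128, 128, 100, n_full = 128)
  df <- project(setup$phantom, gf)
  rf <- padded_fbp(df, gf)
  ff <- residual_sinogram(df, rf$x0, gf)
  expect_lt(sqrt(sum(ff$data^2) / sum(df$data^2)), 0.06)

  expect_error(residual_sinogram(d, matrix(0, 10, 10), geom), "x0")
})

test_that("CG solves the normal equations like a direct solver", {
  # tiny well-conditioned system: 3x3 blobs at wide spacing, beta = 0 (raw)
  g <- local_geometry(14, 18, 12)
  b <- build_blob_basis(g, 3, multiresolution = FALSE, spacing_factor = 2)
  expect_equal(b$n_coeffs, 9)
  setup_zone <- known_zone(6, 6, 0.5)
  A <- blob_operator(b, g, zone = setup_zone)
  set.seed(41)
  f <- sinogram(matrix(rnorm(12 * 14), 12), g$angles, (14 - 1) / 2)
  x0 <- matrix(0, 14, 14)

  prob <- correction_problem(f, A, x0, beta = 0, beta_scale = "raw",
                             max_iters = b$n_coeffs + 10)
  fit <- solve_correction(prob)

  # dense normal-equations solution
  Amat <- vapply(seq_len(b$n_coeffs), function(j) {
    e <- numeric(b$n_coeffs); e[j] <- 1
    as.vector(op_forward(A, e))
  }, numeric(12 * 14))
  H <- crossprod(Amat)
  rhs <- as.numeric(crossprod(Amat, as.vector(f$data)))
  want <- solve(H + diag(1e-10, ncol(H)), rhs)
  expect_lt(relerr(fit$coefficients, want), 1e-5)

  # objective trace is nonincreasing (up to relative jitter)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-6 * abs(tr[-length(tr)]) + 1e-9))
})

test_that("balanced beta scaling is wired through the operator norms", {
  setup <- tiny_setup()
  b <- build_blob_basis(setup$geom, 7)
  A <- blob_operator(b, setup$geom, zone = setup$zone)
  expect_true(is.finite(A$norm_ratio) && A$norm_ratio > 1)
  fbp <- padded_fbp(setup$sinogram, setup$geom)
  f <- residual_sinogram(setup$sinogram, fbp$x0, setup$geom,
                         x0_ext = fbp$x0_ext)
  pb <- correction_problem(f, A, fbp$x0, beta = 2)
  expect_equal(pb$beta, 2 * A$norm_ratio)
  pr <- correction_problem(f, A, fbp$x0, beta = 2, beta_scale = "raw")
  expect_equal(pr$beta, 2)
})

test_that("composition restores x0 when the correction is zero and is linear", {
  setup <- tiny_setup()
  fbp <- padded_fbp(setup$sinogram, setup$geom)
  b <- build_blob_basis(setup$geom, 7)
  expect_equal(compose_result(fbp$x0_ext, b, numeric(b$n_coeffs), 64), fbp$x0)
  set.seed(42)
  c1 <- rnorm(b$n_coeffs); c2 <- rnorm(b$n_coeffs)
  lhs <- compose_result(fbp$x0_ext, b, c1 + c2, 64)
  rhs <- compose_result(fbp$x0_ext, b, c1, 64) +
    crop_image(synthesize(b, c2), 64)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("the correction removes most of the cupping on a truncated setup", {
  setup <- tiny_setup(side = 256, roi = 136, n_angles = 400, n_ext = 286)
  rec <- reconstruct_roi(setup$sinogram, setup$geom, setup$zone,
                         sigma0 = 10, iters = 120)
  m <- roi_disk_mask(136)
  mae_fbp <- mean(abs(rec$x0 - setup$truth_roi)[m])
  mae_cor <- mean(abs(rec$x - setup$truth_roi)[m])
  expect_lt(mae_cor, 0.5 * mae_fbp)

  # known-zone mean bias shrinks to <= 10% of the padded-FBP bias
  om <- cbind(setup$zone$rows + 1, setup$zone$cols + 1)
  bias_fbp <- mean((rec$x0 - setup$truth_roi)[om])
  bias_cor <- mean((rec$x - setup$truth_roi)[om])
  expect_lt(abs(bias_cor), 0.1 * abs(bias_fbp))

  # end-to-end improvement in PSNR as well
  expect_gt(psnr(rec$x, setup$truth_roi), psnr(rec$x0, setup$truth_roi))
})

test_that("pixel-domain baseline behaves like the exact method", {
  setup <- tiny_setup(side = 96, roi = 48, n_angles = 80, n_ext = 104,
                      known_radius = 6)
  # TV + known zone on a piecewise-constant phantom: large improvement
  tv <- baseline_pixel_exact(setup$sinogram, setup$geom, setup$zone,
                             lambda = 1, tv_weight = 1, iters = 600)
  m <- roi_disk_mask(48)
  fbp <- padded_fbp(setup$sinogram, setup$geom)
  err_tv <- sqrt(mean((tv$x - setup$truth_roi)[m]^2))
  err_fbp <- sqrt(mean((fbp$x0 - setup$truth_roi)[m]^2))
  expect_lt(err_tv, 0.25 * err_fbp)

  # unregularized least squares run long: low-frequency bias shrinks while
  # high-frequency error grows
  ls_short <- baseline_pixel_exact(setup$sinogram, setup$geom, setup$zone,
                                   lambda = 1, tv_weight = 0, iters = 150)
  ls_long <- baseline_pixel_exact(setup$sinogram, setup$geom, setup$zone,
                                  lambda = 1, tv_weight = 0, iters = 1200)
  k <- gaussian_blob_kernel(4); k <- k / sum(k)
  smooth <- function(e) localtomo:::.conv2_sep(e, k)
  hf <- function(x) {
    e <- x - setup$truth_roi
    ee <- embed_image(e, 104)
    sqrt(mean((e - crop_image(smooth(ee), 48))[m]^2))
  }
  lf <- function(x) {
    e <- embed_image(x - setup$truth_roi, 104)
    sqrt(mean(crop_image(smooth(e), 48)[m]^2))
  }
  expect_lt(lf(ls_long$x), lf(ls_short$x))     # bias keeps shrinking
  expect_gt(hf(ls_long$x), hf(ls_short$x))     # noise keeps growing

  # objective decreases overall
  tr <- tv$objective_trace
  expect_lt(tr[length(tr)], tr[5])
  expect_error(baseline_pixel_exact(setup$sinogram, setup$geom, setup$zone,
                                    iters = 0), "iters")
})
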