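# Correction solver: residual sinogram, conjugate-gradient fit of the blob
# coefficients with the known-zone penalty, composition of the corrected
# slice, and the pixel-domain exact baseline (preconditioned primal-dual).

#' Residual sinogram f = d - P x0
#'
#' The data the correction is fitted to: the truncated measurements minus the
#' reprojection of the padded-FBP image. Computed through the zero-extended
#' x0 on the N2^2 support, `f = d - C P x0_ext`, which equals `d - P x0`
#' exactly because the extension adds no exterior contribution.
#'
#' @param d truncated [sinogram()] of width `geom$n_roi`.
#' @param x0 `N^2` padded-FBP reconstruction (or NULL with `x0_ext` given).
#' @param geom a [local_geometry()].
#' @param x0_ext optional precomputed zero-extended x0 (N2^2).
#' @return [sinogram()] of width N.
#' @export
residual_sinogram <- function(d, x0, geom, x0_ext = NULL) {
  if (ncol(d$data) != geom$n_roi) stop("d must have width geom$n_roi")
  if (is.null(x0_ext)) {
    if (nrow(x0) != geom$n_roi) stop("x0 must be N x N")
    x0_ext <- embed_image(x0, geom$n_ext)
  }
  px0 <- crop_sinogram(project(x0_ext, geom), geom$n_roi)
  sinogram(d$data - px0$data, d$angles, d$center)
}

#' Assemble a correction problem
#'
#' The quadratic problem `min_c ||A c - f||^2 + beta ||M c - r||^2` where A
#' is the merged blob projector, M the known-zone sampling and
#' `r = u0 - x0|Omega` the known-zone residual (the correction G c must
#' bring the FBP image to the known values).
#'
#' @param f residual [sinogram()] (width N).
#' @param operator a [blob_operator()] built with the known zone.
#' @param x0 the padded-FBP ROI image (supplies `x0|Omega`).
#' @param beta known-zone weight (>= 0); overrides `zone$weight` when given.
#'   On the default `"balanced"` scale, beta is dimensionless: the penalty
#'   applied is `beta * (||A||^2 / ||M||^2) * ||M c - r||^2`, so `beta = 1`
#'   puts the two blocks on equal spectral footing. The known values are
#'   exact prior knowledge (no measurement noise), so the default
#'   `beta = 10` weights them an order of magnitude above the data block —
#'   a near-hard constraint. Much larger values make the normal matrix stiff
#'   (penalty-method ill-conditioning) and visibly stall the data-term fit
#'   within a fixed CG budget.
#' @param beta_scale `"balanced"` (default, see `beta`) or `"raw"` (beta
#'   multiplies `||M c - r||^2` as written, no normalization).
#' @param max_iters CG iteration count (the solver runs exactly this many
#'   unless `tolerance` stops it earlier).
#' @param tolerance relative residual-norm stop (0 = run all iterations,
#'   matching fixed-iteration benchmarking).
#' @return object of class `"correction_problem"`.
#' @export
correction_problem <- function(f, operator, x0, beta = NULL,
                               beta_scale = c("balanced", "raw"),
                               max_iters = 200L, tolerance = 0) {
  beta_scale <- match.arg(beta_scale)
  zone <- operator$zone
  if (is.null(zone) || is.null(operator$M)) {
    stop("operator must carry a known zone (build blob_operator(zone = ...))")
  }
  if (is.null(beta)) beta <- 10
  if (beta < 0) stop("beta must be nonnegative")
  if (max_iters < 1) stop("max_iters must be >= 1")
  beta_eff <- if (beta_scale == "balanced") beta * operator$norm_ratio else beta
  x0_omega <- x0[cbind(zone$rows + 1L, zone$cols + 1L)]
  structure(list(f = f, operator = operator, zone = zone, beta = beta_eff,
                 beta_given = beta, beta_scale = beta_scale,
                 zone_residual = zone$values - x0_omega,
                 max_iters = as.integer(max_iters), tolerance = tolerance),
            class = "correction_problem")
}

#' Solve the correction problem by conjugate gradient
#'
#' CG on the normal equations `(A^T A + beta M^T M) c = A^T f + beta M^T r`
#' from `c = 0`. All arithmetic is double precision (inner products
#' accumulate in doubles). The objective
#' `||A c - f||^2 + beta ||M c - r||^2` is tracked per iteration through the
#' running quadratic form, so no extra operator applications are needed.
#'
#' @param problem a [correction_problem()].
#' @return list of class `"correction_fit"`: `coefficients`,
#'   `objective_trace` (length `iterations_run + 1`, starting at c = 0),
#'   `iterations_run`, `normal_residuals`.
#' @export
solve_correction <- function(problem) {
  A <- problem$operator
  beta <- problem$beta
  M <- A$M
  fvec <- problem$f$data
  r <- problem$zone_residual

  apply_H <- function(c) {
    out <- op_adjoint(A, op_forward(A, c))
    if (beta > 0) out <- out + beta * as.numeric(crossprod(M, M %*% c))
    out
  }
  b <- op_adjoint(A, fvec)
  if (beta > 0) b <- b + beta * as.numeric(crossprod(M, r))
  const <- sum(fvec^2) + beta * sum(r^2)

  ng <- A$basis$n_coeffs
  cvec <- numeric(ng)
  hc <- numeric(ng)                 # H c, updated incrementally
  res <- b                          # b - H c
  p <- res
  rs <- sum(res^2)
  rs0 <- rs
  obj <- const                      # objective at c = 0
  trace <- numeric(problem$max_iters + 1L)
  nres <- numeric(problem$max_iters)
  trace[1] <- obj
  iters <- 0L
  for (it in seq_len(problem$max_iters)) {
    q <- apply_H(p)
    denom <- sum(p * q)
    if (!is.finite(denom) || denom <= 0) {
      if (!is.finite(denom)) {
        stop(sprintf("numerical failure in CG at iteration %d", it))
      }
      break                          # p in the null space: converged
    }
    alpha <- rs / denom
    cvec <- cvec + alpha * p
    hc <- hc + alpha * q
    res <- res - alpha * q
    obj <- sum(cvec * hc) - 2 * sum(cvec * b) + const
    iters <- it
    trace[it + 1L] <- obj
    rs_new <- sum(res^2)
    nres[it] <- sqrt(rs_new)
    if (!all(is.finite(cvec))) {
      stop(sprintf("numerical failure in CG at iteration %d", it))
    }
    if (problem$tolerance > 0 && sqrt(rs_new / rs0) < problem$tolerance) {
      p <- res + (rs_new / rs) * p
      rs <- rs_new
      break
    }
    p <- res + (rs_new / rs) * p
    rs <- rs_new
  }
  structure(list(coefficients = cvec,
                 objective_trace = trace[seq_len(iters + 1L)],
                 normal_residuals = nres[seq_len(iters)],
                 iterations_run = iters),
            class = "correction_fit")
}

#' Compose the corrected ROI image
#'
#' `x = crop(x0_ext + G c)`: the fitted low-frequency correction added to the
#' zero-extended FBP image, cropped back to the ROI.
#'
#' @param x0_ext zero-extended padded-FBP image (N2^2).
#' @param basis the [build_blob_basis()] used for the fit.
#' @param coeffs fitted coefficient vector.
#' @param n_roi ROI side N.
#' @return `N x N` corrected image.
#' @export
compose_result <- function(x0_ext, basis, coeffs, n_roi) {
  if (nrow(x0_ext) != basis$n_ext) stop("x0_ext side must match the basis")
  crop_image(x0_ext + synthesize(basis, coeffs), n_roi)
}

#' Full correction pipeline for a truncated sinogram
#'
#' Padded FBP, residual sinogram, blob-basis fit by CG with the known-zone
#' constraint, and composition of the corrected ROI. This is the "proposed"
#' reconstruction method end to end.
#'
#' @param d truncated [sinogram()] (width `geom$n_roi`).
#' @param geom a [local_geometry()].
#' @param zone a [known_zone()].
#' @param sigma0 base blob standard deviation (pixels).
#' @param multiresolution use the multi-resolution basis (default TRUE).
#' @param beta known-zone weight on the balanced scale (default 10, see
#'   [correction_problem()]).
#' @param beta_scale `"balanced"` or `"raw"`, see [correction_problem()].
#' @param iters CG iterations (default 200).
#' @param mode LUT splat mode (`"linear"` or `"nearest"`).
#' @param cap sigma-doubling cap, see [build_blob_basis()].
#' @param verbose print the objective every `verbose` iterations (0 = quiet).
#' @return list of class `"local_recon"`: `x` (corrected ROI), `x0`
#'   (padded FBP), `coefficients`, `objective_trace`, `basis`, `geom`, `fit`.
#' @export
reconstruct_roi <- function(d, geom, zone, sigma0, multiresolution = TRUE,
                            beta = NULL, beta_scale = "balanced",
                            iters = 200L, mode = "linear",
                            cap = "diameter", verbose = 0) {
  fbp <- padded_fbp(d, geom)
  basis <- build_blob_basis(geom, sigma0, multiresolution = multiresolution,
                            cap = cap)
  A <- blob_operator(basis, geom, zone = zone, mode = mode)
  f <- residual_sinogram(d, fbp$x0, geom, x0_ext = fbp$x0_ext)
  prob <- correction_problem(f, A, fbp$x0, beta = beta,
                             beta_scale = beta_scale, max_iters = iters)
  fit <- solve_correction(prob)
  if (verbose > 0) {
    idx <- unique(c(seq(1, length(fit$objective_trace), by = verbose),
                    length(fit$objective_trace)))
    for (i in idx) message(sprintf("  it %4d  objective %.6e", i - 1,
                                   fit$objective_trace[i]))
  }
  x <- compose_result(fbp$x0_ext, basis, fit$coefficients, geom$n_roi)
  structure(list(x = x, x0 = fbp$x0, x0_ext = fbp$x0_ext,
                 coefficients = fit$coefficients,
                 objective_trace = fit$objective_trace,
                 basis = basis, geom = geom, zone = zone, fit = fit),
            class = "local_recon")
}

#' @export
print.local_recon <- function(x, ...) {
  cat(sprintf("local_recon: N=%d, Ng=%d, %d CG iterations, objective %.4e\n",
              x$geom$n_roi, x$basis$n_coeffs, x$fit$iterations_run,
              tail(x$objective_trace, 1)))
  invisible(x)
}

#' Pixel-domain exact baseline (preconditioned primal-dual)
#'
#' Solves the full interior problem on the extended N2^2 pixel grid,
#' `min_x ||C P x - d||^2 + lambda ||x|Omega - u0||^2 + tv ||grad x||_1`,
#' with the diagonally preconditioned Chambolle-Pock algorithm (isotropic
#' TV; `tv = 0` reduces to known-zone least squares). Slow by design — every
#' iteration projects and backprojects the full extended slice — it is the
#' reference the blob correction is benchmarked against.
#'
#' @param d truncated [sinogram()] (width `geom$n_roi`).
#' @param geom a [local_geometry()].
#' @param zone a [known_zone()] (raw known values u0 are used here).
#' @param lambda known-zone weight.
#' @param tv_weight total-variation weight (0 disables TV).
#' @param iters primal-dual iterations.
#' @param verbose print objective every `verbose` iterations (0 = quiet).
#' @return list: `x` (ROI crop), `x_ext`, `objective_trace`.
#' @export
baseline_pixel_exact <- function(d, geom, zone, lambda = 1, tv_weight = 0,
                                 iters = 500L, verbose = 0) {
  if (iters < 1) stop("iters must be >= 1")
  n2 <- geom$n_ext
  n <- geom$n_roi
  np <- geom$n_angles
  off <- (n2 - n) %/% 2
  om <- cbind(zone$rows + off + 1L, zone$cols + off + 1L)
  u0 <- zone$values

  Kp <- function(x) crop_sinogram(project(x, geom), n)$data
  Kpt <- function(y) backproject(
    sinogram(.pad_zero_cols(y, n2), geom$angles, geom$center), geom)

  grad <- function(x) {
    gx <- rbind(diff(x), 0)
    gy <- cbind(t(diff(t(x))), 0)
    list(gx = gx, gy = gy)
  }
  # adjoint of forward differences with zero last row/col:
  gradT <- function(gx, gy) {
    a <- matrix(0, n2, n2)
    a[1, ] <- a[1, ] - gx[1, ]
    if (n2 > 2) a[2:(n2 - 1), ] <- a[2:(n2 - 1), ] +
      gx[1:(n2 - 2), ] - gx[2:(n2 - 1), ]
    a[n2, ] <- a[n2, ] + gx[n2 - 1, ]
    a[, 1] <- a[, 1] - gy[, 1]
    if (n2 > 2) a[, 2:(n2 - 1)] <- a[, 2:(n2 - 1)] +
      gy[, 1:(n2 - 2)] - gy[, 2:(n2 - 1)]
    a[, n2] <- a[, n2] + gy[, n2 - 1]
    a
  }

  # diagonal preconditioners (row/column absolute sums, alpha = 1)
  rowsum_P <- Kp(matrix(1, n2, n2))
  sig1 <- 1 / pmax(rowsum_P, 1e-8)
  colsum_P <- Kpt(matrix(1, np, n))
  use_tv <- tv_weight > 0
  colsum_G <- if (use_tv) 4 else 0
  tau <- 1 / pmax(colsum_P + colsum_G, 1e-8)

  x <- matrix(0, n2, n2)
  xbar <- x
  y1 <- matrix(0, np, n)
  gx <- gy <- matrix(0, n2, n2)
  dd <- d$data
  obj <- function(x) {
    o <- sum((Kp(x) - dd)^2) + lambda * sum((x[om] - u0)^2)
    if (use_tv) {
      g <- grad(x)
      o <- o + tv_weight * sum(sqrt(g$gx^2 + g$gy^2))
    }
    o
  }
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    v <- y1 + sig1 * Kp(xbar)
    y1 <- 2 * (v - sig1 * dd) / (sig1 + 2)     # prox of (||. - d||^2)^*
    if (use_tv) {
      g <- grad(xbar)
      px <- gx + 0.5 * g$gx
      py <- gy + 0.5 * g$gy
      nrm <- pmax(1, sqrt(px^2 + py^2) / tv_weight)
      gx <- px / nrm
      gy <- py / nrm
    }
    kty <- Kpt(y1)
    if (use_tv) kty <- kty + gradT(gx, gy)
    u <- x - tau * kty
    xn <- u
    if (lambda > 0) {
      tl <- tau[om] * lambda
      xn[om] <- (u[om] + 2 * tl * u0) / (1 + 2 * tl)
    }
    xbar <- 2 * xn - x
    x <- xn
    trace[it] <- obj(x)
    if (verbose > 0 && it %% verbose == 0) {
      message(sprintf("  it %4d  objective %.6e", it, trace[it]))
    }
    if (it >= 51 && trace[it] > 10 * trace[it - 50]) {
      stop(sprintf("numerical failure: objective diverging at iteration %d", it))
    }
  }
  list(x = crop_image(x, n), x_ext = x, objective_trace = trace)
}

# zero-extend sinogram columns to width n2 (adjoint of the central crop)
.pad_zero_cols <- function(data, n2) {
  w <- ncol(data)
  left <- (n2 - w) %/% 2
  out <- matrix(0, nrow(data), n2)
  out[, (left + 1):(left + w)] <- data
  out
}
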