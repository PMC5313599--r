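---
title: "Correcting interior-tomography reconstructions with a known subregion"
author: "localtomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting interior-tomography reconstructions with a known subregion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(localtomo)
```

## The problem

In local (interior) tomography the detector is narrower than the scanned
object: every parallel-beam projection is truncated to the N central
detector bins, and only the region of interest (ROI) — the disk inscribed in
the N-wide field of view — is seen at every angle. The interior problem is
not uniquely solvable from such data; practical reconstructions extrapolate
each sinogram row by replicating its edge values and apply filtered
backprojection ("padded FBP"). The resulting image x0 recovers mid and high
spatial frequencies well but carries a smooth radial bias — the cupping
artifact — that can reach a large fraction of the attenuation scale.

Uniqueness is restored when the attenuation values are known a priori on
some subregion Omega of the ROI (for real scans, typically an air pocket
where attenuation is zero). `localtomo` implements a correction scheme built
on that prior: instead of solving the full interior problem on the extended
N2^2 pixel grid, it *refines* x0 by estimating only its reconstruction
error, represented in a coarse basis.

## The model

Let d be the truncated sinogram (Np x N), P the parallel-beam projector on
the extended N2^2 support, and C the operator keeping the N central detector
columns. With x0 zero-extended to the N2^2 grid, the residual sinogram

    f = d - C P x0

is (approximately) the projection of the reconstruction error. The error is
modelled as a tiling of isotropic Gaussian blobs,

    e(u, v) = sum_j c_j g_sigma_j(u - u_j, v - v_j),
    g_sigma(u, v) = exp(-(u^2 + v^2) / (2 sigma^2)) / (sigma sqrt(2 pi)),

with kernels truncated at 3 sigma (length `ceiling(6 sigma + 1)`, forced
odd) and blob centers on lattices of spacing s = 0.65 sigma — a strong
overlap that makes the family numerically close to a basis. The coefficients
solve the penalized least-squares problem

    min_c ||C P G c - f||^2 + beta_eff ||(G c)|Omega - (u0 - x0|Omega)||^2

by conjugate gradient on the normal equations, and the corrected ROI is
x = crop(x0_ext + G c). The known-zone term constrains the *correction* to
bring x0 to the known values u0 on Omega — the reading consistent with the
additive error model.

## Operators: why each iteration is cheap

Applying C P G naively would convolve the coefficient image and project it
with a full projector at every iteration. Because the Gaussian is both
separable and rotationally invariant, projection and convolution can be
exchanged: project the bare coefficient *points*, then convolve each
sinogram row with the 1-D kernel of the same sigma. The point projection is
precomputed once as a sparse matrix in CSR form (`pos`/`j`/`w`): for each
blob center and angle, the continuous detector coordinate
t = (x - c) cos(theta) + (y - c) sin(theta) + center receives a two-bin
linear splat (mode `"linear"`; `"nearest"` stores one unit entry). The same
entries re-sorted by coefficient (`pos2`/`j2`/`w2`) give the exact transpose,
so one CG iteration is two sparse matvecs plus a batch of FFT row
convolutions. The row convolutions share one padded FFT length across bands
and are summed in the frequency domain.

The forward/adjoint pair is an *exact* algebraic transpose (inner-product
identity at machine precision) regardless of how well the splat approximates
the true projector — this is the property conjugate gradient relies on. The
agreement with the unmerged route, crop(project(synthesize(c))), is a
separate, approximate property: about 2% relative L2 for blobs whose 3-sigma
support lies inside the image (blobs clipped by the support edge project
differently by construction).

## Multi-resolution basis

Only the ROI needs fine correction; the exterior of the ROI merely has to be
estimated coarsely for its contribution to the truncated projections. Band j
uses sigma_j = 2^(j-1) sigma0, doubling until sigma reaches the cap (the ROI
diameter N by default; `cap = "radius"` stops at N/2), and covers blob
centers out to the dyadic radius 2^(j-1) N/2 *plus the band's own 3 sigma
support margin*. The margin matters: with a hard cutoff at exactly the ROI
radius, the rim of the ROI — where the cupping is steepest and where
reconstruction quality is judged — would be corrected mostly by coarse
exterior blobs. Each band carries its own lattice at spacing 0.65 sigma_j,
so the total coefficient count N_g is well below the single-lattice count
(N2 / 0.65 sigma0)^2. `tune_sigma0()` bisects sigma0 so that N_g matches a
requested size within 5%.

Blob centers are kept continuous everywhere: the LUT uses the continuous
detector coordinate, and synthesis and known-zone sampling place each center
with a bilinear four-corner splat before the separable kernel convolution.
An integer-rounding variant was tried first and made the benchmark PSNR
erratically sensitive (about +/-1.5 dB) to sub-percent changes in sigma0
through lattice aliasing; the sub-pixel model removes that inconsistency
between the operators.

## The known-zone weight

The raw penalty weight of the formulation is not dimensionless: on the 512^2
benchmark the spectral ratio ||A||^2 / ||M||^2 between the data block
A = C P G and the zone-sampling block M is about 10^6, so a raw weight of
order one leaves the constraint numerically inert and the cupping bias
stays. `correction_problem()` therefore expresses beta on a *balanced*
scale: the penalty applied is beta * (||A||^2 / ||M||^2) * ||M c - r||^2,
with the two spectral norms estimated once per operator by deterministic
power iteration. The default beta = 10 reflects that the known values are
exact prior knowledge (no measurement noise) and should dominate the
model-error-laden data block by an order of magnitude; much larger weights
(10^2 and beyond) make the normal matrix stiff in the classic penalty-method
sense and measurably stall the data-term decrease within a fixed CG budget.
`beta_scale = "raw"` restores the literal penalized formulation.

## Numerical choices

* **Projector.** Joseph-style ray sampling: one linear interpolation per
  image row (or column, whichever the ray crosses more slowly) with a
  1/|cos| path-length weight. The backprojector is the exact transpose.
* **Padded FBP.** Rows are edge-padded to N2, ramp-filtered (band-limited
  Ram-Lak built from its discrete impulse response, FFT-padded to the next
  power of two >= 2 N2) and backprojected pixel-driven with the pi/(2 Np)
  parallel-beam normalization. On full (untruncated) 256^2 data this
  pipeline reconstructs the interior to RMSE below 0.01 with no mean bias.
* **CG.** Zero initialization, exactly `iters` iterations by default
  (`tolerance = 0`): the iteration count is part of the method. The problem
  is semiconvergent — past the useful number of iterations the fit starts
  pulling high-frequency content of the residual into the coarse basis — so
  running "to convergence" is *worse*; Jacobi preconditioning was tried and
  discarded for the same reason (it accelerates onto the noise). All
  arithmetic is double precision, including the dot products.
* **Conventions.** 0-based pixel coordinates with the image center at
  (side-1)/2; angles evenly spaced in [0, pi) (half-turn parallel beam);
  when a padding/cropping width difference is odd, the extra column goes to
  the right; crop-then-pad round trips are bit-exact.
* **Degenerate inputs.** A zero sinogram reconstructs to zero; CG stops
  early (converged) if the search direction falls in the null space; a
  non-finite iterate raises an error carrying the iteration index, as does a
  diverging primal-dual objective (10x growth over 50 iterations).

## What the generator simulates — and what it does not

`make_local_setup()` projects a classical Shepp-Logan head phantom (10
ellipses, additive intensities, values up to about 2.04) at Np angles over
the half turn, truncates to the N central columns, and reads the known-zone
values off the phantom in a disk of radius N/10 centered on the ROI center
(both configurable). This reproduces the geometry that makes cupping
prominent: a low-contrast object much wider than the detector. It does not
simulate photon noise (an optional additive-Gaussian flag exists), detector
blur, rings, beam hardening, or rotation-center error — so passing
benchmarks here demonstrate correctness of the operators and solver on the
idealized forward model, not robustness on experimental data. The known-zone
values are exact by construction; on real scans their accuracy bounds the
achievable correction.

## Benchmark scales and observed behavior

The package's default study sizes keep a single-CPU run short: the full
benchmark row N0 = 512 (N = 272, N2 = 572, Np = 800, N_g about 729, 200 CG
iterations) runs in about two minutes; the test suite also uses a 256^2
variant (N = 136, Np = 400) for the cupping-correction properties and a
96^2 variant for the pixel-domain exact baseline, whose primal-dual solver
needs thousands of full-size projections to converge at larger scales.
Larger rows (1024^2, 2048^2 with Np = 1500/2500) are available through
`run_benchmark()` or the `localtomo benchmark --large` command.

On the 512 row the correction lifts the ROI-disk PSNR from about 10 dB
(padded FBP) to the low 30s dB, removes the known-zone mean bias to below
10% of its FBP value, and halves the mean absolute ROI error several times
over. Two sensitivities are worth knowing about. First, because of CG
semiconvergence the result depends on the iteration count in a non-monotone
way. Second, at fixed N_g the PSNR varies by roughly +/-1.5 dB with the
exact sigma0 the tuner lands on — the fit quality at the ROI rim depends on
how the outermost fine-band lattice ring falls relative to the detector
edge. Reported PSNR uses the ROI disk and peak = max of the ground truth
over the mask; both choices are stated in every report because conventions
differ across the literature.

## Limitations

* The residual f = d - P x0 only approximates the projection of the ROI
  error (the exterior contributes too); the blob fit absorbs the smooth part
  of the discrepancy but the approximation is intrinsic to the refinement
  approach.
* The cupping is never fully corrected in the last few pixels at the ROI
  rim, where the detector-edge transition of the padded FBP lives; metrics
  over the full disk are dominated by this rim at high quality levels.
* The exact pixel-domain baseline (`baseline_pixel_exact()`) is a reference
  implementation: at benchmark sizes it needs thousands of iterations, each
  with a full projection/backprojection pair of the extended slice.
* Parallel-beam, single-slice geometry only; volumes are loops over slices.
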