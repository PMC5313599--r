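# localtomo

Region-of-interest (interior) tomography in R: reconstruct an ROI from
truncated parallel-beam projections and remove the cupping artifact using a
known subregion.

## The problem and the method

In local tomography the detector (width N) covers only part of the object,
so every projection is truncated and the interior problem has no unique
solution. The standard workaround — edge-pad each sinogram row and apply
filtered backprojection ("padded FBP") — restores mid and high frequencies
but leaves a smooth radial bias, the *cupping* artifact. When the
attenuation values are known on a subregion Ω of the ROI (e.g. an air
pocket), uniqueness is restored and the bias can be corrected.

`localtomo` refines the padded-FBP image x₀ rather than solving the full
problem: the reconstruction error is expanded in a multi-resolution basis of
truncated Gaussian blobs (σ doubling away from the ROI, lattice spacing
s = 0.65 σ) and its coefficients c solve

    min_c ‖ C P G c − f ‖² + β_eff ‖ (G c)|Ω − (u₀ − x₀|Ω) ‖² ,
    f = d − C P x₀ ,  x = crop(x₀ + G c)

by conjugate gradient on the normal equations. The operator C P G is applied
as a sparse (CSR) look-up-table *point projector* followed by per-band 1-D
convolutions of the sinogram rows, so each CG iteration costs two sparse
matvecs plus FFTs. Projector/backprojector, synthesis/analysis and the
merged operator pair are exact algebraic adjoints (machine-precision
inner-product identities), the property CG depends on. A pixel-domain exact
baseline (preconditioned primal–dual with total variation and the same
known-zone penalty) is included for comparison, plus a Shepp–Logan fixture
generator, PSNR/line-profile metrics, and a benchmark driver.

## Worked example

```r
library(localtomo)

# 512^2 phantom, detector covering only the central 272 pixels, 800 views
setup <- make_local_setup(shepp_logan(512), roi_diameter = 272,
                          n_angles = 800, n_ext = 572)

# basis sized to ~1345 blobs, 200 CG iterations
tune <- tune_sigma0(setup$geom, 1345)
rec  <- reconstruct_roi(setup$sinogram, setup$geom, setup$zone,
                        sigma0 = tune$sigma0, iters = 200)

psnr(rec$x0, setup$truth_roi)   # padded FBP : 10.31 dB
psnr(rec$x,  setup$truth_roi)   # corrected  : 35.82 dB
```

The padded FBP reconstructs the ROI disk at 10.31 dB — the cupping bias is a
sizeable fraction of the attenuation scale. The blob correction with the
known-zone constraint (a centered disk of radius N/10 whose values are read
from the phantom) lifts it to 35.82 dB, and the mean error over the known
zone drops to well under 1% of its FBP value. PSNR here is
10·log10(peak²/MSE) over the ROI disk with peak = max of the ground truth
over the disk. On a 256² variant of the same experiment the corrected image
keeps only 3.8% of the padded-FBP mean absolute error.

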