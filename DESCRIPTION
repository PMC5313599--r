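Package: localtomo
Title: Interior Tomography Correction with a Known Subregion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of a region of interest (ROI) from truncated
    parallel-beam projections. Implements the padded filtered backprojection
    baseline, and a correction of its low-frequency cupping artifact by fitting
    the reconstruction error in a multi-resolution Gaussian-blob basis with a
    known-subregion constraint. The fit is solved by conjugate gradient using a
    sparse (CSR) look-up-table point-projector with per-band one-dimensional
    sinogram convolutions. Includes Shepp-Logan phantom fixtures, a pixel-domain
    exact baseline (preconditioned primal-dual with total variation), PSNR and
    line-profile evaluation, and a benchmark driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    jsonlite,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
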