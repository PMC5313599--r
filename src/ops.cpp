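#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam Joseph (linear-interpolation) projector.
//
// Conventions (shared with the R side):
//  * image is a side x side matrix, entry (i, j) at continuous coordinates
//    y = i-1, x = j-1 (0-based), rotation axis at cx = cy = (side-1)/2;
//  * detector coordinate of a point: t = (x-cx)*cos(th) + (y-cy)*sin(th) + det_center;
//  * the ray through detector bin b (0-based) at angle th is sampled once per
//    row (|cos| >= |sin|) or once per column (otherwise), with linear
//    interpolation along the other axis and a 1/|cos| (resp. 1/|sin|) length
//    weight, so line integrals are in pixel * attenuation units.
//
// Sinograms are passed in "width x n_angles" layout (detector bins as rows).

// [[Rcpp::export]]
NumericMatrix joseph_project_cpp(const NumericMatrix& image,
                                 const NumericVector& angles,
                                 const double det_center,
                                 const int width) {
  const int side = image.nrow();
  if (image.ncol() != side) stop("image must be square");
  const int np = angles.size();
  const double c0 = (side - 1.0) / 2.0;
  NumericMatrix sino(width, np);

  for (int a = 0; a < np; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    if (std::fabs(ct) >= std::fabs(st)) {
      const double wlen = 1.0 / std::fabs(ct);
      for (int b = 0; b < width; ++b) {
        const double tau = b - det_center;
        double acc = 0.0;
        for (int y = 0; y < side; ++y) {
          const double xx = c0 + (tau - (y - c0) * st) / ct;
          const int i0 = (int)std::floor(xx);
          const double fx = xx - i0;
          if (i0 >= 0 && i0 < side) acc += image(y, i0) * (1.0 - fx);
          if (i0 + 1 >= 0 && i0 + 1 < side) acc += image(y, i0 + 1) * fx;
        }
        sino(b, a) = acc * wlen;
      }
    } else {
      const double wlen = 1.0 / std::fabs(st);
      for (int b = 0; b < width; ++b) {
        const double tau = b - det_center;
        double acc = 0.0;
        for (int x = 0; x < side; ++x) {
          const double yy = c0 + (tau - (x - c0) * ct) / st;
          const int i0 = (int)std::floor(yy);
          const double fy = yy - i0;
          if (i0 >= 0 && i0 < side) acc += image(i0, x) * (1.0 - fy);
          if (i0 + 1 >= 0 && i0 + 1 < side) acc += image(i0 + 1, x) * fy;
        }
        sino(b, a) = acc * wlen;
      }
    }
  }
  return sino;
}

// Exact algebraic transpose of joseph_project_cpp (same weights, scatter).
// [[Rcpp::export]]
NumericMatrix joseph_backproject_cpp(const NumericMatrix& sino,
                                     const NumericVector& angles,
                                     const double det_center,
                                     const int side) {
  const int width = sino.nrow();
  const int np = sino.ncol();
  if (np != angles.size()) stop("angle count mismatch");
  const double c0 = (side - 1.0) / 2.0;
  NumericMatrix image(side, side);

  for (int a = 0; a < np; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    if (std::fabs(ct) >= std::fabs(st)) {
      const double wlen = 1.0 / std::fabs(ct);
      for (int b = 0; b < width; ++b) {
        const double v = sino(b, a) * wlen;
        if (v == 0.0) continue;
        const double tau = b - det_center;
        for (int y = 0; y < side; ++y) {
          const double xx = c0 + (tau - (y - c0) * st) / ct;
          const int i0 = (int)std::floor(xx);
          const double fx = xx - i0;
          if (i0 >= 0 && i0 < side) image(y, i0) += v * (1.0 - fx);
          if (i0 + 1 >= 0 && i0 + 1 < side) image(y, i0 + 1) += v * fx;
        }
      }
    } else {
      const double wlen = 1.0 / std::fabs(st);
      for (int b = 0; b < width; ++b) {
        const double v = sino(b, a) * wlen;
        if (v == 0.0) continue;
        const double tau = b - det_center;
        for (int x = 0; x < side; ++x) {
          const double yy = c0 + (tau - (x - c0) * ct) / st;
          const int i0 = (int)std::floor(yy);
          const double fy = yy - i0;
          if (i0 >= 0 && i0 < side) image(i0, x) += v * (1.0 - fy);
          if (i0 + 1 >= 0 && i0 + 1 < side) image(i0 + 1, x) += v * fy;
        }
      }
    }
  }
  return image;
}

// Pixel-driven backprojector used by FBP (linear interpolation on the
// filtered detector rows). Not the adjoint of the Joseph projector; the
// adjoint pair used by the solver is joseph_project/joseph_backproject.
// [[Rcpp::export]]
NumericMatrix fbp_backproject_cpp(const NumericMatrix& filtered,
                                  const NumericVector& angles,
                                  const double det_center,
                                  const int side) {
  const int width = filtered.nrow();
  const int np = filtered.ncol();
  const double c0 = (side - 1.0) / 2.0;
  NumericMatrix image(side, side);
  std::vector<double> cs(np), sn(np);
  for (int a = 0; a < np; ++a) { cs[a] = std::cos(angles[a]); sn[a] = std::sin(angles[a]); }

  for (int x = 0; x < side; ++x) {
    const double dx = x - c0;
    for (int y = 0; y < side; ++y) {
      const double dy = y - c0;
      double acc = 0.0;
      for (int a = 0; a < np; ++a) {
        const double t = dx * cs[a] + dy * sn[a] + det_center;
        const int i0 = (int)std::floor(t);
        const double f = t - i0;
        if (i0 >= 0 && i0 < width) acc += filtered(i0, a) * (1.0 - f);
        if (i0 + 1 >= 0 && i0 + 1 < width) acc += filtered(i0 + 1, a) * f;
      }
      image(y, x) = acc;
    }
  }
  return image;
}

// y[k] = sum_{j in [pos[k], pos[k+1])} w[j] * x[idx[j]]
// pos and idx are 0-based; serves both the CSR point-projector (rows are
// sinogram indices) and its CSC transpose (rows are coefficient indices).
// [[Rcpp::export]]
NumericVector csr_matvec_cpp(const IntegerVector& pos,
                             const IntegerVector& idx,
                             const NumericVector& w,
                             const NumericVector& x) {
  const int m = pos.size() - 1;
  NumericVector y(m);
  for (int k = 0; k < m; ++k) {
    double acc = 0.0;
    for (int j = pos[k]; j < pos[k + 1]; ++j) acc += w[j] * x[idx[j]];
    y[k] = acc;
  }
  return y;
}
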