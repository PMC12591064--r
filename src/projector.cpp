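// Ray-driven parallel-beam projector and its exact adjoint, plus a 3x3
// median filter used by the faulty-pixel detector. The backprojector scatters
// with the same bilinear weights the forward projector gathers with, so the
// pair is adjoint to floating precision -- a property SIRT and the
// reprojection alignment rely on.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Projection geometry: pixel centers at integer coordinates, rotation axis
// through the slice center ((N-1)/2, (N-1)/2); detector column u maps to
// signed axis distance s = u - ((N-1)/2 + corOffset). Ray direction at angle
// theta is (-sin t, cos t), the detector axis is (cos t, sin t); samples are
// taken every `step` pixels and weighted by `step`.

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix slice, NumericVector angles,
                                  double corOffset, double step = 0.5) {
  const int ny = slice.nrow(), nx = slice.ncol(), na = angles.size();
  if (ny != nx) stop("slice must be square");
  const int n = nx;
  const double c = (n - 1) / 2.0;
  const double cdet = c + corOffset;
  const double tmax = (n - 1) * 0.7071067811865476 + 1.0;
  const int nt = 2 * (int)std::ceil(tmax / step);  // grid symmetric about t = 0
  const double t0 = -(nt / 2) * step;
  NumericMatrix out(na, n);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int u = 0; u < n; ++u) {
      const double s = u - cdet;
      double acc = 0.0;
      for (int it = 0; it <= nt; ++it) {
        const double t = t0 + it * step;
        const double x = c + s * ct - t * st;
        const double y = c + s * st + t * ct;
        const int ix = (int)std::floor(x), iy = (int)std::floor(y);
        if (ix < -1 || ix > n - 1 || iy < -1 || iy > n - 1) continue;
        const double fx = x - ix, fy = y - iy;
        double v = 0.0;
        if (iy >= 0 && ix >= 0)         v += (1 - fy) * (1 - fx) * slice(iy, ix);
        if (iy >= 0 && ix + 1 <= n - 1) v += (1 - fy) * fx * slice(iy, ix + 1);
        if (iy + 1 <= n - 1 && ix >= 0) v += fy * (1 - fx) * slice(iy + 1, ix);
        if (iy + 1 <= n - 1 && ix + 1 <= n - 1)
          v += fy * fx * slice(iy + 1, ix + 1);
        acc += v;
      }
      out(a, u) = acc * step;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector angles,
                              double corOffset, double step = 0.5) {
  const int na = sino.nrow(), n = sino.ncol();
  if (na != angles.size()) stop("sinogram rows must match angle count");
  const double c = (n - 1) / 2.0;
  const double cdet = c + corOffset;
  const double tmax = (n - 1) * 0.7071067811865476 + 1.0;
  const int nt = 2 * (int)std::ceil(tmax / step);  // grid symmetric about t = 0
  const double t0 = -(nt / 2) * step;
  NumericMatrix out(n, n);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int u = 0; u < n; ++u) {
      const double s = u - cdet;
      const double val = sino(a, u) * step;
      if (val == 0.0) continue;
      for (int it = 0; it <= nt; ++it) {
        const double t = t0 + it * step;
        const double x = c + s * ct - t * st;
        const double y = c + s * st + t * ct;
        const int ix = (int)std::floor(x), iy = (int)std::floor(y);
        if (ix < -1 || ix > n - 1 || iy < -1 || iy > n - 1) continue;
        const double fx = x - ix, fy = y - iy;
        if (iy >= 0 && ix >= 0)         out(iy, ix) += (1 - fy) * (1 - fx) * val;
        if (iy >= 0 && ix + 1 <= n - 1) out(iy, ix + 1) += (1 - fy) * fx * val;
        if (iy + 1 <= n - 1 && ix >= 0) out(iy + 1, ix) += fy * (1 - fx) * val;
        if (iy + 1 <= n - 1 && ix + 1 <= n - 1)
          out(iy + 1, ix + 1) += fy * fx * val;
      }
    }
  }
  return out;
}

// Pixel-driven backprojection (gather with linear detector interpolation):
// smoother than the scatter adjoint, used by FBP. Not the exact adjoint of
// the forward projector.
// [[Rcpp::export]]
NumericMatrix cpp_backproject_pixel(NumericMatrix sino, NumericVector angles,
                                    double corOffset) {
  const int na = sino.nrow(), n = sino.ncol();
  if (na != angles.size()) stop("sinogram rows must match angle count");
  const double c = (n - 1) / 2.0;
  const double cdet = c + corOffset;
  NumericMatrix out(n, n);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int x = 0; x < n; ++x) {
      const double sx = (x - c) * ct;
      for (int y = 0; y < n; ++y) {
        const double u = sx + (y - c) * st + cdet;
        const int iu = (int)std::floor(u);
        if (iu < -1 || iu > n - 1) continue;
        const double fu = u - iu;
        double v = 0.0;
        if (iu >= 0) v += (1 - fu) * sino(a, iu);
        if (iu + 1 <= n - 1) v += fu * sino(a, iu + 1);
        out(y, x) += v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix median3x3(NumericMatrix x) {
  const int ny = x.nrow(), nx = x.ncol();
  NumericMatrix out(ny, nx);
  double w[9];
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nx - 1);
        for (int di = -1; di <= 1; ++di) {
          int ii = std::min(std::max(i + di, 0), ny - 1);
          w[k++] = x(ii, jj);
        }
      }
      std::nth_element(w, w + 4, w + 9);
      out(i, j) = w[4];
    }
  }
  return out;
}
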