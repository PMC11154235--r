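#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// World-space resampler shared by reslicing, registration resampling and the
// registration cost metric. Destination voxel centroids are mapped through an
// optional 4x4 world transform and sampled from the source lattice.
//
// Geometry convention: world(i,j,k) = origin + orient %*% (spacing * (i,j,k)),
// 0-based indices, orient orthonormal (inverse == transpose).
//
// interp: 0 = nearest, 1 = trilinear. boundary: 0 = constant fill, 1 = clamp
// to the nearest edge voxel.

// [[Rcpp::export]]
List cpp_resample(NumericVector data, IntegerVector sdim,
                  NumericVector ssp, NumericVector sor, NumericMatrix sR,
                  IntegerVector ddim,
                  NumericVector dsp, NumericVector dor, NumericMatrix dR,
                  NumericMatrix tf, int interp, double fill, int boundary,
                  bool want_mask) {
  const int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  const int dnx = ddim[0], dny = ddim[1], dnz = ddim[2];
  const R_xlen_t n = (R_xlen_t)dnx * dny * dnz;
  NumericVector out(n);
  LogicalVector mask(want_mask ? n : 0);
  const double *src = data.begin();

  // Fold dst geometry and world transform into one affine: world q = A * idx + b
  double A[9], b[3];
  for (int r = 0; r < 3; r++) {
    for (int c = 0; c < 3; c++) {
      double s = 0.0;
      for (int m = 0; m < 3; m++) s += tf(r, m) * dR(m, c);
      A[3 * r + c] = s * dsp[c];
    }
    double s = tf(r, 3);
    for (int m = 0; m < 3; m++) s += tf(r, m) * dor[m];
    b[r] = s;
  }

  R_xlen_t pos = 0;
  for (int k = 0; k < dnz; k++) {
    for (int j = 0; j < dny; j++) {
      for (int i = 0; i < dnx; i++, pos++) {
        double qx = A[0] * i + A[1] * j + A[2] * k + b[0];
        double qy = A[3] * i + A[4] * j + A[5] * k + b[1];
        double qz = A[6] * i + A[7] * j + A[8] * k + b[2];
        // continuous source index u = R^T (q - origin) / spacing
        double vx = qx - sor[0], vy = qy - sor[1], vz = qz - sor[2];
        double u0 = (sR(0, 0) * vx + sR(1, 0) * vy + sR(2, 0) * vz) / ssp[0];
        double u1 = (sR(0, 1) * vx + sR(1, 1) * vy + sR(2, 1) * vz) / ssp[1];
        double u2 = (sR(0, 2) * vx + sR(1, 2) * vy + sR(2, 2) * vz) / ssp[2];
        bool inside = (u0 >= 0.0 && u0 <= snx - 1.0 &&
                       u1 >= 0.0 && u1 <= sny - 1.0 &&
                       u2 >= 0.0 && u2 <= snz - 1.0);
        if (want_mask) mask[pos] = inside;
        if (!inside && boundary == 0) { out[pos] = fill; continue; }
        if (boundary == 1) {
          if (u0 < 0) u0 = 0; else if (u0 > snx - 1.0) u0 = snx - 1.0;
          if (u1 < 0) u1 = 0; else if (u1 > sny - 1.0) u1 = sny - 1.0;
          if (u2 < 0) u2 = 0; else if (u2 > snz - 1.0) u2 = snz - 1.0;
        }
        if (interp == 0) {
          int i0 = (int)std::floor(u0 + 0.5);
          int j0 = (int)std::floor(u1 + 0.5);
          int k0 = (int)std::floor(u2 + 0.5);
          out[pos] = src[(R_xlen_t)i0 + (R_xlen_t)snx * (j0 + (R_xlen_t)sny * k0)];
        } else {
          int i0 = (int)std::floor(u0), j0 = (int)std::floor(u1), k0 = (int)std::floor(u2);
          if (i0 > snx - 2) i0 = snx - 2; if (i0 < 0) i0 = 0;
          if (j0 > sny - 2) j0 = sny - 2; if (j0 < 0) j0 = 0;
          if (k0 > snz - 2) k0 = snz - 2; if (k0 < 0) k0 = 0;
          if (snx == 1) i0 = 0; if (sny == 1) j0 = 0; if (snz == 1) k0 = 0;
          double fx = u0 - i0, fy = u1 - j0, fz = u2 - k0;
          if (snx == 1) fx = 0; if (sny == 1) fy = 0; if (snz == 1) fz = 0;
          int i1 = (snx == 1) ? i0 : i0 + 1;
          int j1 = (sny == 1) ? j0 : j0 + 1;
          int k1 = (snz == 1) ? k0 : k0 + 1;
          #define SRC(a, bb, cc) src[(R_xlen_t)(a) + (R_xlen_t)snx * ((bb) + (R_xlen_t)sny * (cc))]
          double c00 = SRC(i0, j0, k0) * (1 - fx) + SRC(i1, j0, k0) * fx;
          double c10 = SRC(i0, j1, k0) * (1 - fx) + SRC(i1, j1, k0) * fx;
          double c01 = SRC(i0, j0, k1) * (1 - fx) + SRC(i1, j0, k1) * fx;
          double c11 = SRC(i0, j1, k1) * (1 - fx) + SRC(i1, j1, k1) * fx;
          #undef SRC
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          out[pos] = c0 * (1 - fz) + c1 * fz;
        }
      }
    }
    if (k % 16 == 0) Rcpp::checkUserInterrupt();
  }
  if (want_mask) return List::create(_["data"] = out, _["mask"] = mask);
  return List::create(_["data"] = out);
}

// Separable Gaussian smoothing (sigma in voxels per axis), used by the
// registration pyramid. Kernel truncated at 3 sigma, edges renormalised.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector data, IntegerVector dim,
                               NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(data.begin(), data.end()), tmp(n);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ax++) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    for (int t = -r; t <= r; t++) kern[t + r] = std::exp(-0.5 * t * t / (s * s));
    int len = nd[ax];
    R_xlen_t st = stride[ax];
    R_xlen_t nlines = n / len;
    for (R_xlen_t line = 0; line < nlines; line++) {
      // base offset of this line
      R_xlen_t rem = line, base = 0;
      for (int o = 0; o < 3; o++) {
        if (o == ax) continue;
        R_xlen_t sz = nd[o];
        base += (rem % sz) * stride[o];
        rem /= sz;
      }
      for (int p = 0; p < len; p++) {
        double acc = 0, wsum = 0;
        int lo = std::max(0, p - r), hi = std::min(len - 1, p + r);
        for (int q = lo; q <= hi; q++) {
          double w = kern[q - p + r];
          acc += w * a[base + (R_xlen_t)q * st];
          wsum += w;
        }
        tmp[base + (R_xlen_t)p * st] = acc / wsum;
      }
    }
    a.swap(tmp);
  }
  return NumericVector(a.begin(), a.end());
}
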