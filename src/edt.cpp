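#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact 3D squared Euclidean distance transform (Felzenszwalb-Huttenlocher,
// separable lower-envelope-of-parabolas). Distances are center-to-center in
// voxel units; squared values are returned so callers can keep them exact.

static const double EDT_INF = 1e30;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// fg: voxels for which distance to the nearest !fg voxel center is wanted.
// borderSolid: treat the planes just outside the grid as solid.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dim, bool borderSolid) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = fg[i] ? EDT_INF : 0.0;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int k = 0; k < d3; k++)
    for (int j = 0; j < d2; j++) {
      R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
      for (int i = 0; i < d1; i++) f[i] = out[base + i];
      dt1d(f, dd, v, z, d1);
      for (int i = 0; i < d1; i++) out[base + i] = dd[i];
    }
  // axis 2 (stride d1)
  for (int k = 0; k < d3; k++)
    for (int i = 0; i < d1; i++) {
      R_xlen_t base = i + (R_xlen_t)d1 * d2 * k;
      for (int j = 0; j < d2; j++) f[j] = out[base + (R_xlen_t)d1 * j];
      dt1d(f, dd, v, z, d2);
      for (int j = 0; j < d2; j++) out[base + (R_xlen_t)d1 * j] = dd[j];
    }
  // axis 3 (stride d1*d2)
  const R_xlen_t s3 = (R_xlen_t)d1 * d2;
  for (int j = 0; j < d2; j++)
    for (int i = 0; i < d1; i++) {
      R_xlen_t base = i + (R_xlen_t)d1 * j;
      for (int k = 0; k < d3; k++) f[k] = out[base + s3 * k];
      dt1d(f, dd, v, z, d3);
      for (int k = 0; k < d3; k++) out[base + s3 * k] = dd[k];
    }

  if (borderSolid) {
    R_xlen_t idx = 0;
    for (int k = 0; k < d3; k++)
      for (int j = 0; j < d2; j++)
        for (int i = 0; i < d1; i++, idx++) {
          if (!fg[idx]) continue;
          double b = (double)std::min(std::min(i + 1, d1 - i),
                                      std::min(std::min(j + 1, d2 - j),
                                               std::min(k + 1, d3 - k)));
          double b2 = b * b;
          if (b2 < out[idx]) out[idx] = b2;
        }
  }
  return out;
}
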