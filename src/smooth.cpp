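#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian smoothing with mirror (reflect) boundary handling.
// The kernel is normalized, so the gray-value sum is conserved up to the
// boundary reflection; sigma is in voxels.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector x, IntegerVector dim, double sigma) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (sigma <= 0) return clone(x);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; t++) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + r];
  }
  for (int t = 0; t <= 2 * r; t++) ker[t] /= s;

  NumericVector a = clone(x), b(n);
  const int dims[3] = {d1, d2, d3};
  const R_xlen_t strides[3] = {1, (R_xlen_t)d1, (R_xlen_t)d1 * d2};

  for (int axis = 0; axis < 3; axis++) {
    const int len = dims[axis];
    const R_xlen_t str = strides[axis];
    // iterate over all lines along `axis`
    const int o1 = axis == 0 ? 1 : 0;
    const int o2 = axis == 2 ? 1 : 2;
    const int lo1 = dims[o1], lo2 = dims[o2];
    const R_xlen_t st1 = strides[o1], st2 = strides[o2];
    std::vector<double> line(len);
    for (int v = 0; v < lo2; v++)
      for (int u = 0; u < lo1; u++) {
        R_xlen_t base = st1 * u + st2 * v;
        for (int p = 0; p < len; p++) line[p] = a[base + str * p];
        for (int p = 0; p < len; p++) {
          double acc = 0;
          for (int t = -r; t <= r; t++) {
            int q = p + t;
            // mirror: reflect about -0.5 and len-0.5
            while (q < 0 || q >= len) {
              if (q < 0) q = -q - 1;
              if (q >= len) q = 2 * len - q - 1;
            }
            acc += ker[t + r] * line[q];
          }
          b[base + str * p] = acc;
        }
      }
    std::swap(a, b);
  }
  return a;
}
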