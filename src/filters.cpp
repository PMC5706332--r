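#include "vox.h"
using namespace Rcpp;

// Separable 1D convolution along one axis with replicate border handling.
static void conv_axis(std::vector<double>& vol, const Grid3& g, int axis,
                      const std::vector<double>& k) {
  int r = ((int)k.size() - 1) / 2;
  int len = axis == 0 ? g.n1 : (axis == 1 ? g.n2 : g.n3);
  std::vector<double> line(len), outl(len);
  int nA = axis == 0 ? g.n2 : g.n1;
  int nB = axis == 2 ? g.n2 : g.n3;
  for (int b = 0; b < nB; ++b)
    for (int a = 0; a < nA; ++a) {
      for (int t = 0; t < len; ++t) {
        R_xlen_t v = axis == 0 ? g.idx(t, a, b)
                   : axis == 1 ? g.idx(a, t, b)
                               : g.idx(a, b, t);
        line[t] = vol[v];
      }
      for (int t = 0; t < len; ++t) {
        double s = 0;
        for (int j = -r; j <= r; ++j) {
          int u = t + j;
          if (u < 0) u = 0;
          if (u >= len) u = len - 1;
          s += line[u] * k[j + r];
        }
        outl[t] = s;
      }
      for (int t = 0; t < len; ++t) {
        R_xlen_t v = axis == 0 ? g.idx(t, a, b)
                   : axis == 1 ? g.idx(a, t, b)
                               : g.idx(a, b, t);
        vol[v] = outl[t];
      }
    }
}

// 3D Sobel gradient magnitude: for each axis the derivative kernel
// [-1, 0, 1] combined with triangle smoothing [1, 2, 1] on the two
// orthogonal axes; magnitude is the Euclidean norm of the three responses.
// [[Rcpp::export]]
NumericVector cpp_sobel3d(NumericVector vol, IntegerVector dim) {
  Grid3 g(dim);
  R_xlen_t n = g.size();
  if (vol.size() != n) stop("volume length does not match dim");
  std::vector<double> base(vol.begin(), vol.end());
  NumericVector mag(n);
  std::vector<double> deriv = {-1, 0, 1};
  std::vector<double> smooth = {1, 2, 1};
  for (int axis = 0; axis < 3; ++axis) {
    std::vector<double> w = base;
    for (int ax = 0; ax < 3; ++ax)
      conv_axis(w, g, ax, ax == axis ? deriv : smooth);
    for (R_xlen_t v = 0; v < n; ++v) mag[v] += w[v] * w[v];
  }
  for (R_xlen_t v = 0; v < n; ++v) mag[v] = std::sqrt(mag[v]);
  mag.attr("dim") = dim;
  return mag;
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma, normalized.
// [[Rcpp::export]]
NumericVector cpp_gaussian3d(NumericVector vol, IntegerVector dim,
                             double sigma) {
  Grid3 g(dim);
  R_xlen_t n = g.size();
  if (vol.size() != n) stop("volume length does not match dim");
  std::vector<double> w(vol.begin(), vol.end());
  if (sigma > 0) {
    int r = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> k(2 * r + 1);
    double s = 0;
    for (int j = -r; j <= r; ++j) {
      k[j + r] = std::exp(-0.5 * j * j / (sigma * sigma));
      s += k[j + r];
    }
    for (auto& x : k) x /= s;
    for (int ax = 0; ax < 3; ++ax) conv_axis(w, g, ax, k);
  }
  NumericVector out(w.begin(), w.end());
  out.attr("dim") = dim;
  return out;
}
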