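#include "vox.h"
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// applied per axis. Returns, for every foreground voxel, the squared
// distance in voxel units to the nearest background voxel; 0 on background.

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -R_PosInf;
  z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dim) {
  Grid3 g(dim);
  R_xlen_t n = g.size();
  if (fg.size() != n) stop("mask length does not match dim");
  NumericVector out(n);
  const double INF = 1e18;
  for (R_xlen_t v = 0; v < n; ++v) out[v] = fg[v] ? INF : 0.0;

  int nmax = std::max(g.n1, std::max(g.n2, g.n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> vv(nmax);

  // axis 1
  for (int i3 = 0; i3 < g.n3; ++i3)
    for (int i2 = 0; i2 < g.n2; ++i2) {
      f.resize(g.n1); d.resize(g.n1);
      for (int i1 = 0; i1 < g.n1; ++i1) f[i1] = out[g.idx(i1, i2, i3)];
      dt1d(f, d, vv, z);
      for (int i1 = 0; i1 < g.n1; ++i1) out[g.idx(i1, i2, i3)] = d[i1];
    }
  // axis 2
  for (int i3 = 0; i3 < g.n3; ++i3)
    for (int i1 = 0; i1 < g.n1; ++i1) {
      f.resize(g.n2); d.resize(g.n2);
      for (int i2 = 0; i2 < g.n2; ++i2) f[i2] = out[g.idx(i1, i2, i3)];
      dt1d(f, d, vv, z);
      for (int i2 = 0; i2 < g.n2; ++i2) out[g.idx(i1, i2, i3)] = d[i2];
    }
  // axis 3
  for (int i2 = 0; i2 < g.n2; ++i2)
    for (int i1 = 0; i1 < g.n1; ++i1) {
      f.resize(g.n3); d.resize(g.n3);
      for (int i3 = 0; i3 < g.n3; ++i3) f[i3] = out[g.idx(i1, i2, i3)];
      dt1d(f, d, vv, z);
      for (int i3 = 0; i3 < g.n3; ++i3) out[g.idx(i1, i2, i3)] = d[i3];
    }
  out.attr("dim") = dim;
  return out;
}
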