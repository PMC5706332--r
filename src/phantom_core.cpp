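#include "vox.h"
using namespace Rcpp;

// For every voxel, the nearest and second-nearest seed point (brute force,
// exact). Seeds are given in 0-based voxel coordinates, one row per seed.
// Returns 1-based seed ids and Euclidean distances in voxel units. The
// (d2 - d1) gap is the workhorse of the phantom: it is ~2x the distance to
// the Voronoi bisector between the two nearest cells.
// [[Rcpp::export]]
List cpp_nearest_two_seeds(NumericMatrix seeds, IntegerVector dim) {
  Grid3 g(dim);
  R_xlen_t n = g.size();
  int ns = seeds.nrow();
  if (ns < 2) stop("need at least two seeds");
  IntegerVector id1(n), id2(n);
  NumericVector d1(n), d2(n);
  std::vector<double> sx(ns), sy(ns), sz(ns);
  for (int s = 0; s < ns; ++s) {
    sx[s] = seeds(s, 0);
    sy[s] = seeds(s, 1);
    sz[s] = seeds(s, 2);
  }
  for (int i3 = 0; i3 < g.n3; ++i3)
    for (int i2 = 0; i2 < g.n2; ++i2)
      for (int i1 = 0; i1 < g.n1; ++i1) {
        R_xlen_t v = g.idx(i1, i2, i3);
        double b1 = R_PosInf, b2 = R_PosInf;
        int j1 = -1, j2 = -1;
        for (int s = 0; s < ns; ++s) {
          double dx = i1 - sx[s], dy = i2 - sy[s], dz = i3 - sz[s];
          double dd = dx * dx + dy * dy + dz * dz;
          if (dd < b1) {
            b2 = b1; j2 = j1;
            b1 = dd; j1 = s;
          } else if (dd < b2) {
            b2 = dd; j2 = s;
          }
        }
        id1[v] = j1 + 1;
        id2[v] = j2 + 1;
        d1[v] = std::sqrt(b1);
        d2[v] = std::sqrt(b2);
      }
  id1.attr("dim") = dim;
  id2.attr("dim") = dim;
  d1.attr("dim") = dim;
  d2.attr("dim") = dim;
  return List::create(_["id1"] = id1, _["id2"] = id2, _["d1"] = d1,
                      _["d2"] = d2);
}
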