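#include "vox.h"
using namespace Rcpp;

// Connected-component labeling of a binary mask by breadth-first flood
// fill. Labels are assigned in raster order of each component's first
// voxel, so output is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  Grid3 g(dim);
  R_xlen_t n = g.size();
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  auto off = neighbor_offsets(connectivity);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i1, i2, i3;
      g.coords(v, i1, i2, i3);
      for (auto& o : off) {
        int a = i1 + o[0], b = i2 + o[1], c = i3 + o[2];
        if (!g.inside(a, b, c)) continue;
        R_xlen_t w = g.idx(a, b, c);
        if (mask[w] && !lab[w]) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Per-label statistics in one pass: voxel count, centroid (voxel units,
// 0-based), raw second moments, bounding box, and whether the label owns a
// voxel on any of the six faces of the grid. Labels must be 1..max.
// [[Rcpp::export]]
List cpp_region_stats(IntegerVector labels, IntegerVector dim) {
  Grid3 g(dim);
  R_xlen_t n = g.size();
  if (labels.size() != n) stop("labels length does not match dim");
  int nlab = 0;
  for (R_xlen_t v = 0; v < n; ++v)
    if (labels[v] > nlab) nlab = labels[v];

  NumericVector cnt(nlab);
  NumericMatrix s1(nlab, 3);       // sums of coords
  NumericMatrix s2(nlab, 6);       // sums of products: 11,22,33,12,13,23
  IntegerMatrix bb(nlab, 6);       // min1,max1,min2,max2,min3,max3
  LogicalVector border(nlab);
  for (int k = 0; k < nlab; ++k) {
    bb(k, 0) = bb(k, 2) = bb(k, 4) = INT_MAX;
    bb(k, 1) = bb(k, 3) = bb(k, 5) = -1;
  }
  for (R_xlen_t v = 0; v < n; ++v) {
    int L = labels[v];
    if (L <= 0) continue;
    int k = L - 1;
    int i1, i2, i3;
    g.coords(v, i1, i2, i3);
    cnt[k] += 1;
    s1(k, 0) += i1; s1(k, 1) += i2; s1(k, 2) += i3;
    s2(k, 0) += (double)i1 * i1;
    s2(k, 1) += (double)i2 * i2;
    s2(k, 2) += (double)i3 * i3;
    s2(k, 3) += (double)i1 * i2;
    s2(k, 4) += (double)i1 * i3;
    s2(k, 5) += (double)i2 * i3;
    if (i1 < bb(k, 0)) bb(k, 0) = i1;
    if (i1 > bb(k, 1)) bb(k, 1) = i1;
    if (i2 < bb(k, 2)) bb(k, 2) = i2;
    if (i2 > bb(k, 3)) bb(k, 3) = i2;
    if (i3 < bb(k, 4)) bb(k, 4) = i3;
    if (i3 > bb(k, 5)) bb(k, 5) = i3;
    if (i1 == 0 || i1 == g.n1 - 1 || i2 == 0 || i2 == g.n2 - 1 ||
        i3 == 0 || i3 == g.n3 - 1)
      border[k] = true;
  }
  return List::create(_["count"] = cnt, _["sum1"] = s1, _["sum2"] = s2,
                      _["bbox"] = bb, _["touches_border"] = border);
}

// Relabel: map[k] is the new value for old label k (1-based); 0 deletes.
// [[Rcpp::export]]
IntegerVector cpp_relabel(IntegerVector labels, IntegerVector map) {
  R_xlen_t n = labels.size();
  IntegerVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    int L = labels[v];
    out[v] = (L > 0 && L <= map.size()) ? map[L - 1] : 0;
  }
  out.attr("dim") = labels.attr("dim");
  return out;
}
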