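#include "vox.h"
#include <queue>
using namespace Rcpp;

// Marker-controlled watershed by priority flooding. Voxels inside `mask`
// are flooded from the marker labels in increasing order of `landscape`;
// ties broken by insertion order (markers are seeded in raster order), so
// the result is fully deterministic. Every masked voxel reachable from a
// marker receives exactly one label; no watershed-line voxels are left
// unassigned.
struct QItem {
  double prio;
  uint64_t seq;
  R_xlen_t vox;
  int label;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.seq > b.seq;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector landscape, IntegerVector markers,
                            LogicalVector mask, IntegerVector dim,
                            int connectivity) {
  Grid3 g(dim);
  R_xlen_t n = g.size();
  if (landscape.size() != n || markers.size() != n || mask.size() != n)
    stop("input lengths do not match dim");
  IntegerVector lab(n, 0);
  auto off = neighbor_offsets(connectivity);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  uint64_t seq = 0;
  for (R_xlen_t v = 0; v < n; ++v) {
    if (markers[v] > 0 && mask[v]) {
      lab[v] = markers[v];
      pq.push({landscape[v], seq++, v, markers[v]});
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int i1, i2, i3;
    g.coords(it.vox, i1, i2, i3);
    for (auto& o : off) {
      int a = i1 + o[0], b = i2 + o[1], c = i3 + o[2];
      if (!g.inside(a, b, c)) continue;
      R_xlen_t w = g.idx(a, b, c);
      if (!mask[w] || lab[w]) continue;
      lab[w] = it.label;
      double p = std::max(it.prio, landscape[w]);
      pq.push({p, seq++, w, it.label});
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Greyscale morphological reconstruction by dilation (Vincent's hybrid
// algorithm): raster scan, anti-raster scan, then FIFO propagation.
// Requires marker <= ceiling everywhere; uses full 26-neighborhood.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_gray(NumericVector marker,
                                   NumericVector ceiling,
                                   IntegerVector dim) {
  Grid3 g(dim);
  R_xlen_t n = g.size();
  if (marker.size() != n || ceiling.size() != n)
    stop("input lengths do not match dim");
  NumericVector J(n);
  for (R_xlen_t v = 0; v < n; ++v)
    J[v] = std::min(marker[v], ceiling[v]);

  auto off = neighbor_offsets(26);
  std::vector<std::array<int, 3>> plus, minus;
  for (auto& o : off) {
    // split into neighbors already visited in a raster (plus) or
    // anti-raster (minus) scan
    if (o[2] < 0 || (o[2] == 0 && (o[1] < 0 || (o[1] == 0 && o[0] < 0))))
      plus.push_back(o);
    else
      minus.push_back(o);
  }
  // raster scan
  for (R_xlen_t v = 0; v < n; ++v) {
    int i1, i2, i3;
    g.coords(v, i1, i2, i3);
    double m = J[v];
    for (auto& o : plus) {
      int a = i1 + o[0], b = i2 + o[1], c = i3 + o[2];
      if (g.inside(a, b, c)) m = std::max(m, J[g.idx(a, b, c)]);
    }
    J[v] = std::min(m, ceiling[v]);
  }
  // anti-raster scan + queue seeding
  std::queue<R_xlen_t> fifo;
  for (R_xlen_t v = n - 1; v >= 0; --v) {
    int i1, i2, i3;
    g.coords(v, i1, i2, i3);
    double m = J[v];
    for (auto& o : minus) {
      int a = i1 + o[0], b = i2 + o[1], c = i3 + o[2];
      if (g.inside(a, b, c)) m = std::max(m, J[g.idx(a, b, c)]);
    }
    J[v] = std::min(m, ceiling[v]);
    for (auto& o : minus) {
      int a = i1 + o[0], b = i2 + o[1], c = i3 + o[2];
      if (!g.inside(a, b, c)) continue;
      R_xlen_t w = g.idx(a, b, c);
      if (J[w] < J[v] && J[w] < ceiling[w]) {
        fifo.push(v);
        break;
      }
    }
    if (v == 0) break;
  }
  // propagation
  while (!fifo.empty()) {
    R_xlen_t v = fifo.front();
    fifo.pop();
    int i1, i2, i3;
    g.coords(v, i1, i2, i3);
    for (auto& o : off) {
      int a = i1 + o[0], b = i2 + o[1], c = i3 + o[2];
      if (!g.inside(a, b, c)) continue;
      R_xlen_t w = g.idx(a, b, c);
      if (J[w] < J[v] && ceiling[w] != J[w]) {
        J[w] = std::min(J[v], ceiling[w]);
        fifo.push(w);
      }
    }
  }
  J.attr("dim") = dim;
  return J;
}
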