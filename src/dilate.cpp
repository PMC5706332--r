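#include "vox.h"
#include <queue>
using namespace Rcpp;

// Iterative one-voxel geodesic dilation of a label image: per iteration an
// unlabeled voxel that is inside `allowed`, not a `barrier` voxel, and
// face-adjacent to at least one labeled voxel takes the smallest adjacent
// label (a deterministic tie-break). Existing labels are never rewritten,
// so labels grow monotonically and can touch but never merge.
// [[Rcpp::export]]
IntegerVector cpp_geodesic_label_dilate(IntegerVector labels,
                                        LogicalVector allowed,
                                        LogicalVector barrier,
                                        IntegerVector dim, int iterations) {
  Grid3 g(dim);
  R_xlen_t n = g.size();
  if (labels.size() != n || allowed.size() != n || barrier.size() != n)
    stop("input lengths do not match dim");
  IntegerVector lab = clone(labels);
  auto off = neighbor_offsets(6);
  std::vector<R_xlen_t> frontier;
  for (R_xlen_t v = 0; v < n; ++v)
    if (lab[v] > 0) frontier.push_back(v);
  for (int it = 0; it < iterations && !frontier.empty(); ++it) {
    // collect candidate assignments from the current frontier, then apply
    std::vector<std::pair<R_xlen_t, int>> takes;
    for (R_xlen_t v : frontier) {
      int i1, i2, i3;
      g.coords(v, i1, i2, i3);
      for (auto& o : off) {
        int a = i1 + o[0], b = i2 + o[1], c = i3 + o[2];
        if (!g.inside(a, b, c)) continue;
        R_xlen_t w = g.idx(a, b, c);
        if (lab[w] == 0 && allowed[w] && !barrier[w])
          takes.push_back({w, lab[v]});
      }
    }
    std::vector<R_xlen_t> next;
    for (auto& t : takes) {
      if (lab[t.first] == 0 || t.second < lab[t.first]) {
        if (lab[t.first] == 0) next.push_back(t.first);
        lab[t.first] = t.second;
      }
    }
    frontier.swap(next);
  }
  lab.attr("dim") = dim;
  return lab;
}
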