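#include "vox.h"
using namespace Rcpp;

// Exhaustive multi-level Otsu on a 256-bin histogram: choose 1-3 cut
// points minimizing total within-class variance (equivalently maximizing
// between-class variance). Cut point t means "class boundary after bin t":
// a class covers bins [lo, t]. Returned thresholds are bin indices
// (0-based intensity values); a voxel with value <= threshold[1] is in
// class 0, etc.
// [[Rcpp::export]]
IntegerVector cpp_multiotsu(NumericVector hist, int classes) {
  int B = hist.size();
  if (B != 256) stop("expected a 256-bin histogram");
  if (classes < 2 || classes > 4) stop("classes must be 2, 3 or 4");
  std::vector<double> w(B + 1, 0.0), m(B + 1, 0.0);
  for (int i = 0; i < B; ++i) {
    w[i + 1] = w[i] + hist[i];
    m[i + 1] = m[i] + hist[i] * i;
  }
  if (w[B] <= 0) stop("empty histogram");
  // between-class contribution of bins [a, b]
  auto score = [&](int a, int b) {
    double wt = w[b + 1] - w[a];
    if (wt <= 0) return 0.0;
    double mu = m[b + 1] - m[a];
    return mu * mu / wt;
  };
  double best = -1.0;
  IntegerVector cuts(classes - 1);
  if (classes == 2) {
    for (int t1 = 0; t1 < B - 1; ++t1) {
      double s = score(0, t1) + score(t1 + 1, B - 1);
      if (s > best) { best = s; cuts[0] = t1; }
    }
  } else if (classes == 3) {
    for (int t1 = 0; t1 < B - 2; ++t1) {
      double s1 = score(0, t1);
      for (int t2 = t1 + 1; t2 < B - 1; ++t2) {
        double s = s1 + score(t1 + 1, t2) + score(t2 + 1, B - 1);
        if (s > best) { best = s; cuts[0] = t1; cuts[1] = t2; }
      }
    }
  } else {
    for (int t1 = 0; t1 < B - 3; ++t1) {
      double s1 = score(0, t1);
      for (int t2 = t1 + 1; t2 < B - 2; ++t2) {
        double s2 = s1 + score(t1 + 1, t2);
        for (int t3 = t2 + 1; t3 < B - 1; ++t3) {
          double s = s2 + score(t2 + 1, t3) + score(t3 + 1, B - 1);
          if (s > best) {
            best = s; cuts[0] = t1; cuts[1] = t2; cuts[2] = t3;
          }
        }
      }
    }
  }
  return cuts;
}
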