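#ifndef CTMORPH_VOX_H
#define CTMORPH_VOX_H

#include <Rcpp.h>
#include <vector>
#include <cstdint>

// Shared helpers for 3D grids stored as R arrays (column-major: the first
// index varies fastest). All voxel offsets are 0-based internally.

struct Grid3 {
  int n1, n2, n3;
  Grid3(const Rcpp::IntegerVector& d) : n1(d[0]), n2(d[1]), n3(d[2]) {}
  inline R_xlen_t size() const {
    return (R_xlen_t)n1 * n2 * n3;
  }
  inline R_xlen_t idx(int i1, int i2, int i3) const {
    return (R_xlen_t)i1 + (R_xlen_t)n1 * ((R_xlen_t)i2 + (R_xlen_t)n2 * i3);
  }
  inline void coords(R_xlen_t v, int& i1, int& i2, int& i3) const {
    i1 = (int)(v % n1);
    R_xlen_t r = v / n1;
    i2 = (int)(r % n2);
    i3 = (int)(r / n2);
  }
  inline bool inside(int i1, int i2, int i3) const {
    return i1 >= 0 && i1 < n1 && i2 >= 0 && i2 < n2 && i3 >= 0 && i3 < n3;
  }
};

// Neighborhood offset tables. connectivity is 6 (faces) or 26 (full cube).
inline std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  if (connectivity == 6) {
    off = {{{-1, 0, 0}}, {{1, 0, 0}}, {{0, -1, 0}},
           {{0, 1, 0}},  {{0, 0, -1}}, {{0, 0, 1}}};
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c)
          if (a || b || c) off.push_back({{a, b, c}});
  }
  return off;
}

#endif
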