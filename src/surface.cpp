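#include "vox.h"
using namespace Rcpp;

// Total area of the triangulated isosurface of a scalar field, extracted
// by marching tetrahedra: each grid cell is split into six tetrahedra
// sharing the main diagonal, and each tetrahedron contributes 0, 1 or 2
// triangles with vertices linearly interpolated to the iso level. Units:
// voxel edge = 1.

struct P3 {
  double x, y, z;
};

static inline P3 lerp(const P3& a, const P3& b, double va, double vb,
                      double iso) {
  double t = (iso - va) / (vb - va);
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
          a.z + t * (b.z - a.z)};
}

static inline double tri_area(const P3& a, const P3& b, const P3& c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static double tet_area(const P3 p[4], const double v[4], double iso) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) {
    in[i] = v[i] >= iso;
    if (in[i]) ++nin;
  }
  if (nin == 0 || nin == 4) return 0.0;
  int a[3], b[3], na = 0, nb = 0;
  for (int i = 0; i < 4; ++i) {
    if (in[i]) a[na++] = i;
    else b[nb++] = i;
  }
  if (nin == 1 || nin == 3) {
    // single triangle: the lone vertex against the other three
    int lone = (nin == 1) ? a[0] : b[0];
    int* rest = (nin == 1) ? b : a;
    P3 q0 = lerp(p[lone], p[rest[0]], v[lone], v[rest[0]], iso);
    P3 q1 = lerp(p[lone], p[rest[1]], v[lone], v[rest[1]], iso);
    P3 q2 = lerp(p[lone], p[rest[2]], v[lone], v[rest[2]], iso);
    return tri_area(q0, q1, q2);
  }
  // 2-2 split: quad across the four crossing edges, two triangles
  P3 q0 = lerp(p[a[0]], p[b[0]], v[a[0]], v[b[0]], iso);
  P3 q1 = lerp(p[a[0]], p[b[1]], v[a[0]], v[b[1]], iso);
  P3 q2 = lerp(p[a[1]], p[b[1]], v[a[1]], v[b[1]], iso);
  P3 q3 = lerp(p[a[1]], p[b[0]], v[a[1]], v[b[0]], iso);
  return tri_area(q0, q1, q2) + tri_area(q0, q2, q3);
}

// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector field, IntegerVector dim,
                           double iso) {
  Grid3 g(dim);
  if (field.size() != g.size()) stop("field length does not match dim");
  // cube corners (Bourke ordering) and 6-tet decomposition on diagonal 0-6
  static const int corner[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0},
                                   {0, 1, 0}, {0, 0, 1}, {1, 0, 1},
                                   {1, 1, 1}, {0, 1, 1}};
  static const int tets[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                                 {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  double area = 0.0;
  for (int k = 0; k + 1 < g.n3; ++k)
    for (int j = 0; j + 1 < g.n2; ++j)
      for (int i = 0; i + 1 < g.n1; ++i) {
        double cv[8];
        P3 cp[8];
        bool lo = false, hi = false;
        for (int c = 0; c < 8; ++c) {
          int a = i + corner[c][0], b = j + corner[c][1],
              d = k + corner[c][2];
          cv[c] = field[g.idx(a, b, d)];
          cp[c] = {(double)a, (double)b, (double)d};
          if (cv[c] >= iso) hi = true;
          else lo = true;
        }
        if (!lo || !hi) continue;
        for (int t = 0; t < 6; ++t) {
          P3 tp[4];
          double tv[4];
          for (int c = 0; c < 4; ++c) {
            tp[c] = cp[tets[t][c]];
            tv[c] = cv[tets[t][c]];
          }
          area += tet_area(tp, tv, iso);
        }
      }
  return area;
}
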