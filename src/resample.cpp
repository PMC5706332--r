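#include "vox.h"
using namespace Rcpp;

// Resample a volume under an affine map: for output voxel index q
// (0-based), the source position is p = A q + b (also 0-based voxel
// coordinates of the input). Trilinear interpolation for greyscale,
// nearest-neighbor for label data; out-of-bounds samples get `fill`.
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, IntegerVector dim_in,
                                  IntegerVector dim_out, NumericMatrix A,
                                  NumericVector b, bool nearest,
                                  double fill) {
  Grid3 gin(dim_in), gout(dim_out);
  if (vol.size() != gin.size()) stop("volume length does not match dim_in");
  NumericVector out(gout.size());
  double a11 = A(0, 0), a12 = A(0, 1), a13 = A(0, 2);
  double a21 = A(1, 0), a22 = A(1, 1), a23 = A(1, 2);
  double a31 = A(2, 0), a32 = A(2, 1), a33 = A(2, 2);
  for (int k = 0; k < gout.n3; ++k)
    for (int j = 0; j < gout.n2; ++j)
      for (int i = 0; i < gout.n1; ++i) {
        double x = a11 * i + a12 * j + a13 * k + b[0];
        double y = a21 * i + a22 * j + a23 * k + b[1];
        double z = a31 * i + a32 * j + a33 * k + b[2];
        R_xlen_t q = gout.idx(i, j, k);
        if (nearest) {
          int xi = (int)std::lround(x), yi = (int)std::lround(y),
              zi = (int)std::lround(z);
          out[q] = gin.inside(xi, yi, zi) ? vol[gin.idx(xi, yi, zi)] : fill;
        } else {
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
          if (x0 < 0 || y0 < 0 || z0 < 0 || x0 + 1 >= gin.n1 ||
              y0 + 1 >= gin.n2 || z0 + 1 >= gin.n3) {
            // allow exact upper-boundary hits
            if (x >= 0 && y >= 0 && z >= 0 && x <= gin.n1 - 1 &&
                y <= gin.n2 - 1 && z <= gin.n3 - 1) {
              int xi = std::min((int)x, gin.n1 - 1);
              int yi = std::min((int)y, gin.n2 - 1);
              int zi = std::min((int)z, gin.n3 - 1);
              out[q] = vol[gin.idx(xi, yi, zi)];
            } else {
              out[q] = fill;
            }
            continue;
          }
          double fx = x - x0, fy = y - y0, fz = z - z0;
          double c000 = vol[gin.idx(x0, y0, z0)];
          double c100 = vol[gin.idx(x0 + 1, y0, z0)];
          double c010 = vol[gin.idx(x0, y0 + 1, z0)];
          double c110 = vol[gin.idx(x0 + 1, y0 + 1, z0)];
          double c001 = vol[gin.idx(x0, y0, z0 + 1)];
          double c101 = vol[gin.idx(x0 + 1, y0, z0 + 1)];
          double c011 = vol[gin.idx(x0, y0 + 1, z0 + 1)];
          double c111 = vol[gin.idx(x0 + 1, y0 + 1, z0 + 1)];
          double c00 = c000 * (1 - fx) + c100 * fx;
          double c10 = c010 * (1 - fx) + c110 * fx;
          double c01 = c001 * (1 - fx) + c101 * fx;
          double c11 = c011 * (1 - fx) + c111 * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          out[q] = c0 * (1 - fz) + c1 * fz;
        }
      }
  out.attr("dim") = dim_out;
  return out;
}

// 2x mean-pooling downsample (trailing odd slices dropped), for the
// registration pyramid.
// [[Rcpp::export]]
NumericVector cpp_downsample2(NumericVector vol, IntegerVector dim) {
  Grid3 g(dim);
  if (vol.size() != g.size()) stop("volume length does not match dim");
  IntegerVector dn = IntegerVector::create(g.n1 / 2, g.n2 / 2, g.n3 / 2);
  Grid3 go(dn);
  NumericVector out(go.size());
  for (int k = 0; k < go.n3; ++k)
    for (int j = 0; j < go.n2; ++j)
      for (int i = 0; i < go.n1; ++i) {
        double s = 0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx)
              s += vol[g.idx(2 * i + dx, 2 * j + dy, 2 * k + dz)];
        out[go.idx(i, j, k)] = s / 8.0;
      }
  out.attr("dim") = dn;
  return out;
}
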