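#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// reflect-101 index (no edge duplication)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// Edge-preserving bilateral filter (Tomasi & Manduchi). Square neighbourhood of
// diameter d; weights = spatial Gaussian (sigma_spatial) x radiometric Gaussian
// (sigma_range). Intensities are expected on the 0..255 scale; the radiometric
// kernel is tabulated over integer differences, exact for integer-valued input.
// [[Rcpp::export]]
NumericMatrix bilateral_cpp(NumericMatrix img, double sigma_spatial,
                            double sigma_range, int d) {
  int nr = img.nrow(), nc = img.ncol();
  int radius = d / 2;
  if (radius < 1) return clone(img);

  int w = 2 * radius + 1;
  std::vector<double> ws(w * w);
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      ws[(dy + radius) * w + (dx + radius)] =
        std::exp(-(double)(dx * dx + dy * dy) / (2.0 * sigma_spatial * sigma_spatial));

  // range kernel LUT over |difference| rounded to nearest integer
  std::vector<double> wr(512);
  for (int k = 0; k < 512; ++k)
    wr[k] = std::exp(-(double)(k * k) / (2.0 * sigma_range * sigma_range));

  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double centre = img(i, j), num = 0.0, den = 0.0;
      for (int dy = -radius; dy <= radius; ++dy) {
        int ii = reflect_idx(i + dy, nr);
        for (int dx = -radius; dx <= radius; ++dx) {
          int jj = reflect_idx(j + dx, nc);
          double v = img(ii, jj);
          int k = (int)(std::fabs(v - centre) + 0.5);
          if (k > 511) k = 511;
          double wgt = ws[(dy + radius) * w + (dx + radius)] * wr[k];
          num += wgt * v;
          den += wgt;
        }
      }
      out(i, j) = num / den;
    }
  }
  return out;
}

// Inverse-mapped affine resampling. m = (a, b, tx, c, d, ty) maps an OUTPUT
// pixel position (x, y) (0-based col/row) to its SOURCE sampling position.
// bilinear = true: bilinear interpolation; false: nearest neighbour.
// Samples falling outside the source are set to fill.
// [[Rcpp::export]]
NumericMatrix warp_cpp(NumericMatrix img, NumericVector m, bool bilinear,
                       double fill) {
  int nr = img.nrow(), nc = img.ncol();
  double a = m[0], b = m[1], tx = m[2], c = m[3], d = m[4], ty = m[5];
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double x = (double)j;
    for (int i = 0; i < nr; ++i) {
      double y = (double)i;
      double sx = a * x + b * y + tx;
      double sy = c * x + d * y + ty;
      if (bilinear) {
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
        if (x0 < -1 || y0 < -1 || x0 > nc - 1 || y0 > nr - 1) {
          out(i, j) = fill;
          continue;
        }
        double fx = sx - x0, fy = sy - y0;
        // fetch with fill outside
        double v00 = (x0 >= 0 && y0 >= 0) ? img(y0, x0) : fill;
        double v01 = (x0 + 1 < nc && y0 >= 0) ? img(y0, x0 + 1) : fill;
        double v10 = (x0 >= 0 && y0 + 1 < nr) ? img(y0 + 1, x0) : fill;
        double v11 = (x0 + 1 < nc && y0 + 1 < nr) ? img(y0 + 1, x0 + 1) : fill;
        out(i, j) = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                    fy * ((1 - fx) * v10 + fx * v11);
      } else {
        int xn = (int)std::floor(sx + 0.5), yn = (int)std::floor(sy + 0.5);
        out(i, j) = (xn >= 0 && yn >= 0 && xn < nc && yn < nr) ? img(yn, xn) : fill;
      }
    }
  }
  return out;
}
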