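// Low-level raster kernels: separable Gaussian filtering with reflective
// boundaries, Catmull-Rom resampling, and the distance/arc-length fields
// used by the phantom renderer.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // mirror with edge duplication: -1 -> 0, n -> n-1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma, int &radius) {
  radius = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (auto &v : k) v /= s;
  return k;
}

// Separable Gaussian blur, reflective padding. sigma = 0 returns a copy.
// [[Rcpp::export(name = ".gauss_blur_cpp")]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  int radius;
  std::vector<double> k = gauss_kernel(sigma, radius);
  NumericMatrix tmp(H, W), out(H, W);
  // along rows (vertical)
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int d = -radius; d <= radius; ++d)
        acc += k[d + radius] * img(reflect_idx(r + d, H), c);
      tmp(r, c) = acc;
    }
  // along columns (horizontal)
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int d = -radius; d <= radius; ++d)
        acc += k[d + radius] * tmp(r, reflect_idx(c + d, W));
      out(r, c) = acc;
    }
  return out;
}

static inline double catmull_rom(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.0 - 2.5 * t * t + 1.5 * t * t * t;
  if (t < 2.0) return 2.0 - 4.0 * t + 2.5 * t * t - 0.5 * t * t * t;
  return 0.0;
}

// Catmull-Rom (bicubic) resampling to an H2 x W2 grid; edges clamped.
// [[Rcpp::export(name = ".bicubic_resize_cpp")]]
NumericMatrix bicubic_resize_cpp(NumericMatrix img, int H2, int W2) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H2, W2);
  double sr = (double)H / H2, sc = (double)W / W2;
  for (int j = 0; j < W2; ++j) {
    double xc = (j + 0.5) * sc - 0.5;
    int c0 = (int)std::floor(xc);
    double wc[4];
    for (int d = -1; d <= 2; ++d) wc[d + 1] = catmull_rom(xc - (c0 + d));
    for (int i = 0; i < H2; ++i) {
      double xr = (i + 0.5) * sr - 0.5;
      int r0 = (int)std::floor(xr);
      double wr[4];
      for (int d = -1; d <= 2; ++d) wr[d + 1] = catmull_rom(xr - (r0 + d));
      double acc = 0.0;
      for (int dc = -1; dc <= 2; ++dc) {
        int cc = std::min(std::max(c0 + dc, 0), W - 1);
        double rowacc = 0.0;
        for (int dr = -1; dr <= 2; ++dr) {
          int rr = std::min(std::max(r0 + dr, 0), H - 1);
          rowacc += wr[dr + 1] * img(rr, cc);
        }
        acc += wc[dc + 1] * rowacc;
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// For every pixel within `radius` of the sampled centerline, record the
// distance to the nearest centerline sample and that sample's arc length.
// pts: n x 3 matrix (row, col, arc), 0-based coordinates; pixels never
// reached keep distance = Inf.
// [[Rcpp::export(name = ".polyline_field_cpp")]]
List polyline_field_cpp(int H, int W, NumericMatrix pts, double radius) {
  NumericMatrix dist(H, W), arc(H, W);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  std::fill(arc.begin(), arc.end(), NA_REAL);
  int n = pts.nrow(), rad = (int)std::ceil(radius);
  for (int s = 0; s < n; ++s) {
    double pr = pts(s, 0), pc = pts(s, 1), pa = pts(s, 2);
    int r0 = std::max(0, (int)std::floor(pr) - rad);
    int r1 = std::min(H - 1, (int)std::ceil(pr) + rad);
    int c0 = std::max(0, (int)std::floor(pc) - rad);
    int c1 = std::min(W - 1, (int)std::ceil(pc) + rad);
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) {
        double d = std::sqrt((r - pr) * (r - pr) + (c - pc) * (c - pc));
        if (d < dist(r, c)) {
          dist(r, c) = d;
          arc(r, c) = pa;
        }
      }
  }
  return List::create(_["dist"] = dist, _["arc"] = arc);
}
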