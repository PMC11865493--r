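// Local SSIM map and the region-prioritized structural-dissimilarity loss,
// with an exact reverse-mode gradient w.r.t. the prediction. Window
// statistics use a separable Gaussian filter with zero padding; that
// operator is symmetric, hence self-adjoint, which keeps the backward pass
// a plain convolution with the same window.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::_;

static vec window_kernel(int radius, double sigma) {
  vec k(2 * radius + 1);
  for (int i = -radius; i <= radius; ++i)
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
  return k / accu(k);
}

// zero-padded 'same' separable convolution with a symmetric 1-D kernel
static mat gwconv(const mat &x, const vec &k) {
  int H = x.n_rows, W = x.n_cols, radius = (k.n_elem - 1) / 2;
  mat tmp(H, W, fill::zeros), out(H, W, fill::zeros);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      int dlo = std::max(-radius, -r), dhi = std::min(radius, H - 1 - r);
      for (int d = dlo; d <= dhi; ++d) acc += k[d + radius] * x(r + d, c);
      tmp(r, c) = acc;
    }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double acc = 0.0;
      int dlo = std::max(-radius, -c), dhi = std::min(radius, W - 1 - c);
      for (int d = dlo; d <= dhi; ++d) acc += k[d + radius] * tmp(r, c + d);
      out(r, c) = acc;
    }
  return out;
}

struct SsimParts {
  mat mux, muy, sxx, syy, sxy, A1, A2, B1, B2, S;
};

static SsimParts ssim_parts(const mat &y, const mat &x, double c1, double c2,
                            const vec &k) {
  SsimParts p;
  p.mux = gwconv(x, k);
  p.muy = gwconv(y, k);
  p.sxx = gwconv(x % x, k) - p.mux % p.mux;
  p.syy = gwconv(y % y, k) - p.muy % p.muy;
  p.sxy = gwconv(x % y, k) - p.mux % p.muy;
  p.A1 = 2.0 * p.mux % p.muy + c1;
  p.A2 = 2.0 * p.sxy + c2;
  p.B1 = p.mux % p.mux + p.muy % p.muy + c1;
  p.B2 = p.sxx + p.syy + c2;
  p.S = (p.A1 % p.A2) / (p.B1 % p.B2);
  return p;
}

// [[Rcpp::export(name = ".ssim_map_cpp")]]
NumericMatrix ssim_map_cpp(NumericMatrix y, NumericMatrix yhat, double c1,
                           double c2, int radius, double sigma) {
  mat Y(y.begin(), y.nrow(), y.ncol(), false);
  mat X(yhat.begin(), yhat.nrow(), yhat.ncol(), false);
  vec k = window_kernel(radius, sigma);
  SsimParts p = ssim_parts(Y, X, c1, c2, k);
  NumericMatrix out(y.nrow(), y.ncol());
  std::copy(p.S.begin(), p.S.end(), out.begin());
  return out;
}

// loss = mean( ((1 - S) / 2) ^ gamma ); gradient w.r.t. yhat
// [[Rcpp::export(name = ".scop_fwd_bwd_cpp")]]
List scop_fwd_bwd_cpp(NumericMatrix y, NumericMatrix yhat, NumericMatrix gamma,
                      double c1, double c2, int radius, double sigma,
                      bool want_grad) {
  int H = y.nrow(), W = y.ncol();
  mat Y(y.begin(), H, W, false);
  mat X(yhat.begin(), H, W, false);
  mat G(gamma.begin(), H, W, false);
  vec k = window_kernel(radius, sigma);
  SsimParts p = ssim_parts(Y, X, c1, c2, k);
  mat D = (1.0 - p.S) / 2.0;
  double n2 = (double)H * W;
  double loss = accu(pow(D, G)) / n2;
  if (!want_grad)
    return List::create(_["loss"] = loss, _["grad"] = R_NilValue);
  // d loss / d D = gamma * D^(gamma-1) / n2 ; d D / d S = -1/2
  mat gD = G % pow(D, G - 1.0) / n2;
  mat gS = -0.5 * gD;
  mat denom = p.B1 % p.B2;
  mat gA1 = gS % p.A2 / denom;
  mat gA2 = gS % p.A1 / denom;
  mat gB1 = -gS % p.S / p.B1;
  mat gB2 = -gS % p.S / p.B2;
  mat g_sxy = 2.0 * gA2;
  mat g_sxx = gB2;
  mat g_mux = 2.0 * p.muy % gA1 + 2.0 * p.mux % gB1 - 2.0 * p.mux % g_sxx -
              p.muy % g_sxy;
  mat gX = gwconv(g_mux, k) + 2.0 * X % gwconv(g_sxx, k) + Y % gwconv(g_sxy, k);
  NumericMatrix grad(H, W);
  std::copy(gX.begin(), gX.end(), grad.begin());
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
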