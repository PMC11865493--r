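// Convolutional building blocks for the residual U-Net: 3x3 'same'
// convolution, 1x1 convolution, 2x2 max pooling and nearest-neighbour 2x
// upsampling, each with its adjoint for backprop. Feature maps are R
// arrays with dim (H, W, B, C) — batch third, channels last — so a batch
// convolves as 9 large GEMMs over a zero-padded buffer (shifted 3x3 taps
// become contiguous row offsets; padding rows swallow cross-image and
// cross-column pollution and are discarded on harvest).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static IntegerVector dims4(SEXP x) {
  IntegerVector d = as<IntegerVector>(Rf_getAttrib(x, R_DimSymbol));
  if (d.size() != 4) stop("expected a (H, W, B, C) array");
  return d;
}

// The 3x3 convolutions run in single precision internally: the batched
// tap-GEMMs are memory-bandwidth-bound on one core, so halving the element
// size roughly doubles throughput; inputs/outputs stay double at the R
// boundary.
// ((H+2)(W+2)B) x C zero-padded matrix in padded column-major raster order
static arma::fmat pad_to_mat(const double *x, int H, int W, int B, int C) {
  int Hp = H + 2, Wp = W + 2;
  size_t Nb = (size_t)Hp * Wp;
  arma::fmat P(Nb * B, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    float *dst = P.colptr(ch);
    for (int b = 0; b < B; ++b) {
      const double *plane = x + ((size_t)ch * B + b) * H * W;
      float *block = dst + Nb * b;
      for (int c = 0; c < W; ++c) {
        const double *s = plane + (size_t)c * H;
        float *d = block + (size_t)(c + 1) * Hp + 1;
        for (int r = 0; r < H; ++r) d[r] = (float)s[r];
      }
    }
  }
  return P;
}

static void harvest_interior(const arma::fmat &P, double *out, int H, int W,
                             int B, int C, const double *bias) {
  int Hp = H + 2, Wp = W + 2;
  size_t Nb = (size_t)Hp * Wp;
  for (int ch = 0; ch < C; ++ch) {
    const float *src = P.colptr(ch);
    double bv = bias ? bias[ch] : 0.0;
    for (int b = 0; b < B; ++b) {
      double *plane = out + ((size_t)ch * B + b) * H * W;
      const float *block = src + Nb * b;
      for (int c = 0; c < W; ++c) {
        const float *s = block + (size_t)(c + 1) * Hp + 1;
        double *d = plane + (size_t)c * H;
        for (int r = 0; r < H; ++r) d[r] = (double)s[r] + bv;
      }
    }
  }
}

// tap weight slice: Wk(cin, cout) for kernel offset (dr, dc)
static arma::fmat tap_weights(const arma::mat &Wm, int C, int Cout, int dr,
                              int dc) {
  arma::fmat Wk(C, Cout);
  int tap = (dc + 1) * 3 + (dr + 1);
  for (int co = 0; co < Cout; ++co)
    for (int ch = 0; ch < C; ++ch) Wk(ch, co) = (float)Wm(co, ch * 9 + tap);
  return Wk;
}

// weights: Cout x (Cin*9); bias length Cout
// [[Rcpp::export(name = ".conv3_fwd_cpp")]]
NumericVector conv3_fwd_cpp(NumericVector x, NumericMatrix wt, NumericVector b) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], B = d[2], C = d[3], Cout = wt.nrow();
  if (wt.ncol() != C * 9) stop("weight shape mismatch");
  int Hp = H + 2;
  size_t N = (size_t)Hp * (W + 2) * B;
  arma::fmat Xp = pad_to_mat(REAL(x), H, W, B, C);
  arma::mat Wm(wt.begin(), Cout, C * 9, false);
  arma::fmat Op(N, Cout, arma::fill::zeros);
  size_t s = Hp + 1, e = N - Hp - 2; // span covering every interior row
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      int off = dr + dc * Hp;
      arma::fmat Wk = tap_weights(Wm, C, Cout, dr, dc);
      Op.rows(s, e) += Xp.rows(s + off, e + off) * Wk;
    }
  NumericVector out((size_t)H * W * B * Cout);
  harvest_interior(Op, REAL(out), H, W, B, Cout, REAL(b));
  out.attr("dim") = IntegerVector::create(H, W, B, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv3_bwd_cpp")]]
List conv3_bwd_cpp(NumericVector x, NumericMatrix wt, NumericVector gout) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], B = d[2], C = d[3], Cout = wt.nrow();
  int Hp = H + 2;
  size_t N = (size_t)Hp * (W + 2) * B;
  arma::fmat Xp = pad_to_mat(REAL(x), H, W, B, C);
  arma::fmat Gp = pad_to_mat(REAL(gout), H, W, B, Cout);
  arma::mat Wm(wt.begin(), Cout, C * 9, false);
  NumericMatrix gW(Cout, C * 9);
  arma::mat gWm(gW.begin(), Cout, C * 9, false);
  arma::fmat gXp(N, C, arma::fill::zeros);
  size_t s = Hp + 1, e = N - Hp - 2;
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      int off = dr + dc * Hp;
      int tap = (dc + 1) * 3 + (dr + 1);
      // weight gradient for this tap: shifted input against the output grad
      arma::fmat gWk = Xp.rows(s + off, e + off).t() * Gp.rows(s, e);
      for (int co = 0; co < Cout; ++co)
        for (int ch = 0; ch < C; ++ch)
          gWm(co, ch * 9 + tap) = (double)gWk(ch, co);
      // input gradient: output grad through the flipped kernel
      arma::fmat Wk = tap_weights(Wm, C, Cout, dr, dc);
      gXp.rows(s + off, e + off) += Gp.rows(s, e) * Wk.t();
    }
  NumericVector gb(Cout);
  arma::mat G(REAL(gout), (size_t)H * W * B, Cout, false);
  for (int co = 0; co < Cout; ++co) gb[co] = arma::accu(G.col(co));
  NumericVector gx((size_t)H * W * B * C);
  harvest_interior(gXp, REAL(gx), H, W, B, C, nullptr);
  gx.attr("dim") = IntegerVector::create(H, W, B, C);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export(name = ".conv1_fwd_cpp")]]
NumericVector conv1_fwd_cpp(NumericVector x, NumericMatrix wt, NumericVector b) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], B = d[2], C = d[3], Cout = wt.nrow();
  if (wt.ncol() != C) stop("weight shape mismatch");
  size_t N = (size_t)H * W * B;
  arma::mat X(REAL(x), N, C, false);
  arma::mat Wm(wt.begin(), Cout, C, false);
  NumericVector out(N * Cout);
  arma::mat O(REAL(out), N, Cout, false);
  O = X * Wm.t();
  for (int co = 0; co < Cout; ++co) O.col(co) += b[co];
  out.attr("dim") = IntegerVector::create(H, W, B, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv1_bwd_cpp")]]
List conv1_bwd_cpp(NumericVector x, NumericMatrix wt, NumericVector gout) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], B = d[2], C = d[3], Cout = wt.nrow();
  size_t N = (size_t)H * W * B;
  arma::mat X(REAL(x), N, C, false);
  arma::mat G(REAL(gout), N, Cout, false);
  arma::mat Wm(wt.begin(), Cout, C, false);
  NumericMatrix gW(Cout, C);
  arma::mat gWm(gW.begin(), Cout, C, false);
  gWm = G.t() * X;
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) gb[co] = arma::accu(G.col(co));
  NumericVector gx(N * C);
  arma::mat GX(REAL(gx), N, C, false);
  GX = G * Wm;
  gx.attr("dim") = IntegerVector::create(H, W, B, C);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; even H, W required
// [[Rcpp::export(name = ".maxpool_fwd_cpp")]]
List maxpool_fwd_cpp(NumericVector x) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], B = d[2], C = d[3];
  if (H % 2 || W % 2) stop("max pooling needs even spatial dims");
  int H2 = H / 2, W2 = W / 2;
  size_t nplanes = (size_t)B * C;
  NumericVector out((size_t)H2 * W2 * nplanes);
  IntegerVector idx((size_t)H2 * W2 * nplanes);
  const double *X = REAL(x);
  double *O = REAL(out);
  int *I = INTEGER(idx);
  for (size_t pl = 0; pl < nplanes; ++pl) {
    const double *xp = X + pl * H * W;
    double *op = O + pl * H2 * W2;
    int *ip = I + pl * H2 * W2;
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r) {
        size_t base = (size_t)(2 * c) * H + 2 * r;
        const int o4[4] = {0, 1, H, H + 1};
        double best = xp[base];
        int barg = 0;
        for (int k = 1; k < 4; ++k)
          if (xp[base + o4[k]] > best) { best = xp[base + o4[k]]; barg = k; }
        op[(size_t)c * H2 + r] = best;
        ip[(size_t)c * H2 + r] = barg;
      }
  }
  out.attr("dim") = IntegerVector::create(H2, W2, B, C);
  idx.attr("dim") = IntegerVector::create(H2, W2, B, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
NumericVector maxpool_bwd_cpp(NumericVector gout, IntegerVector idx, int H,
                              int W) {
  IntegerVector d = dims4(gout);
  int H2 = d[0], W2 = d[1], B = d[2], C = d[3];
  size_t nplanes = (size_t)B * C;
  NumericVector gx((size_t)H * W * nplanes);
  const double *G = REAL(gout);
  const int *I = INTEGER(idx);
  double *GX = REAL(gx);
  const int o4[4] = {0, 1, H, H + 1};
  for (size_t pl = 0; pl < nplanes; ++pl) {
    const double *gp = G + pl * H2 * W2;
    const int *ip = I + pl * H2 * W2;
    double *xp = GX + pl * H * W;
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r) {
        size_t o = (size_t)c * H2 + r;
        xp[(size_t)(2 * c) * H + 2 * r + o4[ip[o]]] += gp[o];
      }
  }
  gx.attr("dim") = IntegerVector::create(H, W, B, C);
  return gx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export(name = ".upsample_fwd_cpp")]]
NumericVector upsample_fwd_cpp(NumericVector x) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], B = d[2], C = d[3], H2 = 2 * H, W2 = 2 * W;
  size_t nplanes = (size_t)B * C;
  NumericVector out((size_t)H2 * W2 * nplanes);
  const double *X = REAL(x);
  double *O = REAL(out);
  for (size_t pl = 0; pl < nplanes; ++pl) {
    const double *xp = X + pl * H * W;
    double *op = O + pl * H2 * W2;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double v = xp[(size_t)c * H + r];
        size_t base = (size_t)(2 * c) * H2 + 2 * r;
        op[base] = v;
        op[base + 1] = v;
        op[base + H2] = v;
        op[base + H2 + 1] = v;
      }
  }
  out.attr("dim") = IntegerVector::create(H2, W2, B, C);
  return out;
}

// [[Rcpp::export(name = ".upsample_bwd_cpp")]]
NumericVector upsample_bwd_cpp(NumericVector gout) {
  IntegerVector d = dims4(gout);
  int H2 = d[0], W2 = d[1], B = d[2], C = d[3], H = H2 / 2, W = W2 / 2;
  size_t nplanes = (size_t)B * C;
  NumericVector gx((size_t)H * W * nplanes);
  const double *G = REAL(gout);
  double *GX = REAL(gx);
  for (size_t pl = 0; pl < nplanes; ++pl) {
    const double *gp = G + pl * H2 * W2;
    double *xp = GX + pl * H * W;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        size_t base = (size_t)(2 * c) * H2 + 2 * r;
        xp[(size_t)c * H + r] =
            gp[base] + gp[base + 1] + gp[base + H2] + gp[base + H2 + 1];
      }
  }
  gx.attr("dim") = IntegerVector::create(H, W, B, C);
  return gx;
}
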