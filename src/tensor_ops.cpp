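// Low-level tensor kernels for the facnet compute core.
//
// Layout convention (column-major R arrays):
//   activations  dim = c(C, H, W, N)   flat index c + C*(h + H*(w + W*n))
//   conv weights dim = c(Cin, kh, kw, Cout)
// Convolutions are realized as im2col + GEMM; the transposed convolution is
// driven from R through cpp_conv2d_bwd_input (the adjoint of cpp_conv2d).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void get4(const NumericVector& x, int& a, int& b, int& c, int& d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d tensor");
  a = dm[0]; b = dm[1]; c = dm[2]; d = dm[3];
}

static inline int out_size(int H, int k, int stride, int pad, int dil) {
  return (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

static arma::mat im2col(const double* x, int C, int H, int W, int N,
                        int kh, int kw, int stride, int pad, int dil,
                        int Ho, int Wo) {
  const int K = C * kh * kw, L = Ho * Wo * N;
  arma::mat col(K, L, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const int l = ho + Ho * (wo + Wo * n);
        double* cp = col.colptr(l);
        for (int j = 0; j < kw; ++j) {
          const int wi = wo * stride - pad + j * dil;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int hi = ho * stride - pad + i * dil;
            if (hi < 0 || hi >= H) continue;
            const double* xp = x + (size_t)C * (hi + (size_t)H * (wi + (size_t)W * n));
            std::copy(xp, xp + C, cp + (size_t)C * (i + kh * j));
          }
        }
      }
  return col;
}

static void col2im(const arma::mat& col, double* gx, int C, int H, int W, int N,
                   int kh, int kw, int stride, int pad, int dil, int Ho, int Wo) {
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const int l = ho + Ho * (wo + Wo * n);
        const double* cp = col.colptr(l);
        for (int j = 0; j < kw; ++j) {
          const int wi = wo * stride - pad + j * dil;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int hi = ho * stride - pad + i * dil;
            if (hi < 0 || hi >= H) continue;
            double* gp = gx + (size_t)C * (hi + (size_t)H * (wi + (size_t)W * n));
            const double* sp = cp + (size_t)C * (i + kh * j);
            for (int c = 0; c < C; ++c) gp[c] += sp[c];
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int dil) {
  int C, H, W, N, Cin, kh, kw, Cout;
  get4(x, C, H, W, N);
  get4(w, Cin, kh, kw, Cout);
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int Ho = out_size(H, kh, stride, pad, dil);
  const int Wo = out_size(W, kw, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  arma::mat col = im2col(x.begin(), C, H, W, N, kh, kw, stride, pad, dil, Ho, Wo);
  const arma::mat Wm(w.begin(), (size_t)Cin * kh * kw, Cout, false, true);
  arma::mat y = Wm.t() * col;  // Cout x L
  if (b.size() > 0) {
    const arma::colvec bv(b.begin(), Cout, false, true);
    y.each_col() += bv;
  }
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_input(NumericVector gy, NumericVector w,
                                   int H, int W, int stride, int pad, int dil) {
  int Cout, Ho, Wo, N, Cin, kh, kw, Cout2;
  get4(gy, Cout, Ho, Wo, N);
  get4(w, Cin, kh, kw, Cout2);
  if (Cout != Cout2) stop("conv2d backward: channel mismatch");
  const arma::mat Wm(w.begin(), (size_t)Cin * kh * kw, Cout, false, true);
  const arma::mat Gy(gy.begin(), Cout, (size_t)Ho * Wo * N, false, true);
  arma::mat gcol = Wm * Gy;  // K x L
  NumericVector gx((size_t)Cin * H * W * N);
  col2im(gcol, gx.begin(), Cin, H, W, N, kh, kw, stride, pad, dil, Ho, Wo);
  gx.attr("dim") = IntegerVector::create(Cin, H, W, N);
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_weight(NumericVector x, NumericVector gy,
                                    int kh, int kw, int stride, int pad, int dil) {
  int C, H, W, N, Cout, Ho, Wo, N2;
  get4(x, C, H, W, N);
  get4(gy, Cout, Ho, Wo, N2);
  if (N != N2) stop("conv2d backward: batch mismatch");
  arma::mat col = im2col(x.begin(), C, H, W, N, kh, kw, stride, pad, dil, Ho, Wo);
  const arma::mat Gy(gy.begin(), Cout, (size_t)Ho * Wo * N, false, true);
  arma::mat gw = col * Gy.t();  // K x Cout
  NumericVector out(gw.begin(), gw.end());
  out.attr("dim") = IntegerVector::create(C, kh, kw, Cout);
  return out;
}

// Max pooling, zero padding, kernel k / stride s; argmax kept for backward.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int k, int s) {
  int C, H, W, N;
  get4(x, C, H, W, N);
  const int Ho = (H - k) / s + 1, Wo = (W - k) / s + 1;
  if (Ho <= 0 || Wo <= 0) stop("maxpool: kernel larger than input");
  NumericVector y((size_t)C * Ho * Wo * N);
  IntegerVector idx(y.size());  // flat spatial index h + H*w of the max
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          int bidx = -1;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * s + j;
            if (wi >= W) break;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * s + i;
              if (hi >= H) break;
              const double v = xp[c + (size_t)C * (hi + (size_t)H * (wi + (size_t)W * n))];
              if (v > best) { best = v; bidx = hi + H * wi; }
            }
          }
          const size_t o = c + (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * n));
          y[o] = best;
          idx[o] = bidx;
        }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx, int H, int W) {
  int C, Ho, Wo, N;
  get4(gy, C, Ho, Wo, N);
  NumericVector gx((size_t)C * H * W * N);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          const size_t o = c + (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * n));
          gx[c + (size_t)C * (idx[o] + (size_t)H * W * n)] += gy[o];
        }
  gx.attr("dim") = IntegerVector::create(C, H, W, N);
  return gx;
}

static inline void lin_coef(int i, int Ho, int H, int& i0, int& i1, double& t) {
  double src = (i + 0.5) * (double)H / Ho - 0.5;
  if (src < 0) src = 0;
  if (src > H - 1) src = H - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, H - 1);
  t = src - i0;
}

// Bilinear resize to Ho x Wo (half-pixel centers).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  int C, H, W, N;
  get4(x, C, H, W, N);
  NumericVector y((size_t)C * Ho * Wo * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo) {
      int w0, w1; double tw;
      lin_coef(wo, Wo, W, w0, w1, tw);
      for (int ho = 0; ho < Ho; ++ho) {
        int h0, h1; double th;
        lin_coef(ho, Ho, H, h0, h1, th);
        const double* p00 = xp + (size_t)C * (h0 + (size_t)H * (w0 + (size_t)W * n));
        const double* p10 = xp + (size_t)C * (h1 + (size_t)H * (w0 + (size_t)W * n));
        const double* p01 = xp + (size_t)C * (h0 + (size_t)H * (w1 + (size_t)W * n));
        const double* p11 = xp + (size_t)C * (h1 + (size_t)H * (w1 + (size_t)W * n));
        double* yp = y.begin() + (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * n));
        for (int c = 0; c < C; ++c)
          yp[c] = (1 - th) * (1 - tw) * p00[c] + th * (1 - tw) * p10[c] +
                  (1 - th) * tw * p01[c] + th * tw * p11[c];
      }
    }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector gy, int H, int W) {
  int C, Ho, Wo, N;
  get4(gy, C, Ho, Wo, N);
  NumericVector gx((size_t)C * H * W * N);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo) {
      int w0, w1; double tw;
      lin_coef(wo, Wo, W, w0, w1, tw);
      for (int ho = 0; ho < Ho; ++ho) {
        int h0, h1; double th;
        lin_coef(ho, Ho, H, h0, h1, th);
        const double* gp = gy.begin() + (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * n));
        double* p00 = gx.begin() + (size_t)C * (h0 + (size_t)H * (w0 + (size_t)W * n));
        double* p10 = gx.begin() + (size_t)C * (h1 + (size_t)H * (w0 + (size_t)W * n));
        double* p01 = gx.begin() + (size_t)C * (h0 + (size_t)H * (w1 + (size_t)W * n));
        double* p11 = gx.begin() + (size_t)C * (h1 + (size_t)H * (w1 + (size_t)W * n));
        for (int c = 0; c < C; ++c) {
          p00[c] += (1 - th) * (1 - tw) * gp[c];
          p10[c] += th * (1 - tw) * gp[c];
          p01[c] += (1 - th) * tw * gp[c];
          p11[c] += th * tw * gp[c];
        }
      }
    }
  gx.attr("dim") = IntegerVector::create(C, H, W, N);
  return gx;
}

// Per-position channel mode: at each (h, w, n) the C channel values are
// histogrammed into `bins` equal-width intervals spanning their [min, max];
// the result is the midpoint of the most-populated interval, ties broken
// toward the interval with the smaller midpoint. A degenerate range returns
// the common value.
// [[Rcpp::export]]
NumericVector cpp_channel_mode(NumericVector x, int bins) {
  int C, H, W, N;
  get4(x, C, H, W, N);
  if (bins < 2) stop("channel mode requires at least 2 bins");
  NumericVector y((size_t)H * W * N);
  std::vector<int> cnt(bins);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double* p = xp + (size_t)C * (h + (size_t)H * (w + (size_t)W * n));
        double lo = p[0], hi = p[0];
        for (int c = 1; c < C; ++c) {
          if (p[c] < lo) lo = p[c];
          if (p[c] > hi) hi = p[c];
        }
        const size_t o = h + (size_t)H * (w + (size_t)W * n);
        if (hi == lo) { y[o] = lo; continue; }
        const double width = (hi - lo) / bins;
        std::fill(cnt.begin(), cnt.end(), 0);
        for (int c = 0; c < C; ++c) {
          int b = (int)((p[c] - lo) / width);
          if (b >= bins) b = bins - 1;
          ++cnt[b];
        }
        int best = 0;
        for (int b = 1; b < bins; ++b)
          if (cnt[b] > cnt[best]) best = b;  // strict >: ties keep smaller midpoint
        y[o] = lo + (best + 0.5) * width;
      }
  y.attr("dim") = IntegerVector::create(1, H, W, N);
  return y;
}
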