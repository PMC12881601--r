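// Minimal CNN kernels: 2-D convolution (stride/dilation/asymmetric padding),
// 2x2 max pooling and 2x nearest-neighbour upsampling, forward and backward.
// Tensor layout everywhere: column-major R arrays dim (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int dil, int pad_lo, int pad_hi, int stride) {
  int eff = (k - 1) * dil + 1;
  return (in + pad_lo + pad_hi - eff) / stride + 1;
}

// im2col: (Ho*Wo) x (kh*kw*Cin) patch matrix for one sample.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int dil, int stride,
                   int ph, int pw, int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int kcol = ki + kh * (kj + kw * c);
        double* dst = col.colptr(kcol);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pw + kj * dil;
          bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - ph + ki * dil;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = xc[hi + (size_t)wi * H];
            dst[ho + (size_t)wo * Ho] = v;
          }
        }
      }
    }
  }
}

// col2im: scatter-add the patch matrix back onto the input grid.
static void col2im(const arma::mat& col, double* dx, int H, int W, int C,
                   int kh, int kw, int dil, int stride,
                   int ph, int pw, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int kcol = ki + kh * (kj + kw * c);
        const double* src = col.colptr(kcol);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pw + kj * dil;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - ph + ki * dil;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)wi * H] += src[ho + (size_t)wo * Ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int dil,
                         int pad_h_lo, int pad_h_hi, int pad_w_lo, int pad_w_hi) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = out_dim(H, kh, dil, pad_h_lo, pad_h_hi, stride);
  int Wo = out_dim(W, kw, dil, pad_w_lo, pad_w_hi, stride);
  int K = kh * kw * C, P = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(P, K);
  bool has_b = b.size() == Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
           kh, kw, dil, stride, pad_h_lo, pad_w_lo, Ho, Wo, col);
    arma::mat Yn(y.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    Yn = col * Wm;
    if (has_b) Yn.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int dil,
                int pad_h_lo, int pad_h_hi, int pad_w_lo, int pad_w_hi,
                bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int K = kh * kw * C, P = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)kh * kw * C * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::rowvec dB(db.begin(), Cout, false, true);
  arma::mat col(P, K), dcol(P, K);
  for (int n = 0; n < N; ++n) {
    arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)n * P * Cout, P, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
           kh, kw, dil, stride, pad_h_lo, pad_w_lo, Ho, Wo, col);
    dWm += col.t() * dYn;
    if (has_bias) dB += arma::sum(dYn, 0);
    dcol = dYn * Wm.t();
    col2im(dcol, dx.begin() + (size_t)n * H * W * C, H, W, C,
           kh, kw, dil, stride, pad_h_lo, pad_w_lo, Ho, Wo);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // linear index into x of each pooled max
  idx.attr("dim") = y.attr("dim");
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = 2 * ho, w0 = 2 * wo;
          double best = xc[h0 + (size_t)w0 * H];
          size_t bi = h0 + (size_t)w0 * H;
          for (int dw_ = 0; dw_ < 2; ++dw_)
            for (int dh = 0; dh < 2; ++dh) {
              size_t i = (h0 + dh) + (size_t)(w0 + dw_) * H;
              if (xc[i] > best) { best = xc[i]; bi = i; }
            }
          // y is (Ho,Wo,C,N): offset within (c,n) block is ho + Ho*wo
          y[((size_t)n * C + c) * Ho * Wo + ho + (size_t)wo * Ho] = best;
          idx[((size_t)n * C + c) * Ho * Wo + ho + (size_t)wo * Ho] = (int)(base + bi);
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      double* yc = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double v = xc[h + (size_t)w * H];
          size_t b = 2 * h + (size_t)(2 * w) * Ho;
          yc[b] = v; yc[b + 1] = v; yc[b + Ho] = v; yc[b + Ho + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* yc = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* xc = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          size_t b = 2 * h + (size_t)(2 * w) * Ho;
          xc[h + (size_t)w * H] = yc[b] + yc[b + 1] + yc[b + Ho] + yc[b + Ho + 1];
        }
    }
  return dx;
}
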