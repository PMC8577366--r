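#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Strided 2-D convolution kernels for the style-transfer networks,
// implemented as im2col / col2im plus BLAS matrix products.
// Tensors are dense double arrays in R's column-major layout:
//   activations x: dim (H, W, C, N)      weights w: dim (kh, kw, Cin, Cout)
// Zero padding `pad` on all four sides. No dilation.

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

// Gather patches of `src` (H x W x C slab) into a (kh*kw*C) x (Hq*Wq) matrix;
// row index r = ki + kh*kj + kh*kw*c, column q = hq + Hq*wq, source pixel
// (hq*stride - pad + ki, wq*stride - pad + kj).
static void im2col(const double* src, int H, int W, int C,
                   int Hq, int Wq, int kh, int kw, int stride, int pad,
                   arma::mat& K) {
  K.zeros();
  for (int c = 0; c < C; ++c) {
    const double* sc = src + (size_t)c * H * W;
    const int rbase = kh * kw * c;
    for (int wq = 0; wq < Wq; ++wq) {
      const int w0 = wq * stride - pad;
      for (int hq = 0; hq < Hq; ++hq) {
        const int h0 = hq * stride - pad;
        double* col = K.colptr(hq + (size_t)Hq * wq) + rbase;
        for (int kj = 0; kj < kw; ++kj) {
          const int wj = w0 + kj;
          if (wj < 0 || wj >= W) continue;
          const double* scc = sc + (size_t)wj * H;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = h0 + ki;
            if (hi >= 0 && hi < H) col[ki + kh * kj] = scc[hi];
          }
        }
      }
    }
  }
}

// Scatter-add the columns of K back into dst (the adjoint of im2col).
static void col2im(const arma::mat& K, double* dst, int H, int W, int C,
                   int Hq, int Wq, int kh, int kw, int stride, int pad) {
  for (int c = 0; c < C; ++c) {
    double* dc = dst + (size_t)c * H * W;
    const int rbase = kh * kw * c;
    for (int wq = 0; wq < Wq; ++wq) {
      const int w0 = wq * stride - pad;
      for (int hq = 0; hq < Hq; ++hq) {
        const int h0 = hq * stride - pad;
        const double* col = K.colptr(hq + (size_t)Hq * wq) + rbase;
        for (int kj = 0; kj < kw; ++kj) {
          const int wj = w0 + kj;
          if (wj < 0 || wj >= W) continue;
          double* dcc = dc + (size_t)wj * H;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = h0 + ki;
            if (hi >= 0 && hi < H) dcc[hi] += col[ki + kh * kj];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fw_cpp")]]
NumericVector conv_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  IntegerVector dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Ci = dw[2], Co = dw[3];
  if (Ci != C) stop("channel mismatch");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector y(Rcpp::no_init((R_xlen_t)Ho * Wo * Co * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Ci, Co,
                     false, true);
  const arma::colvec bv(const_cast<double*>(b.begin()), Co, false, true);
  arma::mat K(kh * kw * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, Ho, Wo, kh, kw,
           stride, pad, K);
    arma::mat Ym(y.begin() + (size_t)n * Ho * Wo * Co, (size_t)Ho * Wo, Co,
                 false, true);
    Ym = K.t() * Wm;
    Ym.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bw_cpp")]]
List conv_bw_cpp(NumericVector x, NumericVector w, NumericVector gy,
                 int stride, int pad) {
  IntegerVector dx = dims4(x), dw = dims4(w), dy = dims4(gy);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Ci = dw[2], Co = dw[3];
  const int Ho = dy[0], Wo = dy[1];
  NumericVector gx((R_xlen_t)x.size()); gx.attr("dim") = dx;
  NumericVector gwv((R_xlen_t)w.size()); gwv.attr("dim") = dw;
  NumericVector gb(Co);
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Ci, Co,
                     false, true);
  arma::mat gW(gwv.begin(), kh * kw * Ci, Co, false, true);
  arma::colvec gB(gb.begin(), Co, false, true);
  arma::mat K(kh * kw * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const arma::mat Gm(const_cast<double*>(gy.begin()) +
                       (size_t)n * Ho * Wo * Co, (size_t)Ho * Wo, Co,
                       false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, Ho, Wo, kh, kw,
           stride, pad, K);
    gW += K * Gm;
    gB += arma::sum(Gm, 0).t();
    arma::mat gK = Wm * Gm.t();
    col2im(gK, gx.begin() + (size_t)n * H * W * C, H, W, C, Ho, Wo, kh, kw,
           stride, pad);
  }
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gb);
}

// permute weights (kh, kw, Ci, Co) -> matrix (kh*kw*Co) x Ci with row
// r = ki + kh*kj + kh*kw*co
static arma::mat permuteW(const NumericVector& w, int kh, int kw, int Ci,
                          int Co) {
  arma::mat Wp(kh * kw * Co, Ci);
  const double* pw = w.begin();
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wp(ki + kh * kj + kh * kw * co, ci) =
            pw[ki + (size_t)kh * kj + (size_t)kh * kw * ci +
               (size_t)kh * kw * Ci * co];
  return Wp;
}

// Transposed convolution: output (H-1)*stride + kh - 2*pad.
// [[Rcpp::export(name = ".convt_fw_cpp")]]
NumericVector convt_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  IntegerVector dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Ci = dw[2], Co = dw[3];
  if (Ci != C) stop("channel mismatch");
  const int Ho = (H - 1) * stride + kh - 2 * pad;
  const int Wo = (W - 1) * stride + kw - 2 * pad;
  if (Ho <= 0 || Wo <= 0) stop("degenerate transposed-conv output");
  NumericVector y((R_xlen_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat Wp = permuteW(w, kh, kw, Ci, Co);
  const double* pb = b.begin();
  for (int n = 0; n < N; ++n) {
    const arma::mat Xm(const_cast<double*>(x.begin()) +
                       (size_t)n * H * W * C, (size_t)H * W, C, false, true);
    arma::mat M = Wp * Xm.t();            // (kh*kw*Co) x (H*W)
    double* yn = y.begin() + (size_t)n * Ho * Wo * Co;
    col2im(M, yn, Ho, Wo, Co, H, W, kh, kw, stride, pad);
    for (int co = 0; co < Co; ++co) {
      double* yc = yn + (size_t)co * Ho * Wo;
      for (size_t k = 0; k < (size_t)Ho * Wo; ++k) yc[k] += pb[co];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".convt_bw_cpp")]]
List convt_bw_cpp(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad) {
  IntegerVector dx = dims4(x), dw = dims4(w), dy = dims4(gy);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Ci = dw[2], Co = dw[3];
  const int Ho = dy[0], Wo = dy[1];
  NumericVector gx((R_xlen_t)x.size()); gx.attr("dim") = dx;
  NumericVector gwv((R_xlen_t)w.size()); gwv.attr("dim") = dw;
  NumericVector gb(Co);
  arma::mat Wp = permuteW(w, kh, kw, Ci, Co);
  arma::mat gWp(kh * kw * Co, Ci, arma::fill::zeros);
  double* pgb = gb.begin();
  arma::mat Kg(kh * kw * Co, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    const double* gyn = gy.begin() + (size_t)n * Ho * Wo * Co;
    // im2col on gy over the *input* grid (stride-s sampling of gy)
    im2col(gyn, Ho, Wo, Co, H, W, kh, kw, stride, pad, Kg);
    const arma::mat Xm(const_cast<double*>(x.begin()) +
                       (size_t)n * H * W * C, (size_t)H * W, C, false, true);
    arma::mat gXm(gx.begin() + (size_t)n * H * W * C, (size_t)H * W, C,
                  false, true);
    gXm += Kg.t() * Wp;
    gWp += Kg * Xm;
    for (int co = 0; co < Co; ++co) {
      const double* gc = gyn + (size_t)co * Ho * Wo;
      for (size_t k = 0; k < (size_t)Ho * Wo; ++k) pgb[co] += gc[k];
    }
  }
  // un-permute gWp into (kh, kw, Ci, Co)
  double* pgw = gwv.begin();
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          pgw[ki + (size_t)kh * kj + (size_t)kh * kw * ci +
              (size_t)kh * kw * Ci * co] =
            gWp(ki + kh * kj + kh * kw * co, ci);
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gb);
}
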