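// im2col/col2im convolution backed by BLAS GEMM (Armadillo).  Replaces the
// naive loops for the hot path; layout matches nn_ops.cpp: (H, W, C, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int dim4(const NumericVector& x, int k) {
  IntegerVector d = x.attr("dim");
  return d[k];
}

// Build the (HO*WO, KH*KW*C) patch matrix for image n.
static void im2col(const double* X, int H, int W, int C, int n,
                   int KH, int KW, int pad, int HO, int WO, arma::mat& cols) {
  const double* Xn = X + (size_t)H * W * C * n;
  for (int ci = 0; ci < C; ++ci)
    for (int kw = 0; kw < KW; ++kw)
      for (int kh = 0; kh < KH; ++kh) {
        const int col = kh + KH * (kw + KW * ci);
        for (int wo = 0; wo < WO; ++wo) {
          const int wx = wo + kw - pad;
          double* dst = cols.colptr(col) + (size_t)wo * HO;
          if (wx < 0 || wx >= W) {
            for (int ho = 0; ho < HO; ++ho) dst[ho] = 0.0;
            continue;
          }
          const double* src = Xn + (size_t)H * (wx + (size_t)W * ci);
          for (int ho = 0; ho < HO; ++ho) {
            const int hx = ho + kh - pad;
            dst[ho] = (hx >= 0 && hx < H) ? src[hx] : 0.0;
          }
        }
      }
}

// Scatter the patch-matrix gradient back into the image gradient.
static void col2im(const arma::mat& cols, int H, int W, int C, int n,
                   int KH, int KW, int pad, int HO, int WO, double* DX) {
  double* Xn = DX + (size_t)H * W * C * n;
  for (int ci = 0; ci < C; ++ci)
    for (int kw = 0; kw < KW; ++kw)
      for (int kh = 0; kh < KH; ++kh) {
        const int col = kh + KH * (kw + KW * ci);
        for (int wo = 0; wo < WO; ++wo) {
          const int wx = wo + kw - pad;
          if (wx < 0 || wx >= W) continue;
          const double* src = cols.colptr(col) + (size_t)wo * HO;
          double* dst = Xn + (size_t)H * (wx + (size_t)W * ci);
          for (int ho = 0; ho < HO; ++ho) {
            const int hx = ho + kh - pad;
            if (hx >= 0 && hx < H) dst[hx] += src[ho];
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward_gemm(NumericVector x, NumericVector w,
                                      NumericVector b, int pad) {
  const int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  const int KH = dim4(w, 0), KW = dim4(w, 1), CO = dim4(w, 3);
  const int HO = H + 2 * pad - KH + 1, WO = W + 2 * pad - KW + 1;
  NumericVector y((size_t)HO * WO * CO * N);
  y.attr("dim") = IntegerVector::create(HO, WO, CO, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), KH * KW * C, CO, false);
  arma::mat cols(HO * WO, KH * KW * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, KH, KW, pad, HO, WO, cols);
    arma::mat Yn(y.begin() + (size_t)HO * WO * CO * n, HO * WO, CO, false,
                 true);
    Yn = cols * Wm;
    for (int co = 0; co < CO; ++co) Yn.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward_gemm(NumericVector x, NumericVector w,
                              NumericVector dy, int pad) {
  const int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  const int KH = dim4(w, 0), KW = dim4(w, 1), CO = dim4(w, 3);
  const int HO = dim4(dy, 0), WO = dim4(dy, 1);
  NumericVector dx(x.size()); dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size()); dw.attr("dim") = w.attr("dim");
  NumericVector db(CO);
  const arma::mat Wm(const_cast<double*>(w.begin()), KH * KW * C, CO, false);
  arma::mat dWm(dw.begin(), KH * KW * C, CO, false, true);
  arma::vec dbv(db.begin(), CO, false, true);
  arma::mat cols(HO * WO, KH * KW * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, KH, KW, pad, HO, WO, cols);
    const arma::mat dYn(const_cast<double*>(dy.begin()) +
                          (size_t)HO * WO * CO * n, HO * WO, CO, false);
    dWm += cols.t() * dYn;
    dbv += arma::sum(dYn, 0).t();
    arma::mat dcols = dYn * Wm.t();
    col2im(dcols, H, W, C, n, KH, KW, pad, HO, WO, dx.begin());
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
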