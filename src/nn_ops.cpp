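// Low-level numerical kernels for the tiny network stack and image ops.
// Array layout for image batches everywhere: dim = (H, W, C, N), column-major
// (R's native order), so index (h,w,c,n) = h + H*(w + W*(c + C*n)).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>

using namespace Rcpp;

static inline int dim4(const NumericVector& x, int k) {
  IntegerVector d = x.attr("dim");
  return d[k];
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int pad) {
  const int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  const int KH = dim4(w, 0), KW = dim4(w, 1), CO = dim4(w, 3);
  const int HO = H + 2 * pad - KH + 1, WO = W + 2 * pad - KW + 1;
  NumericVector y(HO * WO * CO * N);
  y.attr("dim") = IntegerVector::create(HO, WO, CO, N);
  const double* X = x.begin(); const double* Wt = w.begin();
  double* Y = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < CO; ++co) {
      const double bias = b[co];
      for (int wo = 0; wo < WO; ++wo)
        for (int ho = 0; ho < HO; ++ho) {
          double acc = bias;
          for (int ci = 0; ci < C; ++ci)
            for (int kw = 0; kw < KW; ++kw) {
              const int wx = wo + kw - pad;
              if (wx < 0 || wx >= W) continue;
              for (int kh = 0; kh < KH; ++kh) {
                const int hx = ho + kh - pad;
                if (hx < 0 || hx >= H) continue;
                acc += X[hx + H * (wx + W * (ci + C * n))] *
                       Wt[kh + KH * (kw + KW * (ci + C * co))];
              }
            }
          Y[ho + HO * (wo + WO * (co + CO * n))] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int pad) {
  const int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  const int KH = dim4(w, 0), KW = dim4(w, 1), CO = dim4(w, 3);
  const int HO = dim4(dy, 0), WO = dim4(dy, 1);
  NumericVector dx(x.size()); dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size()); dw.attr("dim") = w.attr("dim");
  NumericVector db(CO);
  const double* X = x.begin(); const double* Wt = w.begin();
  const double* DY = dy.begin();
  double* DX = dx.begin(); double* DW = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < CO; ++co)
      for (int wo = 0; wo < WO; ++wo)
        for (int ho = 0; ho < HO; ++ho) {
          const double g = DY[ho + HO * (wo + WO * (co + CO * n))];
          if (g == 0.0) continue;
          db[co] += g;
          for (int ci = 0; ci < C; ++ci)
            for (int kw = 0; kw < KW; ++kw) {
              const int wx = wo + kw - pad;
              if (wx < 0 || wx >= W) continue;
              for (int kh = 0; kh < KH; ++kh) {
                const int hx = ho + kh - pad;
                if (hx < 0 || hx >= H) continue;
                const int xi = hx + H * (wx + W * (ci + C * n));
                const int wi = kh + KH * (kw + KW * (ci + C * co));
                DX[xi] += g * Wt[wi];
                DW[wi] += g * X[xi];
              }
            }
        }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  const int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  const int HO = H / 2, WO = W / 2;
  NumericVector y(HO * WO * C * N);
  y.attr("dim") = IntegerVector::create(HO, WO, C, N);
  IntegerVector arg(y.size());
  const double* X = x.begin(); double* Y = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < WO; ++wo)
        for (int ho = 0; ho < HO; ++ho) {
          int best = -1; double bv = 0;
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i) {
              const int xi = (2 * ho + i) + H * ((2 * wo + j) + W * (c + C * n));
              if (best < 0 || X[xi] > bv) { best = xi; bv = X[xi]; }
            }
          const int yi = ho + HO * (wo + WO * (c + C * n));
          Y[yi] = bv; arg[yi] = best;
        }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector argmax,
                                    IntegerVector xdim) {
  NumericVector dx(xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (int i = 0; i < dy.size(); ++i) dx[argmax[i]] += dy[i];
  return dx;
}

// 2x2 average pooling, stride 2.
// [[Rcpp::export]]
NumericVector cpp_avgpool2_forward(NumericVector x) {
  const int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  const int HO = H / 2, WO = W / 2;
  NumericVector y(HO * WO * C * N);
  y.attr("dim") = IntegerVector::create(HO, WO, C, N);
  const double* X = x.begin(); double* Y = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < WO; ++wo)
        for (int ho = 0; ho < HO; ++ho) {
          double s = 0;
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i)
              s += X[(2 * ho + i) + H * ((2 * wo + j) + W * (c + C * n))];
          Y[ho + HO * (wo + WO * (c + C * n))] = 0.25 * s;
        }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_backward(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int HO = H / 2, WO = W / 2;
  NumericVector dx(H * W * C * N); dx.attr("dim") = xdim;
  const double* DY = dy.begin(); double* DX = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < WO; ++wo)
        for (int ho = 0; ho < HO; ++ho) {
          const double g = 0.25 * DY[ho + HO * (wo + WO * (c + C * n))];
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i)
              DX[(2 * ho + i) + H * ((2 * wo + j) + W * (c + C * n))] += g;
        }
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x) {
  const int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  const int HO = 2 * H, WO = 2 * W;
  NumericVector y(HO * WO * C * N);
  y.attr("dim") = IntegerVector::create(HO, WO, C, N);
  const double* X = x.begin(); double* Y = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < WO; ++wo)
        for (int ho = 0; ho < HO; ++ho)
          Y[ho + HO * (wo + WO * (c + C * n))] =
            X[(ho / 2) + H * ((wo / 2) + W * (c + C * n))];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int HO = 2 * H, WO = 2 * W;
  NumericVector dx(H * W * C * N); dx.attr("dim") = xdim;
  const double* DY = dy.begin(); double* DX = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < WO; ++wo)
        for (int ho = 0; ho < HO; ++ho)
          DX[(ho / 2) + H * ((wo / 2) + W * (c + C * n))] +=
            DY[ho + HO * (wo + WO * (c + C * n))];
  return dx;
}

// Normalized (zero-mean, unit-variance) cross-correlation of a template over
// an image; returns the correlation map over valid positions
// ((H-th+1) x (W-tw+1)).  Windows with zero variance score 0.
// [[Rcpp::export]]
NumericMatrix cpp_ncc(NumericMatrix image, NumericMatrix templ) {
  const int H = image.nrow(), W = image.ncol();
  const int TH = templ.nrow(), TW = templ.ncol();
  const int HO = H - TH + 1, WO = W - TW + 1;
  const double npix = (double)TH * TW;
  double tmean = 0;
  for (int j = 0; j < TW; ++j)
    for (int i = 0; i < TH; ++i) tmean += templ(i, j);
  tmean /= npix;
  std::vector<double> t0(TH * TW);
  double tss = 0;
  for (int j = 0; j < TW; ++j)
    for (int i = 0; i < TH; ++i) {
      t0[i + TH * j] = templ(i, j) - tmean;
      tss += t0[i + TH * j] * t0[i + TH * j];
    }
  if (tss <= 0) stop("degenerate template: zero variance");
  NumericMatrix out(HO, WO);
  for (int wo = 0; wo < WO; ++wo)
    for (int ho = 0; ho < HO; ++ho) {
      double s = 0, ss = 0, cross = 0;
      for (int j = 0; j < TW; ++j)
        for (int i = 0; i < TH; ++i) {
          const double v = image(ho + i, wo + j);
          s += v; ss += v * v;
          cross += v * t0[i + TH * j];
        }
      const double var = ss - s * s / npix;
      out(ho, wo) = (var > 1e-12) ? cross / std::sqrt(var * tss) : 0.0;
    }
  return out;
}

// 8-connected component labelling of a logical matrix; labels 1..K in
// raster-scan discovery order, 0 elsewhere.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
      }
    }
  return lab;
}
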