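// Conv/pool primitives for the network engine.
// Arrays follow R's column-major layout with dimensions
//   inputs  x : (N, H, W, C)
//   kernels w : (KH, KW, C, F)   -- contiguous (KH*KW*C x F) matrix
//   outputs y : (N, OH, OW, F)
// The convolution is a cross-correlation (no kernel flip), as is
// conventional for neural networks.
//
// Because the batch index N is the fastest-varying dimension, the im2col
// matrix for the WHOLE batch (rows r = n + N*(oh + OH*ow), one column per
// kernel tap q = kh + KH*(kw + KW*c)) can be assembled from contiguous
// N-long block copies, and the GEMM output (R x F) is bit-identical to the
// (N, OH, OW, F) output array's memory, so a single large BLAS call does
// all samples at once with no repacking.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int pad) { return in + 2 * pad - k + 1; }

// Batched im2col: A is (N*OH*OW) x (KH*KW*C), column-major.
static void im2col_batch(const double* x, int N, int H, int W, int C,
                         int KH, int KW, int pad, int OH, int OW,
                         double* A) {
  const size_t R = (size_t)N * OH * OW;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < KW; ++kw)
      for (int kh = 0; kh < KH; ++kh) {
        const size_t q = kh + KH * (kw + (size_t)KW * c);
        double* Acol = A + R * q;
        for (int ow = 0; ow < OW; ++ow) {
          const int iw = ow + kw - pad;
          if (iw < 0 || iw >= W) {
            std::memset(Acol + (size_t)N * OH * ow, 0,
                        sizeof(double) * (size_t)N * OH);
            continue;
          }
          for (int oh = 0; oh < OH; ++oh) {
            const int ih = oh + kh - pad;
            double* dst = Acol + (size_t)N * (oh + (size_t)OH * ow);
            if (ih < 0 || ih >= H) {
              std::memset(dst, 0, sizeof(double) * N);
            } else {
              const double* src =
                x + (size_t)N * (ih + (size_t)H * (iw + (size_t)W * c));
              std::memcpy(dst, src, sizeof(double) * N);
            }
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int KH = wd[0], KW = wd[1], F = wd[3];
  if (wd[2] != C) stop("kernel depth does not match input channels");
  const int OH = out_dim(H, KH, pad), OW = out_dim(W, KW, pad);
  if (OH < 1 || OW < 1) stop("kernel larger than padded input");
  const size_t R = (size_t)N * OH * OW, K = (size_t)KH * KW * C;

  arma::mat A(R, K);
  im2col_batch(x.begin(), N, H, W, C, KH, KW, pad, OH, OW, A.memptr());
  arma::mat Wm(const_cast<double*>(w.begin()), K, F, false, true);

  NumericVector y(R * F);
  y.attr("dim") = IntegerVector::create(N, OH, OW, F);
  arma::mat Y(y.begin(), R, F, false, true);
  Y = A * Wm;
  for (int f = 0; f < F; ++f) Y.col(f) += b[f];
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int KH = wd[0], KW = wd[1], F = wd[3];
  const int OH = out_dim(H, KH, pad), OW = out_dim(W, KW, pad);
  const size_t R = (size_t)N * OH * OW, K = (size_t)KH * KW * C;

  arma::mat A(R, K);
  im2col_batch(x.begin(), N, H, W, C, KH, KW, pad, OH, OW, A.memptr());
  arma::mat Wm(const_cast<double*>(w.begin()), K, F, false, true);
  arma::mat G(const_cast<double*>(gy.begin()), R, F, false, true);

  NumericVector gwv(K * F);
  gwv.attr("dim") = IntegerVector::create(KH, KW, C, F);
  arma::mat GW(gwv.begin(), K, F, false, true);
  GW = A.t() * G;
  NumericVector gbv(F);
  for (int f = 0; f < F; ++f) gbv[f] = arma::accu(G.col(f));

  arma::mat Gc = G * Wm.t();                    // R x K
  NumericVector gx((size_t)N * H * W * C);
  gx.attr("dim") = IntegerVector::create(N, H, W, C);
  double* gxp = gx.begin();
  const double* Gp = Gc.memptr();
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < KW; ++kw)
      for (int kh = 0; kh < KH; ++kh) {
        const size_t q = kh + KH * (kw + (size_t)KW * c);
        const double* Gcol = Gp + R * q;
        for (int ow = 0; ow < OW; ++ow) {
          const int iw = ow + kw - pad;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < OH; ++oh) {
            const int ih = oh + kh - pad;
            if (ih < 0 || ih >= H) continue;
            double* dst =
              gxp + (size_t)N * (ih + (size_t)H * (iw + (size_t)W * c));
            const double* src = Gcol + (size_t)N * (oh + (size_t)OH * ow);
            for (int n = 0; n < N; ++n) dst[n] += src[n];
          }
        }
      }
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// 2x2 max pooling, stride 2, floor output size.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int OH = H / 2, OW = W / 2;
  NumericVector y((size_t)N * OH * OW * C);
  IntegerVector idx((size_t)N * OH * OW * C);   // 0-based index into x
  y.attr("dim") = IntegerVector::create(N, OH, OW, C);
  idx.attr("dim") = IntegerVector::create(N, OH, OW, C);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int c = 0; c < C; ++c)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const size_t oi = (size_t)N * (oh + (size_t)OH * (ow + (size_t)OW * c));
        const size_t b00 = (size_t)N * (2 * oh + (size_t)H * (2 * ow + (size_t)W * c));
        const size_t b10 = b00 + N;                     // (2oh+1, 2ow)
        const size_t b01 = b00 + (size_t)N * H;         // (2oh, 2ow+1)
        const size_t b11 = b01 + N;
        for (int n = 0; n < N; ++n) {
          double best = xp[b00 + n]; size_t bi = b00 + n;
          if (xp[b10 + n] > best) { best = xp[b10 + n]; bi = b10 + n; }
          if (xp[b01 + n] > best) { best = xp[b01 + n]; bi = b01 + n; }
          if (xp[b11 + n] > best) { best = xp[b11 + n]; bi = b11 + n; }
          yp[oi + n] = best; ip[oi + n] = (int)bi;
        }
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector gy,
                              IntegerVector xdim) {
  size_t total = 1;
  for (int i = 0; i < xdim.size(); ++i) total *= (size_t)xdim[i];
  NumericVector gx(total);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}
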