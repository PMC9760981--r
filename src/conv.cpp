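// Convolution and pooling kernels for the segmentation network.
// Tensor layout throughout: H x W x C x N column-major R arrays.
// Convolution is im2col + GEMM; backward returns gradients w.r.t.
// input, weights and bias. Dilation is supported (multi-scale block).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  int eff = (k - 1) * dil + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// Build the patch matrix for one sample.
// x: pointer to H*W*C block. K: (kh*kw*C) x (Ho*Wo), preallocated.
static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int dil,
                       int Ho, int Wo, arma::mat& K, int col0) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          int ij = oj * stride - pad + kj * dil;
          bool jin = (ij >= 0 && ij < W);
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * stride - pad + ki * dil;
            double v = 0.0;
            if (jin && ii >= 0 && ii < H)
              v = x[ii + H * (ij + W * c)];
            K(row, col0 + oi + Ho * oj) = v;
          }
        }
      }
    }
  }
}

// Scatter-add of the patch-matrix gradient back onto the input.
static void col2im_one(const arma::mat& dK, int col0, double* dx,
                       int H, int W, int C, int kh, int kw,
                       int stride, int pad, int dil, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          int ij = oj * stride - pad + kj * dil;
          if (ij < 0 || ij >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * stride - pad + ki * dil;
            if (ii < 0 || ii >= H) continue;
            dx[ii + H * (ij + W * c)] += dK(row, col0 + oi + Ho * oj);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", Cin, C);
  int Ho = out_size(H, kh, stride, pad, dilation);
  int Wo = out_size(W, kw, stride, pad, dilation);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");

  arma::mat K(kh * kw * C, (size_t)Ho * Wo * N);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw,
               stride, pad, dilation, Ho, Wo, K, n * Ho * Wo);

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat Y = Wm.t() * K;            // Cout x (Ho*Wo*N)
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* o = out.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double bb = b[co];
      for (int p = 0; p < Ho * Wo; ++p)
        o[(size_t)p + (size_t)Ho * Wo * (co + (size_t)Cout * n)] =
          Y(co, (size_t)n * Ho * Wo + p) + bb;
    }
  return out;
}

// [[Rcpp::export]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];

  arma::mat K(kh * kw * C, (size_t)Ho * Wo * N);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw,
               stride, pad, dilation, Ho, Wo, K, n * Ho * Wo);

  // dy (Ho,Wo,Cout,N) -> dY_mat Cout x (Ho*Wo*N)
  arma::mat dY(Cout, (size_t)Ho * Wo * N);
  const double* dp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < Ho * Wo; ++p)
        dY(co, (size_t)n * Ho * Wo + p) =
          dp[(size_t)p + (size_t)Ho * Wo * (co + (size_t)Cout * n)];

  arma::mat dWm = dY * K.t();          // Cout x (kh*kw*C)
  NumericVector dw((size_t)kh * kw * C * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < kh * kw * C; ++r)
      dw[(size_t)r + (size_t)kh * kw * C * co] = dWm(co, r);

  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co)
    db[co] = arma::accu(dY.row(co));

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Cout, false, true);
  arma::mat dK = Wm * dY;              // (kh*kw*C) x (Ho*Wo*N)
  NumericVector dx((size_t)H * W * C * N);   // zero-initialized
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    col2im_one(dK, n * Ho * Wo, dx.begin() + (size_t)n * H * W * C,
               H, W, C, kh, kw, stride, pad, dilation, Ho, Wo);

  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 3x3 stride-2 pad-1 style max pooling (parameters general).
// [[Rcpp::export]]
List maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad, 1), Wo = out_size(W, k, stride, pad, 1);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector amax((size_t)Ho * Wo * C * N);   // linear index into x, 0-based
  const double* xp = x.begin();
  double* yp = y.begin();
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int oj = 0; oj < Wo; ++oj)
        for (int oi = 0; oi < Ho; ++oi) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int kj = 0; kj < k; ++kj) {
            int ij = oj * stride - pad + kj;
            if (ij < 0 || ij >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int ii = oi * stride - pad + ki;
              if (ii < 0 || ii >= H) continue;
              size_t idx = base + ii + (size_t)H * ij;
              if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
            }
          }
          // write in (Ho,Wo,C,N) order: oi + Ho*(oj + Wo*(c + C*n))
          q = (size_t)oi + Ho * ((size_t)oj + Wo * (c + (size_t)C * n));
          yp[q] = best;
          amax[q] = (int)bidx;
        }
    }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_backward(NumericVector dy, IntegerVector amax,
                               IntegerVector in_dim) {
  size_t tot = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector dx(tot);
  dx.attr("dim") = in_dim;
  const double* dp = dy.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[amax[i]] += dp[i];
  return dx;
}
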