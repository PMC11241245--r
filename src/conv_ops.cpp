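// Grouped 2-D convolution via im2col + GEMM, with the matching backward pass.
// Tensors are column-major R arrays: x (H, W, C, N), w (k, k, Cin/g, Cout),
// y (Ho, Wo, Cout, N).  Depthwise convolution is groups == Cin.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void im2col_group(const double* x, int H, int W, int C,
                         int k, int stride, int pad,
                         int g, int cin_g, arma::mat& col) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  col.zeros();
  for (int ci = 0; ci < cin_g; ++ci) {
    const double* xc = x + (size_t)(g * cin_g + ci) * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            col(r, ho + Ho * wo) = xc[hi + (size_t)H * wi];
          }
        }
      }
    }
  }
}

static void col2im_group(const arma::mat& col, int H, int W, int C,
                         int k, int stride, int pad,
                         int g, int cin_g, double* dx) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int ci = 0; ci < cin_g; ++ci) {
    double* xc = dx + (size_t)(g * cin_g + ci) * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += col(r, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], cin_g = wd[2], Cout = wd[3];
  const int cout_g = Cout / groups;
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y(Ho * Wo * (size_t)Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  std::vector<arma::mat> Wm(groups);
  for (int g = 0; g < groups; ++g) {
    Wm[g].set_size(cout_g, k * k * cin_g);
    for (int co = 0; co < cout_g; ++co)
      for (int ci = 0; ci < cin_g; ++ci)
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh)
            Wm[g](co, kh + k * kw + k * k * ci) =
              w[kh + (size_t)k * (kw + (size_t)k *
                (ci + (size_t)cin_g * (g * cout_g + co)))];
  }

  arma::mat col(k * k * cin_g, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col_group(xn, H, W, C, k, stride, pad, g, cin_g, col);
      arma::mat yg = Wm[g] * col;  // cout_g x (Ho*Wo)
      for (int co = 0; co < cout_g; ++co) {
        double* dst = yn + (size_t)(g * cout_g + co) * Ho * Wo;
        for (int j = 0; j < Ho * Wo; ++j) dst[j] = yg(co, j);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], cin_g = wd[2], Cout = wd[3];
  const int cout_g = Cout / groups;
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;

  std::vector<arma::mat> Wm(groups), dWm(groups);
  for (int g = 0; g < groups; ++g) {
    Wm[g].set_size(cout_g, k * k * cin_g);
    dWm[g].zeros(cout_g, k * k * cin_g);
    for (int co = 0; co < cout_g; ++co)
      for (int ci = 0; ci < cin_g; ++ci)
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh)
            Wm[g](co, kh + k * kw + k * k * ci) =
              w[kh + (size_t)k * (kw + (size_t)k *
                (ci + (size_t)cin_g * (g * cout_g + co)))];
  }

  arma::mat col(k * k * cin_g, Ho * Wo);
  arma::mat dYg(cout_g, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col_group(xn, H, W, C, k, stride, pad, g, cin_g, col);
      for (int co = 0; co < cout_g; ++co) {
        const double* src = dyn + (size_t)(g * cout_g + co) * Ho * Wo;
        for (int j = 0; j < Ho * Wo; ++j) dYg(co, j) = src[j];
      }
      dWm[g] += dYg * col.t();
      arma::mat dcol = Wm[g].t() * dYg;
      col2im_group(dcol, H, W, C, k, stride, pad, g, cin_g, dxn);
    }
  }
  for (int g = 0; g < groups; ++g)
    for (int co = 0; co < cout_g; ++co)
      for (int ci = 0; ci < cin_g; ++ci)
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh)
            dw[kh + (size_t)k * (kw + (size_t)k *
              (ci + (size_t)cin_g * (g * cout_g + co)))] =
              dWm[g](co, kh + k * kw + k * k * ci);
  return List::create(Named("dx") = dx, Named("dw") = dw);
}
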