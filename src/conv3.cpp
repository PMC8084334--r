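// 3x3 "same" convolution kernels for channel-first batches (C, H, W, B),
// im2col + BLAS gemm. The R level owns the architecture; these routines
// only do the heavy sliding-window algebra.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather the padded 3x3 neighborhoods into IM (9C x HWB), zero-padded.
static void build_im2col(const double* x, int C, int H, int W, int B,
                         arma::mat& IM) {
  const int HW = H * W;
  IM.zeros(9 * C, HW * B);
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (size_t)b * C * HW;
    for (int k = 0; k < 9; ++k) {
      const int di = k / 3 - 1, dj = k % 3 - 1;  // row/col offset
      for (int j = 0; j < W; ++j) {
        const int js = j + dj;
        if (js < 0 || js >= W) continue;
        for (int i = 0; i < H; ++i) {
          const int is = i + di;
          if (is < 0 || is >= H) continue;
          const double* src = xb + ((size_t)js * H + is) * C;
          double* dst = IM.colptr((size_t)b * HW + (size_t)j * H + i) + k * C;
          std::memcpy(dst, src, C * sizeof(double));
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv3_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                   IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int F = b.size();
  arma::mat IM;
  build_im2col(x.begin(), C, H, W, B, IM);
  // weight array (F, C, 3, 3) -> (F x 9C) with column blocks per offset:
  // entry (f, k*C + c) = w[f + F*(c + C*(ki + 3*kj))] with k = 3*ki + kj
  arma::mat Wm(F, 9 * C);
  for (int k = 0; k < 9; ++k) {
    const int ki = k / 3, kj = k % 3;
    for (int c = 0; c < C; ++c)
      for (int f = 0; f < F; ++f)
        Wm(f, k * C + c) = w[f + (size_t)F * (c + (size_t)C * (ki + 3 * kj))];
  }
  arma::mat Y = Wm * IM;
  Y.each_col() += arma::vec(b.begin(), F);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(F, H, W, B);
  // keep the im2col matrix for the backward pass
  return List::create(_["y"] = out,
                      _["im"] = wrap(IM),
                      _["wm"] = wrap(Wm));
}

// [[Rcpp::export]]
List conv3_bwd_cpp(NumericVector dy, NumericMatrix im, NumericMatrix wm,
                   IntegerVector dims, int F) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int n = H * W * B;
  arma::mat dY(dy.begin(), F, n, false);
  arma::mat IM(im.begin(), im.nrow(), im.ncol(), false);
  arma::mat Wm(wm.begin(), wm.nrow(), wm.ncol(), false);
  arma::mat dWm = dY * IM.t();          // (F x 9C)
  arma::vec db = arma::sum(dY, 1);
  arma::mat dIM = Wm.t() * dY;          // (9C x n)
  // col2im scatter-add
  NumericVector dx((size_t)C * n);
  double* dxp = dx.begin();
  const int HW = H * W;
  for (int b = 0; b < B; ++b) {
    double* dxb = dxp + (size_t)b * C * HW;
    for (int k = 0; k < 9; ++k) {
      const int di = k / 3 - 1, dj = k % 3 - 1;
      for (int j = 0; j < W; ++j) {
        const int js = j + dj;
        if (js < 0 || js >= W) continue;
        for (int i = 0; i < H; ++i) {
          const int is = i + di;
          if (is < 0 || is >= H) continue;
          const double* src = dIM.colptr((size_t)b * HW + (size_t)j * H + i) + k * C;
          double* dst = dxb + ((size_t)js * H + is) * C;
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, B);
  // back to (F, C, 3, 3) layout
  NumericVector dW((size_t)F * C * 9);
  for (int k = 0; k < 9; ++k) {
    const int ki = k / 3, kj = k % 3;
    for (int c = 0; c < C; ++c)
      for (int f = 0; f < F; ++f)
        dW[f + (size_t)F * (c + (size_t)C * (ki + 3 * kj))] = dWm(f, k * C + c);
  }
  dW.attr("dim") = IntegerVector::create(F, C, 3, 3);
  return List::create(_["dx"] = dx, _["dW"] = dW,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
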