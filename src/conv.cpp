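#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are column-major arrays with dims (H, W, C).
// im2col unrolls k x k patches at the given stride/padding into a matrix of
// shape (Ho*Wo) x (k*k*C); out-of-bounds (padding) entries are zero.
// Row index = oi + Ho*oj; column index = ki + k*kj + k*k*c.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = ki + k * kj + k * k * c;
        for (int oj = 0; oj < Wo; ++oj) {
          int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            out(oi + Ho * oj, col) = x[i + H * j + H * W * c];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add patch columns back into an (H, W, C) array.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x(H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = ki + k * kj + k * k * c;
        for (int oj = 0; oj < Wo; ++oj) {
          int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            x[i + H * j + H * W * c] += cols(oi + Ho * oj, col);
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}
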