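#include <Rcpp.h>
using namespace Rcpp;

// Tensors are column-major R arrays with dim = c(H, W, C, N).
// im2col lowers a batched 4-D tensor to the patch matrix used by
// GEMM-based convolution: row index runs over (h_out, w_out, n) in
// column-major order, column index over (ki, kj, c) with ki fastest.
// The matching weight layout is a (k*k*Cin) x Cout matrix.

static inline int out_extent(int sz, int k, int stride, int dil, int pad) {
  return (sz + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix nn_im2col(NumericVector x, IntegerVector dims, int k,
                        int stride, int dil, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Hout = out_extent(H, k, stride, dil, pad);
  const int Wout = out_extent(W, k, stride, dil, pad);
  const R_xlen_t M = (R_xlen_t)Hout * Wout * N;
  const int K = k * k * C;
  NumericMatrix out(M, K);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * c);
        double *col = po + (R_xlen_t)q * M;
        for (int n = 0; n < N; ++n) {
          const double *xn = px + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int wo = 0; wo < Wout; ++wo) {
            const int w = wo * stride - pad + kj * dil;
            double *dst = col + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * n);
            if (w < 0 || w >= W) continue;
            const double *src = xn + (R_xlen_t)H * w;
            for (int ho = 0; ho < Hout; ++ho) {
              const int h = ho * stride - pad + ki * dil;
              if (h >= 0 && h < H) dst[ho] = src[h];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of nn_im2col: scatter-adds the patch-matrix gradient back
// onto the input tensor.  cols has the same layout as nn_im2col output.
// [[Rcpp::export]]
NumericVector nn_col2im(NumericMatrix cols, IntegerVector dims, int k,
                        int stride, int dil, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Hout = out_extent(H, k, stride, dil, pad);
  const int Wout = out_extent(W, k, stride, dil, pad);
  const R_xlen_t M = (R_xlen_t)Hout * Wout * N;
  NumericVector out((R_xlen_t)H * W * C * N);
  out.attr("dim") = dims;
  double *po = out.begin();
  const double *pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * c);
        const double *col = pc + (R_xlen_t)q * M;
        for (int n = 0; n < N; ++n) {
          double *xn = po + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int wo = 0; wo < Wout; ++wo) {
            const int w = wo * stride - pad + kj * dil;
            if (w < 0 || w >= W) continue;
            const double *src = col + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * n);
            double *dst = xn + (R_xlen_t)H * w;
            for (int ho = 0; ho < Hout; ++ho) {
              const int h = ho * stride - pad + ki * dil;
              if (h >= 0 && h < H) dst[h] += src[ho];
            }
          }
        }
      }
    }
  }
  return out;
}
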