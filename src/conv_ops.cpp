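// Gather/scatter kernels for the 1-D convolution layers.
//
// Activations are (batch n, length L, channels cin) arrays in column-major
// order (batch fastest). im2col gathers every sliding window into an
// (n*Lout, k*cin) matrix whose columns run kernel-offset fastest, then input
// channel — the layout of a column-major (k, cin, cout) weight array — so a
// convolution is a single GEMM. col2im is its adjoint (scatter-add), used by
// the backward pass.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".im2col_gather")]]
NumericMatrix im2col_gather(const NumericVector& A, const int n, const int L,
                            const int cin, const int k) {
  const int Lout = L - k + 1;
  if (Lout < 1) stop("kernel longer than input");
  if (A.size() != (R_xlen_t)n * L * cin) stop("bad input dimensions");
  NumericMatrix out(n * Lout, k * cin);
  const double* src = A.begin();
  double* dst = out.begin();
  for (int c = 0; c < cin; ++c) {
    for (int a = 0; a < k; ++a) {
      double* col = dst + (R_xlen_t)(c * k + a) * n * Lout;
      const double* plane = src + (R_xlen_t)c * n * L;
      for (int t = 0; t < Lout; ++t) {
        std::copy(plane + (R_xlen_t)(t + a) * n,
                  plane + (R_xlen_t)(t + a + 1) * n,
                  col + (R_xlen_t)t * n);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".col2im_scatter")]]
NumericVector col2im_scatter(const NumericMatrix& dXcol, const int n,
                             const int L, const int cin, const int k) {
  const int Lout = L - k + 1;
  if (dXcol.nrow() != n * Lout || dXcol.ncol() != k * cin) {
    stop("bad column-matrix dimensions");
  }
  NumericVector dA((R_xlen_t)n * L * cin);  // zero-initialized
  const double* src = dXcol.begin();
  double* dst = dA.begin();
  for (int c = 0; c < cin; ++c) {
    for (int a = 0; a < k; ++a) {
      const double* col = src + (R_xlen_t)(c * k + a) * n * Lout;
      double* plane = dst + (R_xlen_t)c * n * L;
      for (int t = 0; t < Lout; ++t) {
        double* d = plane + (R_xlen_t)(t + a) * n;
        const double* s = col + (R_xlen_t)t * n;
        for (int b = 0; b < n; ++b) d[b] += s[b];
      }
    }
  }
  dA.attr("dim") = IntegerVector::create(n, L, cin);
  return dA;
}
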