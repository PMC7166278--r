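// Batch-normalization statistics and ceil-mode max pooling.
//
// Column reductions use long double accumulators, matching base R's
// colMeans/colSums, so these kernels are bit-compatible with the reference
// R expressions they replace.

#include <Rcpp.h>
using namespace Rcpp;

// M: (m x C) responses. Returns xhat, out (= xhat*gamma + beta), sigma.
// [[Rcpp::export(name = ".bn_train_cpp")]]
List bn_train(const NumericMatrix& M, const NumericVector& gamma,
              const NumericVector& beta, const double delta) {
  const int m = M.nrow(), C = M.ncol();
  NumericVector mu(C), v(C), sigma(C);
  NumericMatrix xhat(m, C), out(m, C);
  for (int c = 0; c < C; ++c) {
    const double* col = &M(0, c);
    long double acc = 0.0;
    for (int i = 0; i < m; ++i) acc += col[i];
    const double mu_c = (double)(acc / m);
    long double acc2 = 0.0;
    for (int i = 0; i < m; ++i) {
      const double d = col[i] - mu_c;
      acc2 += d * d;
    }
    const double v_c = (double)(acc2 / m);
    const double sigma_c = std::sqrt(delta + v_c);
    const double inv = 1.0 / sigma_c;
    double* xh = &xhat(0, c);
    double* o = &out(0, c);
    const double g = gamma[c], b = beta[c];
    for (int i = 0; i < m; ++i) {
      const double x = (col[i] - mu_c) * inv;
      xh[i] = x;
      o[i] = x * g + b;
    }
    mu[c] = mu_c; v[c] = v_c; sigma[c] = sigma_c;
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["sigma"] = sigma,
                      _["mu"] = mu, _["v"] = v);
}

// Backward pass: dM (m x C) incoming gradient w.r.t. the BN output.
// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd(const NumericMatrix& dM, const NumericMatrix& xhat,
            const NumericVector& sigma, const NumericVector& gamma) {
  const int m = dM.nrow(), C = dM.ncol();
  NumericVector dgamma(C), dbeta(C);
  NumericMatrix dX(m, C);
  for (int c = 0; c < C; ++c) {
    const double* dm = &dM(0, c);
    const double* xh = &xhat(0, c);
    long double a_dg = 0.0, a_db = 0.0, a_s1 = 0.0, a_s2 = 0.0;
    const double g = gamma[c];
    for (int i = 0; i < m; ++i) {
      a_dg += dm[i] * xh[i];
      a_db += dm[i];
      const double dxh = dm[i] * g;
      a_s1 += dxh;
      a_s2 += dxh * xh[i];
    }
    const double s1m = (double)a_s1 / m;
    const double s2m = (double)a_s2 / m;
    const double inv = 1.0 / sigma[c];
    double* dx = &dX(0, c);
    for (int i = 0; i < m; ++i) {
      dx[i] = (dm[i] * g - s1m - xh[i] * s2m) * inv;
    }
    dgamma[c] = (double)a_dg;
    dbeta[c] = (double)a_db;
  }
  return List::create(_["dA"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Ceil-mode max pooling, size 2 / stride 2, over (n, L, C) arrays; ties and
// the odd right edge route to the first (left) element of the window.
// [[Rcpp::export(name = ".pool2_fwd_cpp")]]
List pool2_fwd(const NumericVector& A, const int n, const int L,
               const int C) {
  const int Lout = (L + 1) / 2;
  const bool odd = (L % 2) != 0;
  NumericVector out((R_xlen_t)n * Lout * C);
  LogicalVector mask1((R_xlen_t)n * Lout * C);
  const double* src = A.begin();
  double* o = out.begin();
  int* msk = LOGICAL(mask1);
  for (int c = 0; c < C; ++c) {
    const double* plane = src + (R_xlen_t)c * n * L;
    double* oc = o + (R_xlen_t)c * n * Lout;
    int* mc = msk + (R_xlen_t)c * n * Lout;
    for (int t = 0; t < Lout; ++t) {
      const double* a1 = plane + (R_xlen_t)(2 * t) * n;
      const bool has2 = !(odd && t == Lout - 1);
      const double* a2 = a1 + n;
      for (int b = 0; b < n; ++b) {
        if (!has2 || a1[b] >= a2[b]) {
          oc[(R_xlen_t)t * n + b] = a1[b];
          mc[(R_xlen_t)t * n + b] = 1;
        } else {
          oc[(R_xlen_t)t * n + b] = a2[b];
          mc[(R_xlen_t)t * n + b] = 0;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n, Lout, C);
  return List::create(_["out"] = out, _["mask1"] = mask1, _["L"] = L);
}

// [[Rcpp::export(name = ".pool2_bwd_cpp")]]
NumericVector pool2_bwd(const NumericVector& dOut, const LogicalVector& mask1,
                        const int n, const int L, const int C) {
  const int Lout = (L + 1) / 2;
  const bool odd = (L % 2) != 0;
  NumericVector dA((R_xlen_t)n * L * C);  // zero-initialized
  const double* g = dOut.begin();
  const int* msk = LOGICAL(mask1);
  double* dst = dA.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = g + (R_xlen_t)c * n * Lout;
    const int* mc = msk + (R_xlen_t)c * n * Lout;
    double* plane = dst + (R_xlen_t)c * n * L;
    for (int t = 0; t < Lout; ++t) {
      double* d1 = plane + (R_xlen_t)(2 * t) * n;
      const bool has2 = !(odd && t == Lout - 1);
      double* d2 = d1 + n;
      for (int b = 0; b < n; ++b) {
        const double gv = gc[(R_xlen_t)t * n + b];
        if (mc[(R_xlen_t)t * n + b]) d1[b] = gv;
        else if (has2) d2[b] = gv;
      }
    }
  }
  dA.attr("dim") = IntegerVector::create(n, L, C);
  return dA;
}
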