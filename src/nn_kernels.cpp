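// Memory-bound inner kernels of the 1-D convolution (im2col gather /
// col2im scatter-add) and batch normalization. The surrounding layer
// logic, shapes and gradients live in R; these loops only move doubles.
#include <Rcpp.h>
using namespace Rcpp;

// Gather frame-major rows into the (N x k*C) patch matrix; idx is 1-based
// with out-of-range taps pointing at the trailing zero row of xa.
// [[Rcpp::export]]
NumericMatrix cpp_gather_patches(const NumericMatrix& x,
                                 const IntegerMatrix& idx) {
  const int N = idx.nrow(), k = idx.ncol(), C = x.ncol();
  const int n_in = x.nrow();  // index n_in + 1 means zero padding
  NumericMatrix P(N, k * C);
  for (int c = 0; c < C; ++c) {
    const double* xcol = &x(0, c);
    for (int j = 0; j < k; ++j) {
      double* pcol = &P(0, c * k + j);
      const int* icol = &idx(0, j);
      for (int i = 0; i < N; ++i) {
        const int r = icol[i] - 1;
        pcol[i] = (r < n_in) ? xcol[r] : 0.0;
      }
    }
  }
  return P;
}

// Transpose of the gather: scatter-add patch gradients back onto input
// rows; taps that pointed at zero padding (index n_rows + 1) are dropped.
// [[Rcpp::export]]
NumericMatrix cpp_scatter_patches(const NumericMatrix& dP,
                                  const IntegerMatrix& idx,
                                  const int n_rows, const int C) {
  const int N = idx.nrow(), k = idx.ncol();
  NumericMatrix dx(n_rows, C);
  for (int c = 0; c < C; ++c) {
    double* dcol = &dx(0, c);
    for (int j = 0; j < k; ++j) {
      const double* pcol = &dP(0, c * k + j);
      const int* icol = &idx(0, j);
      for (int i = 0; i < N; ++i) {
        const int r = icol[i] - 1;
        if (r < n_rows) dcol[r] += pcol[i];
      }
    }
  }
  return dx;
}

// out = (x - mu) * inv_sd * gamma + beta, plus the normalized xhat kept
// for the backward pass; all per-column.
// [[Rcpp::export]]
List cpp_bn_apply(const NumericMatrix& x, const NumericVector& mu,
                  const NumericVector& inv_sd, const NumericVector& gamma,
                  const NumericVector& beta) {
  const int N = x.nrow(), C = x.ncol();
  NumericMatrix xhat(N, C), out(N, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], s = inv_sd[c], g = gamma[c], b = beta[c];
    const double* xc = &x(0, c);
    double* hc = &xhat(0, c);
    double* oc = &out(0, c);
    for (int i = 0; i < N; ++i) {
      const double h = (xc[i] - m) * s;
      hc[i] = h;
      oc[i] = h * g + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}

// dx = (dout - m1 - xhat * m2) * a, per column (training-mode batch-norm
// input gradient; a = gamma * inv_sd, m1/m2 the column means of dout and
// dout*xhat).
// [[Rcpp::export]]
NumericMatrix cpp_bn_dx(const NumericMatrix& dout,
                        const NumericMatrix& xhat,
                        const NumericVector& m1, const NumericVector& m2,
                        const NumericVector& a) {
  const int N = dout.nrow(), C = dout.ncol();
  NumericMatrix dx(N, C);
  for (int c = 0; c < C; ++c) {
    const double mm1 = m1[c], mm2 = m2[c], aa = a[c];
    const double* dc = &dout(0, c);
    const double* hc = &xhat(0, c);
    double* xc = &dx(0, c);
    for (int i = 0; i < N; ++i) xc[i] = (dc[i] - mm1 - hc[i] * mm2) * aa;
  }
  return dx;
}
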