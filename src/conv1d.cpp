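// Batched 1-D convolution via per-sample im2col + GEMM.
//
// Activations are stored as (N*T) x C matrices: sample-major row blocks
// (rows 1..T belong to sample 1). Weights are (k*Cin) x Cout with column
// c*k + j holding tap j (0-based) of input channel c; tap j reads input
// position t + j - padLeft ("same" padding, stride 1).
//
// The im2col patch matrix is built per sample into a reused buffer so it
// stays cache-resident for the GEMMs instead of streaming a batch-sized
// patch matrix through memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2colSample(const mat& X, int base, int T, int k, int padLeft,
                         mat& C) {
  const int Cin = X.n_cols;
  for (int c = 0; c < Cin; ++c) {
    const double* xcol = X.colptr(c) + base;
    for (int j = 0; j < k; ++j) {
      double* ccol = C.colptr(c * k + j);
      const int shift = j - padLeft;
      const int t0 = std::max(0, -shift);
      const int t1 = std::min(T, T - shift);
      for (int t = 0; t < t0; ++t) ccol[t] = 0.0;
      for (int t = t0; t < t1; ++t) ccol[t] = xcol[t + shift];
      for (int t = t1; t < T; ++t) ccol[t] = 0.0;
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv1d_fw(const arma::mat& X, const arma::mat& W,
                        const arma::vec& b, int T, int k, int padLeft) {
  const int Cin = X.n_cols;
  const int NT = X.n_rows;
  const int N = NT / T;
  const int Cout = W.n_cols;
  mat C(T, k * Cin);
  mat Y(NT, Cout);
  for (int n = 0; n < N; ++n) {
    const int base = n * T;
    im2colSample(X, base, T, k, padLeft, C);
    Y.rows(base, base + T - 1) = C * W;
  }
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bw(const arma::mat& X, const arma::mat& W,
                         const arma::mat& dY, int T, int k, int padLeft) {
  const int Cin = X.n_cols;
  const int NT = X.n_rows;
  const int N = NT / T;
  const int Cout = W.n_cols;

  mat C(T, k * Cin);
  mat dW(k * Cin, Cout, fill::zeros);
  mat dC(T, k * Cin);
  mat dX(NT, Cin, fill::zeros);

  for (int n = 0; n < N; ++n) {
    const int base = n * T;
    im2colSample(X, base, T, k, padLeft, C);
    const mat dYn = dY.rows(base, base + T - 1);
    dW += C.t() * dYn;
    dC = dYn * W.t();
    for (int c = 0; c < Cin; ++c) {
      double* dxcol = dX.colptr(c) + base;
      for (int j = 0; j < k; ++j) {
        const double* dccol = dC.colptr(c * k + j);
        const int shift = j - padLeft;
        const int t0 = std::max(0, -shift);
        const int t1 = std::min(T, T - shift);
        for (int t = t0; t < t1; ++t) dxcol[t + shift] += dccol[t];
      }
    }
  }
  vec db = sum(dY, 0).t();
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
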