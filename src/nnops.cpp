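// Fused elementwise/column kernels for the training loop: ELU, batch
// normalization and non-overlapping average pooling on (N*T) x C
// activation matrices (sample-major row blocks).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::mat cpp_elu_fw(const arma::mat& x) {
  mat y = x;
  double* p = y.memptr();
  const uword n = y.n_elem;
  for (uword i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = std::expm1(p[i]);
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_elu_bw(const arma::mat& dy, const arma::mat& y) {
  mat g = dy;
  double* p = g.memptr();
  const double* q = y.memptr();
  const uword n = g.n_elem;
  for (uword i = 0; i < n; ++i)
    if (q[i] < 0) p[i] *= q[i] + 1.0;
  return g;
}

// training-mode batch norm: batch statistics over rows, per column
// [[Rcpp::export]]
Rcpp::List cpp_bn_fw_train(const arma::mat& x, const arma::vec& gamma,
                           const arma::vec& beta, double eps) {
  const uword R = x.n_rows, C = x.n_cols;
  rowvec m = mean(x, 0);
  mat xhat(R, C), y(R, C);
  vec invstd(C), v(C);
  for (uword c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    double acc = 0.0;
    for (uword r = 0; r < R; ++r) {
      const double d = xc[r] - m(c);
      acc += d * d;
    }
    v(c) = acc / R;
    invstd(c) = 1.0 / std::sqrt(v(c) + eps);
    double* xh = xhat.colptr(c);
    double* yc = y.colptr(c);
    const double g = gamma(c), b = beta(c), mu = m(c), is = invstd(c);
    for (uword r = 0; r < R; ++r) {
      xh[r] = (xc[r] - mu) * is;
      yc[r] = g * xh[r] + b;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("mean") = m.t(),
                            Rcpp::Named("var") = v,
                            Rcpp::Named("invstd") = invstd);
}

// evaluation-mode batch norm with running statistics
// [[Rcpp::export]]
arma::mat cpp_bn_fw_eval(const arma::mat& x, const arma::vec& gamma,
                         const arma::vec& beta, const arma::vec& rmean,
                         const arma::vec& rvar, double eps) {
  const uword R = x.n_rows, C = x.n_cols;
  mat y(R, C);
  for (uword c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(rvar(c) + eps);
    const double g = gamma(c) * is;
    const double b = beta(c) - gamma(c) * is * rmean(c);
    const double* xc = x.colptr(c);
    double* yc = y.colptr(c);
    for (uword r = 0; r < R; ++r) yc[r] = g * xc[r] + b;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_bw(const arma::mat& dy, const arma::mat& xhat,
                     const arma::vec& invstd, const arma::vec& gamma) {
  const uword R = dy.n_rows, C = dy.n_cols;
  mat dx(R, C);
  vec dgamma(C), dbeta(C);
  for (uword c = 0; c < C; ++c) {
    const double* dyc = dy.colptr(c);
    const double* xh = xhat.colptr(c);
    double sdy = 0.0, sdyx = 0.0;
    for (uword r = 0; r < R; ++r) {
      sdy += dyc[r];
      sdyx += dyc[r] * xh[r];
    }
    dgamma(c) = sdyx;
    dbeta(c) = sdy;
    const double g = gamma(c), is = invstd(c);
    const double mdy = sdy / R, mdyx = sdyx / R;
    double* dxc = dx.colptr(c);
    for (uword r = 0; r < R; ++r)
      dxc[r] = g * is * (dyc[r] - mdy - xh[r] * mdyx);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// non-overlapping average pooling along time (length = stride = p)
// [[Rcpp::export]]
arma::mat cpp_pool_fw(const arma::mat& x, int T, int p) {
  const int C = x.n_cols;
  const int N = x.n_rows / T;
  const int Tp = T / p;
  mat y(N * Tp, C);
  const double inv = 1.0 / p;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    double* yc = y.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* xb = xc + n * T;
      double* yb = yc + n * Tp;
      for (int t = 0; t < Tp; ++t) {
        double acc = 0.0;
        const double* xs = xb + t * p;
        for (int j = 0; j < p; ++j) acc += xs[j];
        yb[t] = acc * inv;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_pool_bw(const arma::mat& dy, int T, int Tp, int p) {
  const int C = dy.n_cols;
  const int N = dy.n_rows / Tp;
  mat dx(N * T, C, fill::zeros);
  const double inv = 1.0 / p;
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy.colptr(c);
    double* dxc = dx.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* dyb = dyc + n * Tp;
      double* dxb = dxc + n * T;
      for (int t = 0; t < Tp; ++t) {
        const double v = dyb[t] * inv;
        double* xs = dxb + t * p;
        for (int j = 0; j < p; ++j) xs[j] = v;
      }
    }
  }
  return dx;
}
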