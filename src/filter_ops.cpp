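// Direct-form-II-transposed IIR filtering of every column of a matrix.
// Coefficients follow the usual convention: a(0) y[t] = sum_k b(k) x[t-k]
// - sum_k a(k) y[t-k], with a(0) normalized to 1 by the caller's design
// routine. Zero initial conditions; the zero-phase wrapper in R handles
// padding and the backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export(name = ".iir_cols")]]
arma::mat iir_cols(const arma::vec& b, const arma::vec& a, const arma::mat& x) {
  const int nb = b.n_elem, na = a.n_elem, T = x.n_rows, N = x.n_cols;
  const int nz = std::max(nb, na) - 1;
  mat y(T, N);
  std::vector<double> z(nz + 1);
  for (int j = 0; j < N; ++j) {
    std::fill(z.begin(), z.end(), 0.0);
    const double* xc = x.colptr(j);
    double* yc = y.colptr(j);
    for (int t = 0; t < T; ++t) {
      double xt = xc[t];
      double yt = b(0) * xt + z[0];
      for (int k = 1; k <= nz; ++k) {
        double bk = (k < nb) ? b(k) : 0.0;
        double ak = (k < na) ? a(k) : 0.0;
        z[k - 1] = bk * xt - ak * yt + z[k];
      }
      yc[t] = yt;
    }
  }
  return y;
}
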