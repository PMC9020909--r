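#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter applied independently to each
// column of X. Coefficients are normalized by a[0] on the R side.
// `zi` is the steady-state unit-step state vector (lfilter_zi); the
// initial state of each column is zi * x[0], which suppresses the
// slow-pole startup transient of near-DC filters.
// [[Rcpp::export(name = ".iirFilterColsC")]]
NumericMatrix iirFilterCols(NumericVector b, NumericVector a,
                            NumericMatrix X, NumericVector zi) {
  const int n = X.nrow(), m = X.ncol();
  const int nb = b.size(), na = a.size();
  const int ns = std::max(nb, na) - 1;
  NumericMatrix Y(n, m);
  std::vector<double> z(ns);
  for (int j = 0; j < m; ++j) {
    const double x0 = n > 0 ? X(0, j) : 0.0;
    for (int k = 0; k < ns; ++k)
      z[k] = (k < zi.size() ? zi[k] * x0 : 0.0);
    for (int i = 0; i < n; ++i) {
      const double x = X(i, j);
      const double y = (ns > 0 ? z[0] : 0.0) + b[0] * x;
      for (int k = 0; k < ns - 1; ++k)
        z[k] = z[k + 1] + (k + 1 < nb ? b[k + 1] * x : 0.0)
                        - (k + 1 < na ? a[k + 1] * y : 0.0);
      if (ns > 0)
        z[ns - 1] = (ns < nb ? b[ns] * x : 0.0)
                  - (ns < na ? a[ns] * y : 0.0);
      Y(i, j) = y;
    }
  }
  return Y;
}
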