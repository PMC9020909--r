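#include <Rcpp.h>
using namespace Rcpp;

// L2-regularized L1-loss (hinge) linear SVM by dual coordinate descent
// (the liblinear algorithm), deterministic fixed sweep order. The bias
// is the weight of an appended constant feature (augmented
// formulation). Xt is features x samples so each sample is contiguous;
// y is +1/-1.
// [[Rcpp::export(name = ".svmDualCD")]]
List svmDualCD(NumericMatrix Xt, NumericVector y, double C, double tol,
               int maxEpochs) {
  const int p = Xt.nrow(), n = Xt.ncol();
  std::vector<double> w(p, 0.0), alpha(n, 0.0), qii(n);
  const double *X = REAL(Xt);
  for (int i = 0; i < n; ++i) {
    const double *xi = X + (size_t)i * p;
    double s = 0.0;
    for (int k = 0; k < p; ++k) s += xi[k] * xi[k];
    qii[i] = s > 0 ? s : 1.0;
  }
  int epoch = 0;
  for (; epoch < maxEpochs; ++epoch) {
    double pgMax = -1e30, pgMin = 1e30;
    for (int i = 0; i < n; ++i) {
      const double *xi = X + (size_t)i * p;
      double g = 0.0;
      for (int k = 0; k < p; ++k) g += w[k] * xi[k];
      g = y[i] * g - 1.0;
      double pg = g;                    // projected gradient
      if (alpha[i] <= 0.0 && g >= 0.0) pg = 0.0;
      else if (alpha[i] >= C && g <= 0.0) pg = 0.0;
      if (pg > pgMax) pgMax = pg;
      if (pg < pgMin) pgMin = pg;
      if (pg != 0.0) {
        double aOld = alpha[i];
        double aNew = std::min(std::max(aOld - g / qii[i], 0.0), C);
        if (aNew != aOld) {
          const double d = (aNew - aOld) * y[i];
          for (int k = 0; k < p; ++k) w[k] += d * xi[k];
          alpha[i] = aNew;
        }
      }
    }
    if (pgMax - pgMin < tol) { ++epoch; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch);
}
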