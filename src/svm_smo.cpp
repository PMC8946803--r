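#include <Rcpp.h>
using namespace Rcpp;

// Two-variable SMO solver for the weighted hinge-loss linear SVM.
//
// Primal:  min_{w,b} 1/2 ||w||^2 + sum_i Ci_i * max(0, 1 - y_i (w.x_i + b))
// Dual:    min_a 1/2 a'Qa - e'a   s.t. 0 <= a_i <= Ci_i,  sum_i y_i a_i = 0
//          with Q_ij = y_i y_j x_i'x_j.
//
// Working-set selection is the maximal violating pair; updates move along the
// feasible direction (a_i += y_i t, a_j -= y_j t).  Fully deterministic given
// the data (ties resolved toward the lowest index by the scan order).
//
// The bias is recovered from the KKT conditions: for a free support vector
// (0 < a_t < Ci_t), b = y_t - w.x_t; otherwise the midpoint of the final
// violation interval is used.
// [[Rcpp::export(name = ".svm_smo")]]
List svm_smo(const NumericMatrix& X, const IntegerVector& y,
             const NumericVector& Ci, double eps, int max_iter) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> alpha(n, 0.0), G(n, -1.0), w(d, 0.0);
  double gap = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    double Gmax = -R_PosInf, Gmin = R_PosInf;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] == 1) ? (alpha[t] < Ci[t]) : (alpha[t] > 0.0);
      const bool low = (y[t] == 1) ? (alpha[t] > 0.0)   : (alpha[t] < Ci[t]);
      if (up  && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    gap = Gmax - Gmin;
    if (i < 0 || j < 0 || gap < eps) break;

    double Kii = 0.0, Kjj = 0.0, Kij = 0.0;
    for (int k = 0; k < d; ++k) {
      const double xi = X(i, k), xj = X(j, k);
      Kii += xi * xi; Kjj += xj * xj; Kij += xi * xj;
    }
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad < 1e-12) quad = 1e-12;
    double step = gap / quad;
    const double cap_i = (y[i] == 1) ? (Ci[i] - alpha[i]) : alpha[i];
    const double cap_j = (y[j] == 1) ? alpha[j] : (Ci[j] - alpha[j]);
    if (step > cap_i) step = cap_i;
    if (step > cap_j) step = cap_j;
    if (step <= 0.0) break;  // numerically stuck at a bound

    alpha[i] += y[i] * step;
    alpha[j] -= y[j] * step;
    for (int k = 0; k < d; ++k) w[k] += step * (X(i, k) - X(j, k));
    for (int t = 0; t < n; ++t) {
      double dot = 0.0;
      for (int k = 0; k < d; ++k) dot += (X(i, k) - X(j, k)) * X(t, k);
      G[t] += y[t] * step * dot;
    }
  }

  double bsum = 0.0; int nfree = 0;
  double Gmax = -R_PosInf, Gmin = R_PosInf;
  for (int t = 0; t < n; ++t) {
    const double v = -y[t] * G[t];
    const bool up  = (y[t] == 1) ? (alpha[t] < Ci[t]) : (alpha[t] > 0.0);
    const bool low = (y[t] == 1) ? (alpha[t] > 0.0)   : (alpha[t] < Ci[t]);
    if (up  && v > Gmax) Gmax = v;
    if (low && v < Gmin) Gmin = v;
    if (alpha[t] > 1e-12 && alpha[t] < Ci[t] - 1e-12) { bsum += v; ++nfree; }
  }
  double b;
  if (nfree > 0) b = bsum / nfree;
  else if (R_finite(Gmax) && R_finite(Gmin)) b = 0.5 * (Gmax + Gmin);
  else b = 0.0;

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["b"] = b,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = it,
                      _["gap"] = gap,
                      _["converged"] = (gap < eps));
}
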