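#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin SVM dual via sequential minimal optimization with
// maximal-violating-pair working-set selection.
//
// Solves  min_a  0.5 a'Qa - e'a   s.t.  0 <= a_i <= C,  y'a = 0,
// with Q_ij = y_i y_j K_ij. The reported objective is the dual value
// e'a - 0.5 a'Qa (the quantity the MKL wrappers minimize over kernel
// weights). Stops when the maximal KKT violation m(a) - M(a) <= tol.

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double tol,
               int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("K must be square");
  if (y.size() != n) stop("y length must match K");

  std::vector<double> a(n, 0.0), G(n, -1.0); // G_i = (Qa)_i - 1
  int iter = 0;
  double gap = R_PosInf;

  while (iter < max_iter) {
    // working set: i = argmax_{I_up} -y_t G_t, j = argmin_{I_low} -y_t G_t
    int i = -1, j = -1;
    double gmax = -R_PosInf, gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0) ? (a[t] < C) : (a[t] > 0);
      const bool low = (y[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    gap = gmax - gmin;
    if (i < 0 || j < 0 || gap <= tol) break;

    // analytic two-variable step: a_i += y_i d, a_j -= y_j d, d >= 0
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 1e-12) quad = 1e-12;
    double d = gap / quad;
    d = std::min(d, (y[i] > 0) ? (C - a[i]) : a[i]);
    d = std::min(d, (y[j] > 0) ? a[j] : (C - a[j]));
    if (d <= 0) break; // numerically stuck at the box

    a[i] += y[i] * d;
    a[j] -= y[j] * d;
    for (int t = 0; t < n; ++t) G[t] += y[t] * d * (K(t, i) - K(t, j));
    ++iter;
  }

  for (int t = 0; t < n; ++t) a[t] = std::min(std::max(a[t], 0.0), C);

  // bias: average -y_t G_t over free vectors, else KKT interval midpoint
  double bsum = 0.0; int nfree = 0;
  double up = -R_PosInf, lo = R_PosInf;
  for (int t = 0; t < n; ++t) {
    const double v = -y[t] * G[t];
    if (a[t] > 1e-8 && a[t] < C - 1e-8) { bsum += v; ++nfree; }
    const bool isup  = (y[t] > 0) ? (a[t] < C) : (a[t] > 0);
    const bool islow = (y[t] > 0) ? (a[t] > 0) : (a[t] < C);
    if (isup && v > up) up = v;
    if (islow && v < lo) lo = v;
  }
  const double b = nfree > 0 ? bsum / nfree : (up + lo) / 2.0;

  // dual objective e'a - 0.5 a'Qa, using a'Qa = sum_t a_t (G_t + 1)
  double suma = 0.0, aQa = 0.0;
  for (int t = 0; t < n; ++t) { suma += a[t]; aQa += a[t] * (G[t] + 1.0); }

  return List::create(_["alpha"] = NumericVector(a.begin(), a.end()),
                      _["b"] = b,
                      _["objective"] = suma - 0.5 * aQa,
                      _["iterations"] = iter,
                      _["gap"] = gap,
                      _["converged"] = gap <= tol);
}
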