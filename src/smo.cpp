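#include <Rcpp.h>
using namespace Rcpp;

// SMO dual solver for the soft-margin linear SVM:
//   min 0.5 a'Qa - 1'a   s.t. 0 <= a_i <= C, sum(y_i a_i) = 0,
// with Q_ij = y_i y_j <x_i, x_j>. Maximal-violating-pair working-set
// selection; returns the dual variables and the final KKT gap.
// [[Rcpp::export]]
List cpp_smo_solve(NumericMatrix Q, NumericVector y, double C, double tol,
                   int max_iter) {
  const int n = Q.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  double gap = R_PosInf;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    double m_up = -R_PosInf, m_lo = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double yg = -y[t] * G[t];
      const bool in_up = (y[t] > 0 && alpha[t] < C - 1e-15) ||
                         (y[t] < 0 && alpha[t] > 1e-15);
      const bool in_lo = (y[t] < 0 && alpha[t] < C - 1e-15) ||
                         (y[t] > 0 && alpha[t] > 1e-15);
      if (in_up && yg > m_up) { m_up = yg; i = t; }
      if (in_lo && yg < m_lo) { m_lo = yg; j = t; }
    }
    gap = m_up - m_lo;
    if (i < 0 || j < 0 || gap < tol) break;

    double quad = Q(i, i) + Q(j, j) - 2.0 * y[i] * y[j] * Q(i, j);
    if (quad <= 1e-12) quad = 1e-12;
    double t_step = gap / quad;
    double t_max = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    const double t_max_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    if (t_max_j < t_max) t_max = t_max_j;
    if (t_step > t_max) t_step = t_max;
    if (t_step <= 0) break;

    alpha[i] += y[i] * t_step;
    alpha[j] -= y[j] * t_step;
    for (int t = 0; t < n; ++t)
      G[t] += t_step * (y[i] * Q(t, i) - y[j] * Q(t, j));
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter, _["gap"] = gap);
}
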