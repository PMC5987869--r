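#include <Rcpp.h>
using namespace Rcpp;

// Linear soft-margin C-SVC solved in the dual by sequential minimal
// optimisation (maximal-violating-pair working-set selection, the classic
// first-order SMO scheme).  Training sets in leave-pair-out cross-validation
// are tiny (tens of subjects), so a dense kernel matrix is cheap; the point
// of doing this in C++ is the call overhead: the permutation suites need on
// the order of 1e6 fits.
//
// Dual problem: min 0.5 a'Qa - e'a, 0 <= a_i <= C, y'a = 0,
// with Q_ij = y_i y_j K_ij and K the linear kernel X X'.
// Decision function: f(x) = w.x - rho, w = sum_i a_i y_i x_i.

// [[Rcpp::export(name = ".svm_linear_cpp")]]
List svm_linear_cpp(NumericMatrix X, NumericVector y, double C,
                    double eps = 1e-8, int max_iter = 100000) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");

  // linear kernel matrix
  std::vector<double> K(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += X(i, k) * X(j, k);
      K[i + static_cast<size_t>(n) * j] = s;
      K[j + static_cast<size_t>(n) * i] = s;
    }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double TAU = 1e-12;
  int iter = 0;
  double m_up = 0.0, m_low = 0.0;

  for (iter = 0; iter < max_iter; ++iter) {
    // maximal violating pair
    int i = -1, j = -1;
    m_up = -std::numeric_limits<double>::infinity();
    m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double yG = -y[t] * G[t];
      const bool in_up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool in_low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (in_up && yG > m_up) { m_up = yG; i = t; }
      if (in_low && yG < m_low) { m_low = yG; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;

    double quad = K[i + static_cast<size_t>(n) * i] +
                  K[j + static_cast<size_t>(n) * j] -
                  2.0 * K[i + static_cast<size_t>(n) * j];
    if (quad <= 0) quad = TAU;
    const double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }

    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K[t + static_cast<size_t>(n) * i] * dai +
                      y[j] * K[t + static_cast<size_t>(n) * j] * daj);
  }

  // rho from free support vectors (KKT: rho = y_t G_t when 0 < a_t < C)
  double rho = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > TAU && alpha[t] < C - TAU) { rho += y[t] * G[t]; ++nfree; }
  if (nfree > 0) rho /= nfree;
  else rho = -(m_up + m_low) / 2.0;

  NumericVector w(p);
  for (int t = 0; t < n; ++t) {
    const double c = alpha[t] * y[t];
    if (c != 0.0) for (int k = 0; k < p; ++k) w[k] += c * X(t, k);
  }

  return List::create(_["w"] = w, _["rho"] = rho,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter);
}
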