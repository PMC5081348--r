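#include <Rcpp.h>
using namespace Rcpp;

// Deterministic SMO solver for the C-SVC dual:
//   min 1/2 sum_ij a_i a_j y_i y_j K_ij - sum_i a_i
//   s.t. 0 <= a_i <= C,  sum_i a_i y_i = 0
// Working-set selection: maximal violating pair (lowest index wins ties),
// so the solution path is fully deterministic given the inputs.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double C, double tol,
               int max_passes) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), u(n, 0.0); // u_i = sum_j a_j y_j K_ij
  long long iter = 0;
  const long long iter_cap = (long long)max_passes * n;
  double m_up = 0.0, m_low = 0.0;
  bool converged = false;

  while (iter < iter_cap) {
    // first index: maximal violation over I_up; second index: the I_low
    // member with the largest second-order gain (LIBSVM WSS2), ties and
    // scan order fixed by index, so selection is deterministic
    int i = -1, j = -1, j_mvp = -1;
    m_up = -1e300;
    m_low = 1e300;
    for (int t = 0; t < n; ++t) {
      const double negE = y[t] - u[t];
      const bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      const bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (up && negE > m_up) { m_up = negE; i = t; }
      if (low && negE < m_low) { m_low = negE; j_mvp = t; }
    }
    if (i < 0 || j_mvp < 0 || m_up - m_low < tol) { converged = true; break; }
    double best_gain = -1.0;
    for (int t = 0; t < n; ++t) {
      const bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (!low) continue;
      const double diff = m_up - (y[t] - u[t]);
      if (diff <= 0) continue;
      double a = K(i, i) + K(t, t) - 2.0 * K(i, t);
      if (a < 1e-12) a = 1e-12;
      const double gain = diff * diff / a;
      if (gain > best_gain) { best_gain = gain; j = t; }
    }
    if (j < 0) j = j_mvp;

    const double s = (double)y[i] * (double)y[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    const double Ei = u[i] - y[i], Ej = u[j] - y[j];
    double aj_new = alpha[j] + y[j] * (Ei - Ej) / eta;
    if (aj_new > H) aj_new = H;
    if (aj_new < L) aj_new = L;
    double ai_new = alpha[i] + s * (alpha[j] - aj_new);
    double dai = ai_new - alpha[i], daj = aj_new - alpha[j];
    if (std::fabs(dai) < 1e-15 && std::fabs(daj) < 1e-15 && j != j_mvp) {
      // second-order pick pinned by the pair constraint: retry with the
      // maximal-violating partner, which always allows progress
      j = j_mvp;
      const double s2 = (double)y[i] * (double)y[j];
      if (y[i] != y[j]) {
        L = std::max(0.0, alpha[j] - alpha[i]);
        H = std::min(C, C + alpha[j] - alpha[i]);
      } else {
        L = std::max(0.0, alpha[i] + alpha[j] - C);
        H = std::min(C, alpha[i] + alpha[j]);
      }
      eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (eta < 1e-12) eta = 1e-12;
      const double Ej2 = u[j] - y[j];
      aj_new = alpha[j] + y[j] * (Ei - Ej2) / eta;
      if (aj_new > H) aj_new = H;
      if (aj_new < L) aj_new = L;
      ai_new = alpha[i] + s2 * (alpha[j] - aj_new);
      dai = ai_new - alpha[i];
      daj = aj_new - alpha[j];
    }
    if (std::fabs(dai) < 1e-15 && std::fabs(daj) < 1e-15) {
      // numerically stuck on this pair; accept current point
      converged = true;
      break;
    }
    // snap to the box bounds so rounding never leaves an alpha marginally
    // inside a bound (which would be re-selected with zero-size steps)
    const double snap = 1e-12 * C;
    if (ai_new > C - snap) ai_new = C; else if (ai_new < snap) ai_new = 0.0;
    if (aj_new > C - snap) aj_new = C; else if (aj_new < snap) aj_new = 0.0;
    const double dai2 = ai_new - alpha[i], daj2 = aj_new - alpha[j];
    for (int t = 0; t < n; ++t)
      u[t] += dai2 * y[i] * K(i, t) + daj2 * y[j] * K(j, t);
    alpha[i] = ai_new;
    alpha[j] = aj_new;
    ++iter;
  }

  // bias: average -E over free support vectors; fallback to midpoint bound
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-9 && alpha[t] < C - 1e-9) {
      b += y[t] - u[t];
      ++nfree;
    }
  }
  if (nfree > 0) b /= nfree;
  else b = 0.5 * (m_up + m_low);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b,
                      _["u"] = NumericVector(u.begin(), u.end()),
                      _["iterations"] = (double)iter,
                      _["converged"] = converged);
}
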