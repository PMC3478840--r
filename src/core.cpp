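#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Direct-form II transposed IIR filter. a[0] must be 1 (caller normalizes).
// steady_init: start from the steady-state internal state for a constant
// input equal to x[0], so a constant signal passes with zero transient.
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a, NumericVector x,
                             bool steady_init) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nw = std::max(nb, na) - 1;
  std::vector<double> w(nw, 0.0);
  if (steady_init && n > 0 && nw > 0) {
    double bsum = 0.0, asum = 0.0;
    for (int k = 0; k < nb; k++) bsum += b[k];
    for (int k = 0; k < na; k++) asum += a[k];
    double x0 = x[0], y0 = x0 * bsum / asum;
    for (int k = nw - 1; k >= 0; k--) {
      double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
      double ak = (k + 1 < na) ? a[k + 1] : 0.0;
      double next = (k + 1 < nw) ? w[k + 1] : 0.0;
      w[k] = bk * x0 - ak * y0 + next;
    }
  }
  NumericVector y(n);
  for (int i = 0; i < n; i++) {
    double xi = x[i];
    double yi = b[0] * xi + (nw > 0 ? w[0] : 0.0);
    for (int k = 0; k < nw; k++) {
      double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
      double ak = (k + 1 < na) ? a[k + 1] : 0.0;
      double next = (k + 1 < nw) ? w[k + 1] : 0.0;
      w[k] = bk * xi - ak * yi + next;
    }
    y[i] = yi;
  }
  return y;
}

// Causal sliding-window (max - min) per sample over a window of `w` samples
// ending at the current sample; partial windows at the start.
// Monotonic-deque O(n); tests compare against a brute-force oracle.
// [[Rcpp::export]]
NumericVector cpp_sliding_range(NumericVector x, int w) {
  int n = x.size();
  NumericVector out(n);
  std::deque<int> qmax, qmin;
  for (int i = 0; i < n; i++) {
    while (!qmax.empty() && x[qmax.back()] <= x[i]) qmax.pop_back();
    qmax.push_back(i);
    while (!qmin.empty() && x[qmin.back()] >= x[i]) qmin.pop_back();
    qmin.push_back(i);
    int lo = i - w + 1;
    while (qmax.front() < lo) qmax.pop_front();
    while (qmin.front() < lo) qmin.pop_front();
    out[i] = x[qmax.front()] - x[qmin.front()];
  }
  return out;
}

// RBF decision scores: score_r = sum_j coef_j * exp(-gamma * ||sv_j - X_r||^2) + bias
// coef_j = D_j * alpha_j.
// [[Rcpp::export]]
NumericVector cpp_rbf_scores(NumericMatrix sv, NumericVector coef, double bias,
                             double gamma, NumericMatrix X) {
  int k = sv.nrow(), n = sv.ncol(), m = X.nrow();
  NumericVector out(m);
  for (int r = 0; r < m; r++) {
    double acc = bias;
    for (int j = 0; j < k; j++) {
      double d2 = 0.0;
      for (int c = 0; c < n; c++) {
        double d = sv(j, c) - X(r, c);
        d2 += d * d;
      }
      acc += coef[j] * std::exp(-gamma * d2);
    }
    out[r] = acc;
  }
  return out;
}

// SMO solver for the C-SVC dual with RBF kernel (linear slacks),
// maximal-violating-pair working set selection.
//   min 0.5 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,  Q_ij = y_i y_j K_ij.
// Precomputes the full kernel matrix; caller keeps m modest.
// [[Rcpp::export]]
List cpp_svm_smo(NumericMatrix X, NumericVector y, double C, double gamma,
                 double tol, int max_iter) {
  int m = X.nrow(), n = X.ncol();
  // kernel matrix
  std::vector<double> K((size_t)m * m);
  for (int i = 0; i < m; i++) {
    K[(size_t)i * m + i] = 1.0;
    for (int j = i + 1; j < m; j++) {
      double d2 = 0.0;
      for (int c = 0; c < n; c++) {
        double d = X(i, c) - X(j, c);
        d2 += d * d;
      }
      double v = std::exp(-gamma * d2);
      K[(size_t)i * m + j] = v;
      K[(size_t)j * m + i] = v;
    }
  }
  std::vector<double> alpha(m, 0.0), G(m, -1.0); // G = Q a - e
  int iter = 0;
  bool converged = false;
  while (iter < max_iter) {
    // i: argmax -y_t G_t over I_up; j: argmin -y_t G_t over I_low
    int ii = -1, jj = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int t = 0; t < m; t++) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && v > gmax) { gmax = v; ii = t; }
      if (low && v < gmin) { gmin = v; jj = t; }
    }
    if (ii < 0 || jj < 0 || gmax - gmin < tol) { converged = true; break; }
    const double *Ki = &K[(size_t)ii * m], *Kj = &K[(size_t)jj * m];
    double ai = alpha[ii], aj = alpha[jj];
    double eta = Ki[ii] + Kj[jj] - 2.0 * Ki[jj];
    if (eta < 1e-12) eta = 1e-12;
    // E_t (bias-free residual) = y_t G_t; Platt update on pair (ii, jj)
    double Ei = y[ii] * G[ii], Ej = y[jj] * G[jj];
    double aj_new = aj + y[jj] * (Ei - Ej) / eta;
    double L, H;
    if (y[ii] != y[jj]) { L = std::max(0.0, aj - ai); H = std::min(C, C + aj - ai); }
    else                { L = std::max(0.0, ai + aj - C); H = std::min(C, ai + aj); }
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = ai + y[ii] * y[jj] * (aj - aj_new);
    // snap numerical dust to the exact box bounds so stale near-zero /
    // near-C multipliers cannot re-enter the working set and stall it
    if (ai_new < 1e-12) ai_new = 0.0;
    if (ai_new > C - 1e-12) ai_new = C;
    if (aj_new < 1e-12) aj_new = 0.0;
    if (aj_new > C - 1e-12) aj_new = C;
    double dai = ai_new - ai, daj = aj_new - aj;
    if (std::fabs(dai) < 1e-15 && std::fabs(daj) < 1e-15) break;
    alpha[ii] = ai_new;
    alpha[jj] = aj_new;
    for (int t = 0; t < m; t++)
      G[t] += y[t] * (y[ii] * Ki[t] * dai + y[jj] * Kj[t] * daj);
    iter++;
  }
  // bias from free SVs, else midpoint of the violating-pair bounds
  double bsum = 0.0; int bfree = 0;
  double ub = 1e300, lb = -1e300;
  for (int t = 0; t < m; t++) {
    double v = -y[t] * G[t];
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (alpha[t] > 0.0 && alpha[t] < C) { bsum += v; bfree++; }
    if (up) lb = std::max(lb, v);
    if (low) ub = std::min(ub, v);
  }
  double b = bfree > 0 ? bsum / bfree : (ub + lb) / 2.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["bias"] = b, _["iterations"] = iter,
                      _["converged"] = converged);
}
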