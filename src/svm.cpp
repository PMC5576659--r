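// C-SVC dual solver (SMO with maximal-violating-pair working-set selection)
// and RBF kernel evaluation.  Follows the standard libsvm formulation:
//   min_a  1/2 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,  Q_ij = y_i y_j K_ij
// with stopping rule m(a) - M(a) < eps on the violating pair.  The kernel
// matrix is precomputed by the caller (problem sizes here are a few
// thousand), so no caching/shrinking machinery is needed.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix rbf_kernel_cpp(NumericMatrix X, NumericMatrix Y, double gamma) {
  const int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  if (Y.ncol() != d) stop("dimension mismatch in kernel evaluation");
  NumericMatrix K(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = X(i, k) - Y(j, k);
        s += diff * diff;
      }
      K(i, j) = std::exp(-gamma * s);
    }
  }
  return K;
}

// [[Rcpp::export]]
List smo_train_cpp(NumericMatrix K, IntegerVector y, double C, double eps,
                   int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("bad kernel/label dimensions");
  const double TAU = 1e-12;
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working set: i = argmax_{t in I_up} -y_t G_t, j = argmin_{t in I_low}
    int i = -1, j = -1;
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool lo = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      const double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (lo && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    const double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    const double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = Kii + Kjj + 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break;  // numerically stuck
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
  }

  // rho: average of y_t G_t over free support vectors, else bound midpoint
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double sum_free = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 0) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++nfree;
      sum_free += yG;
    }
  }
  const double rho = (nfree > 0) ? sum_free / nfree : (ub + lb) / 2.0;

  // dual objective, for diagnostics: 1/2 a'Qa - e'a = 1/2 sum a_t (G_t - 1)
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (G[t] - 1.0);
  obj /= 2.0;

  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["rho"] = rho, _["iterations"] = iter, _["objective"] = obj
  );
}
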