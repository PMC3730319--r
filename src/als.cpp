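// Asymmetric-least-squares baseline estimation.
//
// Solves (W + lambda * D'D) z = W y iteratively, where D is the second
// difference operator and W holds asymmetric weights (p above the baseline,
// 1 - p below). The system matrix is symmetric pentadiagonal, so each solve
// is a banded LDL^T factorization in O(n).

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".als_baseline")]]
NumericVector als_baseline(NumericVector y, double lambda, double p,
                           int maxit) {
  const int n = y.size();
  if (n < 3) stop("need at least 3 points");

  // bands of lambda * D'D (d0 diagonal, d1 first, d2 second off-diagonal)
  std::vector<double> pd0(n, 0.0), pd1(n - 1, 0.0), pd2(n - 2, 0.0);
  for (int k = 0; k + 2 < n; ++k) {
    // row of D: +1 at k, -2 at k+1, +1 at k+2
    pd0[k] += lambda;   pd0[k + 1] += 4.0 * lambda; pd0[k + 2] += lambda;
    pd1[k] += -2.0 * lambda; pd1[k + 1] += -2.0 * lambda;
    pd2[k] += lambda;
  }

  std::vector<double> w(n, 1.0), z(n, 0.0);
  std::vector<double> d0(n), d1(n - 1), d2(n - 2);
  std::vector<double> l1(n - 1), l2(n - 2), diag(n), rhs(n);

  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < n; ++i) d0[i] = pd0[i] + w[i];
    for (int i = 0; i + 1 < n; ++i) d1[i] = pd1[i];
    for (int i = 0; i + 2 < n; ++i) d2[i] = pd2[i];

    // banded LDL^T, bandwidth 2: A = L D L^T
    for (int i = 0; i < n; ++i) {
      double di = d0[i];
      if (i >= 1) di -= l1[i - 1] * l1[i - 1] * diag[i - 1];
      if (i >= 2) di -= l2[i - 2] * l2[i - 2] * diag[i - 2];
      diag[i] = di;
      if (i + 1 < n) {
        double v = d1[i];
        if (i >= 1) v -= l1[i - 1] * l2[i - 1] * diag[i - 1];
        l1[i] = v / diag[i];
      }
      if (i + 2 < n) l2[i] = d2[i] / diag[i];
    }

    // forward solve L u = W y, then D, then L^T
    for (int i = 0; i < n; ++i) {
      double v = w[i] * y[i];
      if (i >= 1) v -= l1[i - 1] * rhs[i - 1];
      if (i >= 2) v -= l2[i - 2] * rhs[i - 2];
      rhs[i] = v;
    }
    for (int i = 0; i < n; ++i) rhs[i] /= diag[i];
    for (int i = n - 1; i >= 0; --i) {
      double v = rhs[i];
      if (i + 1 < n) v -= l1[i] * rhs[i + 1];
      if (i + 2 < n) v -= l2[i] * rhs[i + 2];
      rhs[i] = v;
    }

    bool changed = false;
    for (int i = 0; i < n; ++i) {
      z[i] = rhs[i];
      double wi = (y[i] > z[i]) ? p : (1.0 - p);
      if (wi != w[i]) { w[i] = wi; changed = true; }
    }
    if (!changed) break;
  }
  return NumericVector(z.begin(), z.end());
}
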