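// Epsilon-insensitive support vector regression, solved in the dual by an
// SMO-style maximal-violating-pair working-set method over a precomputed
// kernel matrix.
//
// Dual (minimization form) over z = [alpha; alpha*] in [0, C]^{2n} with
// sum(alpha) - sum(alpha*) = 0:
//   f(z) = 1/2 (a - a*)' K (a - a*) + eps * sum(a + a*) - y' (a - a*)
// The fitted coefficients are beta = alpha - alpha*, and the predictor is
// f(x) = sum_i beta_i K(x_i, x) + b.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List svr_smo_cpp(NumericMatrix K, NumericVector y, double C, double eps,
                 double tol = 1e-4, int max_iter = 2000000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("K must be n x n and match y");
  const int m = 2 * n;
  std::vector<double> z(m, 0.0), G(m);
  // q[s]: +1 for alpha block, -1 for alpha* block
  for (int s = 0; s < n; ++s) G[s] = eps - y[s];
  for (int s = 0; s < n; ++s) G[n + s] = eps + y[s];

  auto qs = [n](int s) { return s < n ? 1.0 : -1.0; };
  int iter = 0;
  double gap = 0.0;

  for (; iter < max_iter; ++iter) {
    // i: movable in +direction (z_i moves by +q_i), minimizing q_s G_s
    // j: movable in -direction, maximizing q_s G_s
    int i = -1, j = -1;
    double gi = R_PosInf, gj = R_NegInf;
    for (int s = 0; s < m; ++s) {
      const double q = qs(s);
      const double qg = q * G[s];
      const bool up = (q > 0.0) ? (z[s] < C) : (z[s] > 0.0);
      const bool dn = (q > 0.0) ? (z[s] > 0.0) : (z[s] < C);
      if (up && qg < gi) { gi = qg; i = s; }
      if (dn && qg > gj) { gj = qg; j = s; }
    }
    gap = gj - gi;
    if (i < 0 || j < 0 || gap < tol) break;

    const int in = i % n, jn = j % n;
    const double qi = qs(i), qj = qs(j);
    const double a2 = K(in, in) + K(jn, jn) - 2.0 * K(in, jn);
    // box limits for step delta >= 0 along d = (+q_i at i, -q_j at j)
    double dmax = R_PosInf;
    dmax = std::min(dmax, qi > 0.0 ? C - z[i] : z[i]);
    dmax = std::min(dmax, qj > 0.0 ? z[j] : C - z[j]);
    double delta = (a2 > 1e-12) ? (gap / a2) : dmax;
    if (delta > dmax) delta = dmax;
    if (!(delta > 0.0)) break; // numerically stuck

    z[i] += qi * delta;
    z[j] -= qj * delta;
    // G[s] += delta * q_s * (K[s%n, in] - K[s%n, jn])
    const double *ki = &K(0, in), *kj = &K(0, jn);
    for (int s = 0; s < n; ++s) {
      const double dk = delta * (ki[s] - kj[s]);
      G[s] += dk;
      G[n + s] -= dk;
    }
  }

  NumericVector beta(n);
  for (int s = 0; s < n; ++s) beta[s] = z[s] - z[n + s];

  // bias from free variables: b = -q_s G_s on any 0 < z_s < C; fall back to
  // the midpoint of the KKT interval when no variable is strictly inside.
  double bsum = 0.0; int bcount = 0;
  double lo = R_NegInf, hi = R_PosInf;
  for (int s = 0; s < m; ++s) {
    const double q = qs(s);
    const double v = -q * G[s];
    if (z[s] > 1e-12 && z[s] < C - 1e-12) { bsum += v; ++bcount; }
    const bool up = (q > 0.0) ? (z[s] < C) : (z[s] > 0.0);
    const bool dn = (q > 0.0) ? (z[s] > 0.0) : (z[s] < C);
    if (up && v > lo) lo = v;
    if (dn && v < hi) hi = v;
  }
  const double b = bcount > 0 ? bsum / bcount
                              : (std::isfinite(lo) && std::isfinite(hi) ? 0.5 * (lo + hi) : 0.0);

  // dual objective value (minimization form)
  double quad = 0.0, lin = 0.0;
  for (int s = 0; s < n; ++s) {
    lin += eps * (z[s] + z[n + s]) - y[s] * beta[s];
    double ks = 0.0;
    const double *col = &K(0, s);
    for (int t = 0; t < n; ++t) ks += col[t] * beta[t];
    quad += beta[s] * ks;
  }
  return List::create(_["beta"] = beta, _["b"] = b,
                      _["objective"] = 0.5 * quad + lin,
                      _["iterations"] = iter, _["gap"] = gap,
                      _["converged"] = gap < tol);
}
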