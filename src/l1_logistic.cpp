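#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// L1-penalized logistic regression: minimize
//   (1/n) * sum_i log(1 + exp(-m_i)) + lambda * ||beta||_1,  m_i = y*_i eta_i
// with unpenalized intercept, by FISTA (accelerated proximal gradient).
// Returns c(b0, beta). y is 0/1.
// [[Rcpp::export]]
NumericVector cpp_l1_logistic(NumericMatrix X, NumericVector y, double lambda,
                              bool intercept, double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol();
  // Lipschitz bound: 0.25/n * lambda_max([1 X]'[1 X]) via power iteration
  std::vector<double> v(p + 1, 1.0), Av(n), w(p + 1);
  for (int it = 0; it < 40; ++it) {
    for (int i = 0; i < n; ++i) {
      double s = v[0];
      for (int j = 0; j < p; ++j) s += X(i, j) * v[j + 1];
      Av[i] = s;
    }
    double nrm = 0.0;
    w[0] = 0.0;
    for (int i = 0; i < n; ++i) w[0] += Av[i];
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += X(i, j) * Av[i];
      w[j + 1] = s;
    }
    for (int j = 0; j <= p; ++j) nrm += w[j] * w[j];
    nrm = std::sqrt(nrm);
    if (nrm < 1e-12) break;
    for (int j = 0; j <= p; ++j) v[j] = w[j] / nrm;
  }
  double vAv = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = v[0];
    for (int j = 0; j < p; ++j) s += X(i, j) * v[j + 1];
    vAv += s * s;
  }
  double L = 0.25 / n * vAv + 1e-10;
  double step = 1.0 / L;

  std::vector<double> b(p, 0.0), zb(p, 0.0), nb(p, 0.0), g(p, 0.0), pr(n);
  double b0 = 0.0, zb0 = 0.0, nb0 = 0.0, tk = 1.0;
  double thr = step * lambda;
  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < n; ++i) {
      double eta = zb0;
      for (int j = 0; j < p; ++j) eta += X(i, j) * zb[j];
      pr[i] = 1.0 / (1.0 + std::exp(-eta)) - y[i];
    }
    double g0 = 0.0;
    for (int i = 0; i < n; ++i) g0 += pr[i];
    g0 /= n;
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += X(i, j) * pr[i];
      g[j] = s / n;
    }
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      double u = zb[j] - step * g[j];
      double bj = (u > thr) ? u - thr : ((u < -thr) ? u + thr : 0.0);
      double d = std::fabs(bj - b[j]);
      if (d > maxdiff) maxdiff = d;
      nb[j] = bj;
    }
    nb0 = intercept ? zb0 - step * g0 : 0.0;
    if (std::fabs(nb0 - b0) > maxdiff) maxdiff = std::fabs(nb0 - b0);
    // adaptive restart (gradient-mapping criterion) kills FISTA's slow tail
    double dot = (zb0 - nb0) * (nb0 - b0);
    for (int j = 0; j < p; ++j) dot += (zb[j] - nb[j]) * (nb[j] - b[j]);
    if (dot > 0.0) tk = 1.0;
    double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    double mom = (tk - 1.0) / tk1;
    for (int j = 0; j < p; ++j) {
      zb[j] = nb[j] + mom * (nb[j] - b[j]);
      b[j] = nb[j];
    }
    zb0 = nb0 + mom * (nb0 - b0);
    b0 = nb0;
    tk = tk1;
    if (maxdiff < tol && it > 10) break;
  }
  NumericVector out(p + 1);
  out[0] = b0;
  for (int j = 0; j < p; ++j) out[j + 1] = b[j];
  return out;
}
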