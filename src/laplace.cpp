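// Laplace-approximate marginal likelihood for the random-effects
// logistic learning model:
//   y_it ~ Bernoulli(logit^{-1}(x_it' beta + b_i + s_i * t_it))
//   b_i ~ N(0, sigma_b^2), s_i ~ N(0, sigma_s^2), independent.
// Subjects are independent, so the marginal likelihood factorizes per
// bee into a q-dimensional integral (q = 1 or 2) approximated by
// Laplace's method at the per-bee posterior mode, found by damped
// Newton iterations. Observations must be sorted by bee.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct BeeResult {
  double logL;   // Laplace log marginal likelihood contribution
  double u1, u2; // posterior mode
  bool ok;
};

// joint log density (log p(y|u) + log-prior kernel) for one bee
static double joint_g(const double* eta0, const int* y, const double* x,
                      int a, int b, double u1, double u2,
                      double vb, double vs, int q) {
  double ll = 0.0;
  for (int t = a; t < b; ++t) {
    double eta = eta0[t] + u1 + (q == 2 ? u2 * x[t] : 0.0);
    ll += y[t] * eta - softplus(eta);
  }
  double pen = 0.5 * u1 * u1 / vb;
  if (q == 2) pen += 0.5 * u2 * u2 / vs;
  return ll - pen;
}

static BeeResult bee_laplace(const double* eta0, const int* y,
                             const double* x, int a, int b,
                             double vb, double vs, int q) {
  double u1 = 0.0, u2 = 0.0;
  double g = joint_g(eta0, y, x, a, b, u1, u2, vb, vs, q);
  double h11 = 0, h12 = 0, h22 = 0;
  bool ok = false;
  for (int iter = 0; iter < 100; ++iter) {
    double g1 = -u1 / vb, g2 = (q == 2) ? -u2 / vs : 0.0;
    h11 = 1.0 / vb; h12 = 0.0; h22 = (q == 2) ? 1.0 / vs : 0.0;
    for (int t = a; t < b; ++t) {
      double eta = eta0[t] + u1 + (q == 2 ? u2 * x[t] : 0.0);
      double p = 1.0 / (1.0 + std::exp(-eta));
      double w = p * (1.0 - p);
      double r = y[t] - p;
      g1 += r; h11 += w;
      if (q == 2) { g2 += r * x[t]; h12 += w * x[t]; h22 += w * x[t] * x[t]; }
    }
    double gn = std::fabs(g1) + (q == 2 ? std::fabs(g2) : 0.0);
    if (gn < 1e-10 * (1.0 + std::fabs(g))) { ok = true; break; }
    double d1, d2 = 0.0;
    if (q == 2) {
      double det = h11 * h22 - h12 * h12;
      d1 = (h22 * g1 - h12 * g2) / det;
      d2 = (h11 * g2 - h12 * g1) / det;
    } else {
      d1 = g1 / h11;
    }
    double step = 1.0;
    for (int hv = 0; hv < 30; ++hv) {
      double n1 = u1 + step * d1, n2 = u2 + step * d2;
      double gnew = joint_g(eta0, y, x, a, b, n1, n2, vb, vs, q);
      if (gnew >= g - 1e-12) { u1 = n1; u2 = n2; g = gnew; break; }
      step *= 0.5;
    }
    if (std::fabs(step * d1) + std::fabs(step * d2) < 1e-12) {
      ok = true; break;
    }
  }
  double logdetH = (q == 2)
    ? std::log(h11 * h22 - h12 * h12)
    : std::log(h11);
  double logdetD = std::log(vb) + (q == 2 ? std::log(vs) : 0.0);
  BeeResult res;
  res.logL = g - 0.5 * logdetD - 0.5 * logdetH;
  res.u1 = u1; res.u2 = u2; res.ok = ok;
  return res;
}

static void eta_fixed(const NumericMatrix& X, const NumericVector& beta,
                      std::vector<double>& eta0) {
  int n = X.nrow(), p = X.ncol();
  eta0.assign(n, 0.0);
  for (int j = 0; j < p; ++j) {
    double bj = beta[j];
    for (int i = 0; i < n; ++i) eta0[i] += X(i, j) * bj;
  }
}

// [[Rcpp::export]]
double laplace_nll_cpp(NumericVector par, NumericMatrix X, IntegerVector y,
                       IntegerVector bee, NumericVector xt, int q) {
  int n = X.nrow(), p = X.ncol();
  NumericVector beta = par[Range(0, p - 1)];
  double vb = std::exp(2.0 * par[p]);
  double vs = (q == 2) ? std::exp(2.0 * par[p + 1]) : 0.0;
  std::vector<double> eta0;
  eta_fixed(X, beta, eta0);
  double total = 0.0;
  int a = 0;
  while (a < n) {
    int b = a;
    while (b < n && bee[b] == bee[a]) ++b;
    BeeResult r = bee_laplace(eta0.data(), INTEGER(y), REAL(xt), a, b,
                              vb, vs, q);
    total += r.logL;
    a = b;
  }
  return -total;
}

// [[Rcpp::export]]
NumericMatrix laplace_modes_cpp(NumericVector par, NumericMatrix X,
                                IntegerVector y, IntegerVector bee,
                                NumericVector xt, int q) {
  int n = X.nrow(), p = X.ncol();
  NumericVector beta = par[Range(0, p - 1)];
  double vb = std::exp(2.0 * par[p]);
  double vs = (q == 2) ? std::exp(2.0 * par[p + 1]) : 0.0;
  std::vector<double> eta0;
  eta_fixed(X, beta, eta0);
  std::vector<double> m1, m2;
  int a = 0;
  while (a < n) {
    int b = a;
    while (b < n && bee[b] == bee[a]) ++b;
    BeeResult r = bee_laplace(eta0.data(), INTEGER(y), REAL(xt), a, b,
                              vb, vs, q);
    m1.push_back(r.u1); m2.push_back(r.u2);
    a = b;
  }
  NumericMatrix out(m1.size(), q);
  for (size_t i = 0; i < m1.size(); ++i) {
    out(i, 0) = m1[i];
    if (q == 2) out(i, 1) = m2[i];
  }
  return out;
}
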