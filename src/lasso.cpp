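// L1-penalized weighted logistic regression via proximal-Newton coordinate
// descent (deterministic; unpenalized intercept). Minimizes
//   sum_i w_i [log(1 + exp(eta_i)) - y_i * eta_i] + alpha * sum_j |beta_j|
// with eta = b0 + X beta. Used for every fit in the selection, permutation
// and bagging loops; cross-checked against glmnet in the test suite.
#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double x, double a) {
  if (x > a) return x - a;
  if (x < -a) return x + a;
  return 0.0;
}

// [[Rcpp::export]]
List cpp_lasso_logistic(NumericMatrix X, NumericVector y, NumericVector w,
                        double alpha, double tol, int maxit) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> beta(p, 0.0);
  double b0 = 0.0;
  std::vector<double> eta(n, 0.0), q(n), z(n), r(n);
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    // quadratic approximation at the current estimate
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-eta[i]));
      if (pr < 1e-8) pr = 1e-8;
      if (pr > 1.0 - 1e-8) pr = 1.0 - 1e-8;
      q[i] = w[i] * pr * (1.0 - pr);
      z[i] = eta[i] + (y[i] - pr) / (pr * (1.0 - pr));
      r[i] = z[i] - eta[i];  // z - b0 - X beta
    }
    std::vector<double> beta_old(beta);
    double b0_old = b0;
    for (int sweep = 0; sweep < 1000; ++sweep) {
      double delta = 0.0;
      // intercept
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) { num += q[i] * (r[i] + b0); den += q[i]; }
      double b0n = num / den;
      for (int i = 0; i < n; ++i) r[i] -= (b0n - b0);
      delta = std::max(delta, std::fabs(b0n - b0));
      b0 = b0n;
      for (int j = 0; j < p; ++j) {
        double rho = 0.0, d2 = 0.0;
        for (int i = 0; i < n; ++i) {
          double xij = X(i, j);
          rho += q[i] * xij * (r[i] + xij * beta[j]);
          d2 += q[i] * xij * xij;
        }
        if (d2 <= 0) continue;
        double bn = soft(rho, alpha) / d2;
        if (bn != beta[j]) {
          double db = bn - beta[j];
          for (int i = 0; i < n; ++i) r[i] -= X(i, j) * db;
          delta = std::max(delta, std::fabs(db));
          beta[j] = bn;
        }
      }
      if (delta < 1e-9) break;
    }
    double delta_outer = std::fabs(b0 - b0_old);
    for (int j = 0; j < p; ++j)
      delta_outer = std::max(delta_outer, std::fabs(beta[j] - beta_old[j]));
    for (int i = 0; i < n; ++i) {
      double e = b0;
      for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
      eta[i] = e;
    }
    if (delta_outer < tol) { converged = true; break; }
  }
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["beta0"] = b0,
                      _["iter"] = std::min(it, maxit),
                      _["converged"] = converged);
}

// rank-based (Mann-Whitney) ROC AUC with midrank tie handling
// [[Rcpp::export]]
double cpp_auc(NumericVector score, IntegerVector y) {
  int n = score.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return score[a] < score[b]; });
  std::vector<double> rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && score[ord[j + 1]] == score[ord[i]]) ++j;
    double rk = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) rank[ord[k]] = rk;
    i = j + 1;
  }
  double n1 = 0, n0 = 0, rsum = 0;
  for (int k = 0; k < n; ++k) {
    if (y[k] == 1) { n1 += 1; rsum += rank[k]; }
    else n0 += 1;
  }
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (rsum - n1 * (n1 + 1) / 2.0) / (n1 * n0);
}
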