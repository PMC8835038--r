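#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Block coordinate descent for the graphical lasso (Friedman et al. scheme):
// cycle over columns, solve each column's lasso subproblem by coordinate
// descent on the current working covariance W, then recover Theta from the
// final regression coefficients.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
List glasso_cpp(NumericMatrix S_, double lambda, double tol, int max_iter) {
  int p = S_.nrow();
  std::vector<double> S(S_.begin(), S_.end());
  std::vector<double> W(S);
  for (int j = 0; j < p; ++j) W[j * p + j] += lambda;
  std::vector<double> B(p * (p - 1), 0.0);   // beta per column
  std::vector<double> w11((p - 1) * (p - 1));
  std::vector<double> s12(p - 1), cvec(p - 1);
  std::vector<int> idx(p - 1);

  double off_mean = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) off_mean += std::fabs(S[i * p + j]);
  off_mean /= (double)p * (p - 1);
  double crit = tol * std::max(off_mean, 1e-300);

  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    double change = 0.0;
    for (int j = 0; j < p; ++j) {
      int m = 0;
      for (int i = 0; i < p; ++i) if (i != j) idx[m++] = i;
      for (int a = 0; a < p - 1; ++a) {
        s12[a] = S[j * p + idx[a]];
        for (int b = 0; b < p - 1; ++b)
          w11[b * (p - 1) + a] = W[idx[b] * p + idx[a]];
      }
      double* beta = &B[(size_t)j * (p - 1)];
      for (int a = 0; a < p - 1; ++a) {
        cvec[a] = 0.0;
        for (int b = 0; b < p - 1; ++b)
          cvec[a] += w11[b * (p - 1) + a] * beta[b];
      }
      for (int sweep = 0; sweep < 1000; ++sweep) {
        double dmax = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double wkk = w11[k * (p - 1) + k];
          double num = s12[k] - (cvec[k] - wkk * beta[k]);
          double bnew = soft(num, lambda) / wkk;
          double d = bnew - beta[k];
          if (d != 0.0) {
            const double* col = &w11[(size_t)k * (p - 1)];
            for (int a = 0; a < p - 1; ++a) cvec[a] += col[a] * d;
            beta[k] = bnew;
            double ad = std::fabs(d);
            if (ad > dmax) dmax = ad;
          }
        }
        if (dmax < 1e-9) break;
      }
      for (int a = 0; a < p - 1; ++a) {
        double w12 = cvec[a];  // W11 %*% beta
        double old = W[j * p + idx[a]];
        change += std::fabs(w12 - old);
        W[j * p + idx[a]] = w12;
        W[idx[a] * p + j] = w12;
      }
    }
    change /= (double)p * (p - 1);
    if (change < crit) break;
  }
  if (it > max_iter)
    stop("graphical lasso did not converge at lambda = %f", lambda);

  NumericMatrix Theta(p, p), Wout(p, p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    int m = 0;
    for (int i = 0; i < p; ++i) if (i != j)
      dot += W[i * p + j] * B[(size_t)j * (p - 1) + (m++)];
    double theta_jj = 1.0 / (W[j * p + j] - dot);
    Theta(j, j) = theta_jj;
    m = 0;
    for (int i = 0; i < p; ++i) if (i != j)
      Theta(i, j) = -B[(size_t)j * (p - 1) + (m++)] * theta_jj;
  }
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) {
      double sym = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = sym; Theta(j, i) = sym;
      Wout(i, j) = W[j * p + i];
    }
  return List::create(_["Theta"] = Theta, _["W"] = Wout,
                      _["iterations"] = it > max_iter ? max_iter : it);
}
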