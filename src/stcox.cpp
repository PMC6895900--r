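#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Breslow partial log-likelihood, score, and curvature for one stratum.
//
// `times` must be sorted ascending; tied times share a risk set, so the
// running sums are advanced over a whole tie group before any of its events
// are scored.  Linear predictors are max-shifted before exponentiation so
// |x'beta| up to ~700 cannot overflow.
//
// Returns loglik, gradient (m), diagonal curvature (m), and optionally the
// full m x m Hessian (needed only by the per-cell Newton MLE).
// [[Rcpp::export]]
List cpp_cox_derivs(NumericVector times, IntegerVector events,
                    NumericMatrix X, NumericVector beta, bool hessian) {
  const int n = times.size();
  const int m = X.ncol();
  double loglik = 0.0;
  NumericVector grad(m);
  NumericVector diag_curv(m);
  NumericMatrix hess(hessian ? m : 1, hessian ? m : 1);

  if (n == 0) {
    return List::create(_["loglik"] = 0.0, _["gradient"] = grad,
                        _["diag_curvature"] = diag_curv,
                        _["hessian"] = hessian ? (SEXP)hess : R_NilValue);
  }

  std::vector<double> eta(n);
  double max_eta = R_NegInf;
  for (int k = 0; k < n; ++k) {
    double e = 0.0;
    for (int l = 0; l < m; ++l) e += X(k, l) * beta[l];
    eta[k] = e;
    if (e > max_eta) max_eta = e;
  }

  // running risk-set sums, accumulated from the largest time downwards
  double S0 = 0.0;
  std::vector<double> S1(m, 0.0), S2(m, 0.0);
  std::vector<double> SXX(hessian ? m * m : 0, 0.0);

  int pos = n - 1;
  while (pos >= 0) {
    int g = pos;
    while (g > 0 && times[g - 1] == times[pos]) --g;
    for (int k = g; k <= pos; ++k) {        // admit the whole tie group
      double w = std::exp(eta[k] - max_eta);
      S0 += w;
      for (int l = 0; l < m; ++l) {
        double wx = w * X(k, l);
        S1[l] += wx;
        S2[l] += wx * X(k, l);
        if (hessian)
          for (int r = l; r < m; ++r) SXX[l * m + r] += wx * X(k, r);
      }
    }
    for (int k = g; k <= pos; ++k) {
      if (events[k] != 1) continue;
      loglik += (eta[k] - max_eta) - std::log(S0);
      for (int l = 0; l < m; ++l) {
        double mu = S1[l] / S0;
        grad[l] += X(k, l) - mu;
        diag_curv[l] -= S2[l] / S0 - mu * mu;
      }
      if (hessian) {
        for (int l = 0; l < m; ++l)
          for (int r = l; r < m; ++r) {
            double h = SXX[l * m + r] / S0 - (S1[l] / S0) * (S1[r] / S0);
            hess(l, r) -= h;
            if (r != l) hess(r, l) -= h;
          }
      }
    }
    pos = g - 1;
  }

  return List::create(_["loglik"] = loglik, _["gradient"] = grad,
                      _["diag_curvature"] = diag_curv,
                      _["hessian"] = hessian ? (SEXP)hess : R_NilValue);
}

// Inner Gauss-Seidel cycle maximising the quadratic surrogate.
//
// Coefficients are held as a (p*q) x m matrix with cell (i, j) in row
// j * p + i (0-based).  Gradients and diagonal curvatures are frozen at the
// outer expansion point; every block update sees the latest values of all
// other blocks.  `gap_w` holds the q-1 temporal adjacency weights.
//
// Sweeps stop when the l2 norm of the change over one full sweep drops
// below `inner_tol`, or after `max_inner` sweeps.
// [[Rcpp::export]]
List cpp_inner_cycle(NumericMatrix beta0, NumericMatrix beta_tilde,
                     NumericMatrix grad, NumericMatrix curv,
                     NumericMatrix omega, double lambda1, double lambda2,
                     NumericVector gap_w, double inner_tol, int max_inner) {
  const int p = omega.nrow();
  const int q = beta0.nrow() / p;
  const int m = beta0.ncol();
  NumericMatrix beta = clone(beta0);

  std::vector<double> osum(p, 0.0);
  for (int i = 0; i < p; ++i)
    for (int r = 0; r < p; ++r)
      if (r != i) osum[i] += omega(i, r);

  int sweeps = 0;
  bool converged = false;
  std::vector<double> rhs(m), spat(m);
  while (sweeps < max_inner) {
    ++sweeps;
    double change2 = 0.0;
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < q; ++j) {
        const int idx = j * p + i;
        const double gl = (j > 0) ? gap_w[j - 1] : 0.0;
        const double gr = (j < q - 1) ? gap_w[j] : 0.0;
        const double c = lambda1 * (gl + gr) + lambda2 * osum[i];

        for (int l = 0; l < m; ++l) spat[l] = 0.0;
        if (lambda2 > 0.0) {
          for (int r = 0; r < p; ++r) {
            if (r == i) continue;
            const double w = omega(i, r);
            const int ridx = j * p + r;
            for (int l = 0; l < m; ++l) spat[l] += w * beta(ridx, l);
          }
        }
        for (int l = 0; l < m; ++l) {
          double v = curv(idx, l) * beta_tilde(idx, l) - grad(idx, l);
          if (gl > 0.0) v -= lambda1 * gl * beta(idx - p, l);
          if (gr > 0.0) v -= lambda1 * gr * beta(idx + p, l);
          v -= lambda2 * spat[l];
          rhs[l] = v;
        }
        for (int l = 0; l < m; ++l) {
          const double denom = curv(idx, l) - c;
          if (denom == 0.0)
            stop("singular block system: non-identifiable covariate with no penalty");
          const double nb = rhs[l] / denom;
          const double d = nb - beta(idx, l);
          change2 += d * d;
          beta(idx, l) = nb;
        }
      }
    }
    if (std::sqrt(change2) < inner_tol) { converged = true; break; }
  }

  return List::create(_["beta"] = beta, _["sweeps"] = sweeps,
                      _["converged"] = converged);
}
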