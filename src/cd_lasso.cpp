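#include <Rcpp.h>
using namespace Rcpp;

// Soft-threshold operator S(z, g) = sign(z) * max(|z| - g, 0).
static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the L1-penalized least-squares objective
//   J(psi) = 1/(2N) * ||y - X psi||^2 + alpha * ||psi||_1
// X is assumed column-standardized so that (1/N) sum_i x_ij^2 = 1 for every
// active column; columns with active[j] == 0 are frozen at psi_j = 0
// (zero-variance columns). y is assumed centered by the caller when an
// intercept is wanted. Returns psi, final objective, sweeps used and a
// convergence flag (max |delta psi| < tol).
// [[Rcpp::export(name = ".cd_lasso_cpp")]]
List cd_lasso_cpp(NumericMatrix X, NumericVector y, double alpha,
                  double tol, int max_sweeps, LogicalVector active,
                  NumericVector psi0) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector psi = clone(psi0);
  std::vector<double> r(n); // residual y - X psi
  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j) {
    if (psi[j] != 0.0) {
      const double pj = psi[j];
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * pj;
    }
  }

  int sweep = 0;
  bool converged = false;
  for (; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (!active[j]) { psi[j] = 0.0; continue; }
      const double old = psi[j];
      // rho = (1/N) x_j' (r + x_j psi_j); with unit (1/N)||x_j||^2 the
      // coordinate update is psi_j <- S(rho, alpha).
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
      rho = rho / n + old;
      const double updated = soft_threshold(rho, alpha);
      const double delta = updated - old;
      if (delta != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * delta;
        psi[j] = updated;
      }
      if (std::abs(delta) > max_delta) max_delta = std::abs(delta);
    }
    if (max_delta < tol) { converged = true; ++sweep; break; }
  }

  double sse = 0.0, l1 = 0.0;
  for (int i = 0; i < n; ++i) sse += r[i] * r[i];
  for (int j = 0; j < p; ++j) l1 += std::abs(psi[j]);
  const double objective = sse / (2.0 * n) + alpha * l1;

  return List::create(_["psi"] = psi, _["objective"] = objective,
                      _["sweeps_used"] = sweep, _["converged"] = converged);
}

// Mean converged objective over K centered responses (columns of Y) sharing
// one standardized design matrix: the multiclass one-hot fitness kernel used
// inside the FOA loop. Returns the per-class objectives.
// [[Rcpp::export(name = ".cd_lasso_multi_cpp")]]
NumericVector cd_lasso_multi_cpp(NumericMatrix X, NumericMatrix Y,
                                 double alpha, double tol, int max_sweeps,
                                 LogicalVector active) {
  const int p = X.ncol(), K = Y.ncol();
  NumericVector obj(K);
  NumericVector psi0(p);
  for (int k = 0; k < K; ++k) {
    List fit = cd_lasso_cpp(X, Y(_, k), alpha, tol, max_sweeps, active, psi0);
    obj[k] = as<double>(fit["objective"]);
  }
  return obj;
}

// Fitness kernel for the flea search: mean converged objective over K
// centered responses on the masked columns of a standardized design. The
// caller precomputes the full (1/n) X'X Gram matrix and (1/n) X'Y once per
// dataset; this kernel slices the masked submatrix and runs covariance
// coordinate updates, so per-mask cost is independent of sample count.
// [[Rcpp::export(name = ".cd_fitness_cpp")]]
double cd_fitness_cpp(NumericMatrix Gfull, NumericMatrix B, NumericVector yty_n,
                      IntegerVector cols, double alpha, double tol,
                      int max_sweeps) {
  const int K = B.ncol(), p = cols.size();
  std::vector<double> G((size_t)p * p);
  for (int b = 0; b < p; ++b) {
    const double* gcol = &Gfull(0, cols[b]);
    for (int a = 0; a < p; ++a) G[(size_t)b * p + a] = gcol[cols[a]];
  }
  double total = 0.0;
  std::vector<double> psi(p), q(p), bvec(p);
  for (int k = 0; k < K; ++k) {
    const double yty = yty_n[k];
    for (int a = 0; a < p; ++a) bvec[a] = B(cols[a], k);
    std::fill(psi.begin(), psi.end(), 0.0);
    std::fill(q.begin(), q.end(), 0.0); // q = G psi
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double old = psi[j];
        const double rho = bvec[j] - q[j] + G[(size_t)j * p + j] * old;
        const double gjj = G[(size_t)j * p + j];
        double updated = 0.0;
        if (gjj > 0.0) updated = soft_threshold(rho, alpha) / gjj;
        const double delta = updated - old;
        if (delta != 0.0) {
          const double* gj = &G[(size_t)j * p];
          for (int a = 0; a < p; ++a) q[a] += gj[a] * delta;
          psi[j] = updated;
        }
        if (std::abs(delta) > max_delta) max_delta = std::abs(delta);
      }
      if (max_delta < tol) break;
    }
    double quad = 0.0, lin = 0.0, l1 = 0.0;
    for (int a = 0; a < p; ++a) {
      quad += psi[a] * q[a];
      lin += bvec[a] * psi[a];
      l1 += std::abs(psi[a]);
    }
    total += 0.5 * (yty - 2.0 * lin + quad) + alpha * l1;
  }
  return total / K;
}
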