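#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for
//   min_beta  ||y - X beta||^2 + lambda2 ||beta||^2 + lambda1 ||beta||_1
// on precomputed Gram quantities G = X'X and c = X'y (y already centered,
// X already standardized by the caller). Update:
//   beta_j <- S(x_j' r_(-j), lambda1 / 2) / (G_jj + lambda2).
// yty is needed only when check_objective is true (monotonicity assertion).
// [[Rcpp::export(name = ".enet_cd_gram_cpp")]]
List enet_cd_gram_cpp(NumericMatrix G, NumericVector c, double yty,
                      double lambda1, double lambda2,
                      NumericVector beta_init, double tol, int max_sweeps,
                      bool check_objective) {
  int p = c.size();
  NumericVector beta = clone(beta_init);
  std::vector<double> q(p, 0.0);  // q = G beta, maintained incrementally
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0)
      for (int i = 0; i < p; ++i) q[i] += G(i, j) * beta[j];
  }
  double obj_prev = R_PosInf;
  double max_delta = R_PosInf;
  int sweep = 0;
  bool converged = false;
  for (sweep = 1; sweep <= max_sweeps; ++sweep) {
    max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      double gjj = G(j, j);
      if (gjj <= 0.0) { continue; }
      double z = c[j] - q[j] + gjj * beta[j];  // x_j' r_(-j)
      double bnew = soft(z, lambda1 / 2.0) / (gjj + lambda2);
      double d = bnew - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < p; ++i) q[i] += G(i, j) * d;
        beta[j] = bnew;
        double ad = std::fabs(d);
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (check_objective) {
      double quad = 0.0, l1 = 0.0, l2 = 0.0;
      for (int j = 0; j < p; ++j) {
        quad += beta[j] * (q[j] - 2.0 * c[j]);
        l1 += std::fabs(beta[j]);
        l2 += beta[j] * beta[j];
      }
      double obj = yty + quad + lambda2 * l2 + lambda1 * l1;
      if (obj > obj_prev + 1e-8 * (1.0 + std::fabs(obj_prev)))
        stop("coordinate descent objective increased (%.12g -> %.12g)",
             obj_prev, obj);
      obj_prev = obj;
    }
    if (max_delta < tol) { converged = true; break; }
  }
  return List::create(_["beta"] = beta, _["sweeps"] = std::min(sweep, max_sweeps),
                      _["converged"] = converged, _["max_delta"] = max_delta);
}
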