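// Damped Newton maximization of the penalized Poisson log-likelihood used by
// the GLMCC / ShinGLMCC correlogram fits.
//
// Parameter vector x = [a_1..a_n, (a0 knot), (J_pos), (J_neg)].
// Objective: sum_b c_b eta_b - delta * sum_b exp(eta_b) - xa' K xa,
// with eta = a + J_pos * fp + J_neg * fn, delta the bin width (ms) and K the
// quadratic penalty form acting on the background vector (plus knot).
// The objective is concave, so Newton with step halving converges globally.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double glm_obj(const arma::vec& counts, const arma::vec& fp,
                      const arma::vec& fn, const arma::mat& K,
                      double delta, int n, int na, bool free_jp, bool free_jn,
                      const arma::vec& x, arma::vec& eta) {
  double jp = free_jp ? x(na + 0) : 0.0;
  double jn = free_jn ? x(na + (free_jp ? 1 : 0)) : 0.0;
  eta = x.head(n) + jp * fp + jn * fn;
  if (eta.max() > 60.0) return -1e300; // reject absurd steps in line search
  arma::vec xa = x.head(na);
  return arma::dot(counts, eta) - delta * arma::accu(arma::exp(eta)) -
         arma::as_scalar(xa.t() * K * xa);
}

// [[Rcpp::export(name = ".glm_newton")]]
List glm_newton(const arma::vec& counts, const arma::vec& fp, const arma::vec& fn,
                const arma::mat& K, bool has_knot, bool free_jp, bool free_jn,
                double delta, const arma::vec& init,
                double tol_obj, double tol_grad, int max_iter) {
  const int n = counts.n_elem;
  const int na = n + (has_knot ? 1 : 0);
  const int nj = (free_jp ? 1 : 0) + (free_jn ? 1 : 0);
  const int np = na + nj;
  arma::vec x = init;
  if ((int)x.n_elem != np) stop("init length mismatch");

  arma::vec eta(n);
  double obj = glm_obj(counts, fp, fn, K, delta, n, na, free_jp, free_jn, x, eta);
  bool converged = false;
  int iter = 0;
  double gmax = NA_REAL;

  for (iter = 0; iter < max_iter; ++iter) {
    arma::vec w = delta * arma::exp(eta);      // per-bin expected counts
    arma::vec resid = counts - w;              // data-score per bin
    arma::vec Kx = 2.0 * (K * x.head(na));

    arma::vec g(np, arma::fill::zeros);
    g.head(n) = resid;
    g.head(na) -= Kx;
    int col = na;
    int jp_col = -1, jn_col = -1;
    if (free_jp) { jp_col = col++; g(jp_col) = arma::dot(fp, resid); }
    if (free_jn) { jn_col = col++; g(jn_col) = arma::dot(fn, resid); }

    gmax = arma::abs(g).max();
    if (gmax < tol_grad) { converged = true; break; }

    arma::mat H = arma::zeros<arma::mat>(np, np);
    H.submat(0, 0, na - 1, na - 1) = -2.0 * K;
    for (int i = 0; i < n; ++i) H(i, i) -= w(i);
    if (free_jp) {
      for (int i = 0; i < n; ++i) { H(i, jp_col) = -fp(i) * w(i); H(jp_col, i) = H(i, jp_col); }
      H(jp_col, jp_col) = -arma::dot(fp % fp, w);
    }
    if (free_jn) {
      for (int i = 0; i < n; ++i) { H(i, jn_col) = -fn(i) * w(i); H(jn_col, i) = H(i, jn_col); }
      H(jn_col, jn_col) = -arma::dot(fn % fn, w);
      if (free_jp) {
        double c = -arma::dot(fp % fn, w);
        H(jp_col, jn_col) = c; H(jn_col, jp_col) = c;
      }
    }

    // Solve the Newton system; on (near-)singularity — e.g. an almost empty
    // correlogram where the data carry no curvature — fall back to a ridged
    // system, which turns the step into a damped gradient ascent.
    arma::vec dir;
    bool ok = arma::solve(dir, -H, g,
                          arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok || !dir.is_finite()) {
      const double ridge = 1e-8 * (1.0 + arma::abs(H.diag()).max());
      ok = arma::solve(dir, -H + ridge * arma::eye(np, np), g,
                       arma::solve_opts::no_approx);
      if (!ok || !dir.is_finite()) break;
    }

    double step = 1.0;
    double obj_new = -1e300;
    arma::vec x_new;
    int h;
    for (h = 0; h < 50; ++h) {
      x_new = x + step * dir;
      obj_new = glm_obj(counts, fp, fn, K, delta, n, na, free_jp, free_jn, x_new, eta);
      if (obj_new > obj - 1e-12) break;
      step *= 0.5;
    }
    if (h == 50) { // no ascent direction found numerically: at optimum
      converged = true;
      // restore eta for current x
      glm_obj(counts, fp, fn, K, delta, n, na, free_jp, free_jn, x, eta);
      break;
    }
    double rel = std::fabs(obj_new - obj) / (std::fabs(obj) + 1.0);
    x = x_new;
    obj = obj_new;
    if (rel < tol_obj && gmax < 1e-3) { converged = true; break; }
  }

  // final quantities
  double jp = free_jp ? x(na + 0) : 0.0;
  double jn = free_jn ? x(na + (free_jp ? 1 : 0)) : 0.0;
  eta = x.head(n) + jp * fp + jn * fn;
  double loglik = arma::dot(counts, eta) - delta * arma::accu(arma::exp(eta));
  arma::vec xa = x.head(na);
  double penalty = arma::as_scalar(xa.t() * K * xa);

  return List::create(
    _["par"] = x,
    _["loglik"] = loglik,
    _["logpost"] = loglik - penalty,
    _["penalty"] = penalty,
    _["converged"] = converged,
    _["iterations"] = iter,
    _["grad_max"] = gmax
  );
}
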