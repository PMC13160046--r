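#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Log-domain Sinkhorn scaling for entropic (un)balanced optimal transport.
//
// Objective: min_P <P,C> - eps*H(P) + lambda_a*KL(P1 || a) + lambda_b*KL(P'1 || b)
// with the KL fractions tau = lambda/(lambda+eps) entering the dual updates as
// exponents; tau == 1 recovers the balanced (hard-marginal) problem.
//
// Updates are carried out on dual potentials (f, g) with log-sum-exp
// stabilisation, so arbitrarily small eps is safe (no under/overflow in the
// scaling vectors themselves).

using namespace Rcpp;

static arma::vec lse_rows(const arma::mat& M) {
  arma::vec mx = arma::max(M, 1);
  arma::mat S = M;
  S.each_col() -= mx;
  return mx + arma::log(arma::sum(arma::exp(S), 1));
}

// [[Rcpp::export]]
List cpp_sinkhorn_uot(const arma::mat& C,
                      const arma::vec& a,
                      const arma::vec& b,
                      const double eps,
                      const double tau_a,
                      const double tau_b,
                      const int max_iters,
                      const double tol) {
  const arma::uword m = C.n_rows, n = C.n_cols;
  const arma::vec loga = arma::log(a), logb = arma::log(b);
  const arma::mat M0 = -C / eps;

  arma::vec f(m, arma::fill::zeros), g(n, arma::fill::zeros);
  const bool bal_a = (tau_a >= 1.0), bal_b = (tau_b >= 1.0);

  double res = R_PosInf;
  bool converged = false;
  int it = 0;

  for (it = 1; it <= max_iters; ++it) {
    // --- f update (rows) ---
    arma::mat A = M0;
    A.each_row() += (g / eps).t();
    arma::vec Sf = eps * lse_rows(A);
    arma::vec f_new = bal_a ? (eps * loga - Sf) : arma::vec(tau_a * (eps * loga - Sf));
    double res_a;
    if (bal_a) {
      // row marginal residual with the pre-update f: sum_i |(P1)_i - a_i|
      res_a = arma::accu(a % arma::abs(arma::exp((f - f_new) / eps) - 1.0));
    } else {
      res_a = arma::abs(f_new - f).max();
    }
    f = f_new;

    // --- g update (columns) ---
    arma::mat B = M0;
    B.each_col() += f / eps;
    arma::vec Sg = eps * lse_rows(B.t());
    arma::vec g_new = bal_b ? (eps * logb - Sg) : arma::vec(tau_b * (eps * logb - Sg));
    double res_b;
    if (bal_b) {
      res_b = arma::accu(b % arma::abs(arma::exp((g - g_new) / eps) - 1.0));
    } else {
      res_b = arma::abs(g_new - g).max();
    }
    g = g_new;

    if (!f.is_finite() || !g.is_finite()) {
      return List::create(_["error"] = true);
    }
    res = std::max(res_a, res_b);
    if (res < tol) { converged = true; break; }
  }

  arma::mat P = M0;
  P.each_col() += f / eps;
  P.each_row() += (g / eps).t();
  P = arma::exp(P);

  return List::create(
    _["error"] = false,
    _["P"] = P,
    _["f"] = f,
    _["g"] = g,
    _["iterations"] = std::min(it, max_iters),
    _["converged"] = converged,
    _["residual"] = res,
    _["cost"] = arma::accu(P % C));
}
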