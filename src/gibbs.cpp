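#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Draws from R's RNG so set.seed() on the R side gives bit-identical chains.
static arma::vec r_randn(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = norm_rand();
  return z;
}

// Gibbs sampler for y = W beta + sum_b Z_b u_b + eps with flat prior on the
// fixed effects beta, u_b ~ N(0, sig2_b I), eps ~ N(0, sig2_e I), and
// scaled-inverse-chi-square priors (df v0, scale s0) on every variance.
// v0 = 0, s0 = 0 is the Jeffreys limit p(sig2) ~ 1/sig2 used by default.
// Variance draws are guarded below by `lower`.
// [[Rcpp::export]]
List gibbs_mixed(const arma::vec& y, const arma::mat& W, List Zlist,
                 int n_iter, int n_burn, double v0, double s0, double lower) {
  const int N = y.n_elem;
  const int p = W.n_cols;
  const int B = Zlist.size();

  arma::mat WtW = W.t() * W;
  WtW.diag() += 1e-10 * arma::trace(WtW) / std::max(p, 1);
  arma::mat WtW_inv = arma::inv_sympd(WtW);
  arma::mat Lw = arma::chol(WtW_inv, "lower");

  std::vector<arma::mat> Z(B), ZtZ(B);
  std::vector<arma::vec> u(B);
  arma::vec sig2u(B);
  double vy = arma::var(y);
  if (vy <= 0) vy = 1.0;
  for (int b = 0; b < B; ++b) {
    Z[b] = as<arma::mat>(Zlist[b]);
    ZtZ[b] = Z[b].t() * Z[b];
    u[b] = arma::zeros(Z[b].n_cols);
    sig2u(b) = vy / 10.0;
  }
  double sig2e = vy / 2.0;

  arma::vec zu = arma::zeros(N);
  arma::vec beta = arma::solve(WtW, W.t() * y);
  arma::vec wb = W * beta;

  const int S = n_iter - n_burn;
  arma::mat beta_draws(S, p);
  arma::mat sig_draws(S, B + 1);
  arma::mat u_sum(1, 1, arma::fill::zeros);
  std::vector<arma::vec> u_mean(B);
  for (int b = 0; b < B; ++b) u_mean[b] = arma::zeros(Z[b].n_cols);

  for (int it = 0; it < n_iter; ++it) {
    // fixed effects
    arma::vec mb = WtW_inv * (W.t() * (y - zu));
    beta = mb + std::sqrt(sig2e) * (Lw * r_randn(p));
    wb = W * beta;

    // random blocks
    for (int b = 0; b < B; ++b) {
      const int q = Z[b].n_cols;
      arma::vec r_b = y - wb - (zu - Z[b] * u[b]);
      arma::mat Prec = ZtZ[b] / sig2e;
      Prec.diag() += 1.0 / sig2u(b);
      arma::mat U = arma::chol(Prec);  // upper
      arma::vec mean_u = arma::solve(Prec, Z[b].t() * r_b / sig2e);
      arma::vec un = arma::solve(arma::trimatu(U), r_randn(q));
      arma::vec u_new = mean_u + un;
      zu += Z[b] * (u_new - u[b]);
      u[b] = u_new;
      double ss = arma::dot(u[b], u[b]) + v0 * s0;
      double df = q + v0;
      sig2u(b) = std::max(ss / ::Rf_rchisq(df), lower);
    }

    // residual variance
    arma::vec e = y - wb - zu;
    double ss = arma::dot(e, e) + v0 * s0;
    sig2e = std::max(ss / ::Rf_rchisq(N + v0), lower);

    if (it >= n_burn) {
      int s = it - n_burn;
      beta_draws.row(s) = beta.t();
      for (int b = 0; b < B; ++b) {
        sig_draws(s, b) = sig2u(b);
        u_mean[b] += u[b] / S;
      }
      sig_draws(s, B) = sig2e;
    }
  }

  List um(B);
  for (int b = 0; b < B; ++b) um[b] = u_mean[b];
  return List::create(_["beta"] = beta_draws,
                      _["sigma2"] = sig_draws,
                      _["u_mean"] = um);
}
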