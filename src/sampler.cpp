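// Metropolis-within-Gibbs core for the hierarchical movement-rate model.
//
// Model (sqrt km/h scale):
//   y_t = lambda_{c(t)}[i_t] + omega_{k(t)} + fixed_t
//         + sum_j beta_{j,g} exp(-phi_{j,g} x_{j,t}) + eps_t,  eps ~ N(0, sigma2)
// with lambda_c ~ MN(0, C(nu)/psi) on the 24-hour circle (shared nu, psi),
// omega_k ~ N(alpha, rho2), conjugate Gaussian/Gamma priors elsewhere,
// nu ~ U(nu_lo, nu_hi), phi ~ U(phi_lo, phi_hi).
//
// All Gaussian location blocks and the precisions/scale (1/sigma2, 1/rho2,
// psi) are Gibbs updates; nu (log scale) and each phi (natural scale) are
// adaptive random-walk Metropolis with reflection at the uniform bounds,
// adaptation frozen after burn-in. Randomness comes from R's RNG, so a
// set.seed() on the R side makes chains bit-reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat circ_dist24() {
  arma::mat d(24, 24);
  for (int i = 0; i < 24; ++i)
    for (int j = 0; j < 24; ++j) {
      int a = std::abs(i - j);
      d(i, j) = std::min(a, 24 - a);
    }
  return d;
}

struct HourCov {
  arma::mat C, Cinv, L;       // C = L L' (lower Cholesky)
  double logdet;
  void set(double nu, const arma::mat& d) {
    C = arma::exp(-nu * d);
    arma::mat R = arma::chol(C);
    L = R.t();
    logdet = 2.0 * arma::sum(arma::log(R.diag()));
    Cinv = arma::inv_sympd(C);
  }
};

// Draw x ~ N(Q^{-1} b, Q^{-1}) given precision Q (SPD) and linear term b.
static arma::vec draw_gauss_prec(const arma::mat& Q, const arma::vec& b) {
  arma::mat R = arma::chol(Q);                       // Q = R'R, R upper
  arma::vec mu = arma::solve(arma::trimatu(R),
                             arma::solve(arma::trimatl(R.t()), b));
  arma::vec z(b.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return mu + arma::solve(arma::trimatu(R), z);
}

static double reflect(double x, double lo, double hi) {
  double span = 2.0 * (hi - lo);
  double t = (x - lo) / span;
  double r = (t - std::floor(t)) * span;    // remainder in [0, span)
  return lo + (r <= hi - lo ? r : span - r);
}

// One Gibbs draw of a 24-vector hour effect from its full conditional:
// prior MN(0, C(nu)/psi), likelihood sums s_i of partial residuals with
// counts n_i and residual variance sigma2. Exposed for transition tests.
// [[Rcpp::export]]
NumericMatrix lambda_conditional_draws(NumericVector s, NumericVector counts,
                                       double nu, double psi, double sigma2,
                                       int nrep) {
  arma::mat d = circ_dist24();
  HourCov hc; hc.set(nu, d);
  arma::mat Q = psi * hc.Cinv;
  arma::vec b(24);
  for (int i = 0; i < 24; ++i) {
    Q(i, i) += counts[i] / sigma2;
    b(i) = s[i] / sigma2;
  }
  NumericMatrix out(nrep, 24);
  for (int r = 0; r < nrep; ++r) {
    arma::vec v = draw_gauss_prec(Q, b);
    for (int i = 0; i < 24; ++i) out(r, i) = v(i);
  }
  return out;
}

// Deviance -2 log L of each posterior draw. Column-index arguments are
// 1-based positions into `draws`: lam_idx[t] is the hour-effect column for
// observation t, omega_idx[t] its individual effect (0 = none), fix_idx a
// n x F matrix of fixed-coefficient columns (0 = reference), beta_idx /
// phi_idx n x J matrices for the anthropogenic block, X the distances.
// [[Rcpp::export]]
NumericVector deviance_draws_cpp(NumericMatrix draws, NumericVector y,
                                 IntegerVector lam_idx, IntegerVector omega_idx,
                                 IntegerMatrix fix_idx, IntegerMatrix beta_idx,
                                 IntegerMatrix phi_idx, NumericMatrix X,
                                 int sigma2_col) {
  const int D = draws.nrow(), n = y.size();
  const int F = fix_idx.ncol(), J = beta_idx.ncol();
  NumericVector out(D);
  const double l2pi = std::log(2.0 * M_PI);
  for (int d = 0; d < D; ++d) {
    const double s2 = draws(d, sigma2_col - 1);
    double ss = 0;
    for (int t = 0; t < n; ++t) {
      double eta = draws(d, lam_idx[t] - 1);
      if (omega_idx[t] > 0) eta += draws(d, omega_idx[t] - 1);
      for (int f = 0; f < F; ++f)
        if (fix_idx(t, f) > 0) eta += draws(d, fix_idx(t, f) - 1);
      for (int j = 0; j < J; ++j)
        eta += draws(d, beta_idx(t, j) - 1) *
               std::exp(-draws(d, phi_idx(t, j) - 1) * X(t, j));
      double r = y[t] - eta;
      ss += r * r;
    }
    out[d] = n * (l2pi + std::log(s2)) + ss / s2;
  }
  return out;
}

// [[Rcpp::export]]
List run_chain_cpp(NumericVector y, IntegerVector hour, IntegerVector strat,
                   int m, IntegerVector animal, int K, IntegerMatrix fixmap,
                   int nfix, NumericMatrix X, IntegerMatrix agrp,
                   IntegerVector ngrp, List priors, List fixed_vals,
                   int burn, int keep, int thin, bool adapt_burnin) {
  const int n = y.size();
  const int J = X.ncol();
  const int F = fixmap.ncol();
  int totG = 0;
  for (int j = 0; j < J; ++j) totG += ngrp[j];

  // priors
  const double alpha_mean = priors["alpha_mean"], alpha_var = priors["alpha_var"];
  const double rho2_shape = priors["rho2_shape"], rho2_rate = priors["rho2_rate"];
  const double psi_shape = priors["psi_shape"], psi_rate = priors["psi_rate"];
  const double nu_lo = priors["nu_low"], nu_hi = priors["nu_high"];
  const double fixed_var = priors["fixed_var"], beta_var = priors["beta_var"];
  const double phi_lo = priors["phi_low"], phi_hi = priors["phi_high"];
  const double s2_shape = priors["sigma2_shape"], s2_rate = priors["sigma2_rate"];

  auto fixed_of = [&](const char* nm, bool& is_fixed) -> double {
    if (!fixed_vals.containsElementNamed(nm)) { is_fixed = false; return NA_REAL; }
    RObject o = fixed_vals[nm];
    if (o.isNULL()) { is_fixed = false; return NA_REAL; }
    is_fixed = true;
    return as<double>(o);
  };
  bool fix_nu, fix_psi, fix_s2, fix_r2;
  double v_nu = fixed_of("nu", fix_nu), v_psi = fixed_of("psi", fix_psi);
  double v_s2 = fixed_of("sigma2", fix_s2), v_r2 = fixed_of("rho2", fix_r2);

  // observation index lists
  std::vector<std::vector<int>> strat_obs(m);
  std::vector<std::vector<int>> anim_obs(K);
  std::vector<std::vector<int>> fix_obs(nfix);
  std::vector<std::vector<int>> grp_obs(totG);      // flattened anthro groups
  std::vector<int> grp_col(totG);                   // which X column each group uses
  {
    int off = 0;
    for (int j = 0; j < J; ++j) {
      for (int g = 0; g < ngrp[j]; ++g) grp_col[off + g] = j;
      off += ngrp[j];
    }
  }
  std::vector<int> goffset(J, 0);
  for (int j = 1; j < J; ++j) goffset[j] = goffset[j - 1] + ngrp[j - 1];
  for (int t = 0; t < n; ++t) {
    strat_obs[strat[t] - 1].push_back(t);
    if (K > 0) anim_obs[animal[t] - 1].push_back(t);
    for (int f = 0; f < F; ++f) {
      int idx = fixmap(t, f);
      if (idx > 0) fix_obs[idx - 1].push_back(t);
    }
    for (int j = 0; j < J; ++j) grp_obs[goffset[j] + agrp(t, j) - 1].push_back(t);
  }
  // per-stratum hour counts
  arma::mat hour_counts(24, m, arma::fill::zeros);
  for (int t = 0; t < n; ++t) hour_counts(hour[t] - 1, strat[t] - 1) += 1.0;

  // state
  arma::mat lambda(24, m, arma::fill::zeros);
  std::vector<double> omega(K, 0.0);
  double alpha = 0.0;
  double rho2 = fix_r2 ? v_r2 : 1.0;
  std::vector<double> fixco(nfix, 0.0);
  std::vector<double> beta(totG, 0.0);
  std::vector<double> phi(totG, 0.5 * (phi_lo + phi_hi));
  double nu = fix_nu ? v_nu : 0.5 * (nu_lo + nu_hi);
  double psi = fix_psi ? v_psi : 1.0;
  double sigma2 = fix_s2 ? v_s2 : 1.0;

  arma::mat dmat = circ_dist24();
  HourCov hc; hc.set(nu, dmat);

  // anthropogenic weights cache W(t, j) = exp(-phi_{g(t,j)} x_{t,j})
  NumericMatrix W(std::max(n, 1), std::max(J, 1));
  for (int j = 0; j < J; ++j)
    for (int t = 0; t < n; ++t)
      W(t, j) = std::exp(-phi[goffset[j] + agrp(t, j) - 1] * X(t, j));

  // residuals
  std::vector<double> res(n);
  auto rebuild_res = [&]() {
    for (int t = 0; t < n; ++t) {
      double eta = lambda(hour[t] - 1, strat[t] - 1);
      if (K > 0) eta += omega[animal[t] - 1];
      for (int f = 0; f < F; ++f) {
        int idx = fixmap(t, f);
        if (idx > 0) eta += fixco[idx - 1];
      }
      for (int j = 0; j < J; ++j)
        eta += beta[goffset[j] + agrp(t, j) - 1] * W(t, j);
      res[t] = y[t] - eta;
    }
  };
  rebuild_res();

  // Metropolis bookkeeping
  double ls_nu = std::log(0.2);                  // step on log(nu)
  double ls_psi = std::log(0.5);                 // step of the psi rescaling move
  double ls_nu2 = std::log(0.3);                 // step of the nu reshaping move
  std::vector<double> ls_phi(totG, std::log(1.0));
  double acc_nu = 0; int try_nu = 0;
  std::vector<double> acc_phi(totG, 0.0);
  std::vector<int> try_phi(totG, 0);
  const double target = 0.35;

  auto lambda_quad = [&]() {                     // sum_c lambda_c' Cinv lambda_c
    double q = 0;
    for (int c = 0; c < m; ++c) {
      arma::vec v = lambda.col(c);
      q += arma::dot(v, hc.Cinv * v);
    }
    return q;
  };

  const int n_out = keep / thin;
  const int P = 24 * m + K + 2 + nfix + 2 * totG + 3;
  NumericMatrix draws(n_out, P);
  int row = 0;
  const int total_iter = burn + keep;

  for (int it = 1; it <= total_iter; ++it) {
    const bool in_burn = it <= burn;

    // ---- lambda blocks (joint 24-dim Gibbs per stratum)
    for (int c = 0; c < m; ++c) {
      arma::vec s(24, arma::fill::zeros);
      for (int t : strat_obs[c]) {
        double lam_old = lambda(hour[t] - 1, c);
        s(hour[t] - 1) += res[t] + lam_old;
      }
      arma::mat Q = psi * hc.Cinv;
      arma::vec b(24);
      for (int i = 0; i < 24; ++i) {
        Q(i, i) += hour_counts(i, c) / sigma2;
        b(i) = s(i) / sigma2;
      }
      arma::vec lam_new = draw_gauss_prec(Q, b);
      for (int t : strat_obs[c])
        res[t] -= lam_new(hour[t] - 1) - lambda(hour[t] - 1, c);
      lambda.col(c) = lam_new;
    }

    // ---- individual effects and their hyperparameters
    if (K > 0) {
      for (int k = 0; k < K; ++k) {
        double s = 0; int nk = anim_obs[k].size();
        for (int t : anim_obs[k]) s += res[t] + omega[k];
        double prec = nk / sigma2 + 1.0 / rho2;
        double mean = (s / sigma2 + alpha / rho2) / prec;
        double w_new = mean + R::norm_rand() / std::sqrt(prec);
        for (int t : anim_obs[k]) res[t] -= w_new - omega[k];
        omega[k] = w_new;
      }
      double sw = 0;
      for (int k = 0; k < K; ++k) sw += omega[k];
      double prec_a = K / rho2 + 1.0 / alpha_var;
      double mean_a = (sw / rho2 + alpha_mean / alpha_var) / prec_a;
      alpha = mean_a + R::norm_rand() / std::sqrt(prec_a);
      if (!fix_r2) {
        double ss = 0;
        for (int k = 0; k < K; ++k) ss += (omega[k] - alpha) * (omega[k] - alpha);
        double prec = R::rgamma(rho2_shape + 0.5 * K, 1.0 / (rho2_rate + 0.5 * ss));
        rho2 = 1.0 / prec;
      }
    } else {
      alpha = alpha_mean + R::norm_rand() * std::sqrt(alpha_var);
      if (!fix_r2) rho2 = 1.0 / R::rgamma(rho2_shape, 1.0 / rho2_rate);
    }

    // ---- fixed sex/season coefficients (scalar conjugate updates)
    for (int f = 0; f < nfix; ++f) {
      double s = 0; int nf = fix_obs[f].size();
      for (int t : fix_obs[f]) s += res[t] + fixco[f];
      double prec = nf / sigma2 + 1.0 / fixed_var;
      double mean = (s / sigma2) / prec;
      double c_new = mean + R::norm_rand() / std::sqrt(prec);
      for (int t : fix_obs[f]) res[t] -= c_new - fixco[f];
      fixco[f] = c_new;
    }

    // ---- anthropogenic multipliers (conjugate given phi)
    for (int g = 0; g < totG; ++g) {
      int j = grp_col[g];
      double sw = 0, sw2 = 0;
      for (int t : grp_obs[g]) {
        double w = W(t, j);
        sw += (res[t] + beta[g] * w) * w;
        sw2 += w * w;
      }
      double prec = sw2 / sigma2 + 1.0 / beta_var;
      double mean = (sw / sigma2) / prec;
      double b_new = mean + R::norm_rand() / std::sqrt(prec);
      for (int t : grp_obs[g]) res[t] -= (b_new - beta[g]) * W(t, j);
      beta[g] = b_new;
    }

    // ---- anthropogenic decays (reflected random-walk Metropolis)
    for (int g = 0; g < totG; ++g) {
      int j = grp_col[g];
      double prop = reflect(phi[g] + std::exp(ls_phi[g]) * R::norm_rand(),
                            phi_lo, phi_hi);
      double dll = 0;
      for (int t : grp_obs[g]) {
        double w_new = std::exp(-prop * X(t, j));
        double r_new = res[t] + beta[g] * (W(t, j) - w_new);
        dll += (res[t] * res[t] - r_new * r_new) / (2.0 * sigma2);
      }
      double a = std::min(1.0, std::exp(dll));
      if (R::unif_rand() < a) {
        for (int t : grp_obs[g]) {
          double w_new = std::exp(-prop * X(t, j));
          res[t] += beta[g] * (W(t, j) - w_new);
          W(t, j) = w_new;
        }
        phi[g] = prop;
      }
      if (in_burn && adapt_burnin)
        ls_phi[g] += std::pow((double)it, -0.6) * (a - target);
      if (!in_burn) { acc_phi[g] += a; try_phi[g] += 1; }
    }

    // ---- nu (reflected random walk on log scale; conditional on lambda, psi)
    if (!fix_nu) {
      double u = std::log(nu);
      double up = reflect(u + std::exp(ls_nu) * R::norm_rand(),
                          std::log(nu_lo), std::log(nu_hi));
      HourCov hc_p; hc_p.set(std::exp(up), dmat);
      double q_cur = lambda_quad();
      double q_prop = 0;
      for (int c = 0; c < m; ++c) {
        arma::vec v = lambda.col(c);
        q_prop += arma::dot(v, hc_p.Cinv * v);
      }
      // log target on u: -m/2 logdetC - psi/2 quad + u (Jacobian; uniform prior on nu)
      double lr = (-0.5 * m * hc_p.logdet - 0.5 * psi * q_prop + up)
                - (-0.5 * m * hc.logdet - 0.5 * psi * q_cur + u);
      double a = std::min(1.0, std::exp(lr));
      if (R::unif_rand() < a) { nu = std::exp(up); hc = hc_p; }
      if (in_burn && adapt_burnin)
        ls_nu += std::pow((double)it, -0.6) * (a - target);
      if (!in_burn) { acc_nu += a; try_nu += 1; }

      // non-centered companion move: propose nu holding the whitened
      // effects L(nu)^{-1} lambda fixed, so lambda is reshaped through the
      // new Cholesky. The MN prior cancels in whitened coordinates; the
      // ratio is the likelihood change plus the log-scale Jacobian.
      u = std::log(nu);
      up = reflect(u + std::exp(ls_nu2) * R::norm_rand(),
                   std::log(nu_lo), std::log(nu_hi));
      HourCov hc_n; hc_n.set(std::exp(up), dmat);
      arma::mat lam_new(24, m);
      for (int c = 0; c < m; ++c)
        lam_new.col(c) = hc_n.L * arma::solve(arma::trimatl(hc.L),
                                              arma::vec(lambda.col(c)));
      double dll = 0;
      for (int t = 0; t < n; ++t) {
        double r_new = res[t] - (lam_new(hour[t] - 1, strat[t] - 1)
                                 - lambda(hour[t] - 1, strat[t] - 1));
        dll += (res[t] * res[t] - r_new * r_new) / (2.0 * sigma2);
      }
      double lr2 = dll + up - u;
      double a2 = std::min(1.0, std::exp(lr2));
      if (R::unif_rand() < a2) {
        for (int t = 0; t < n; ++t)
          res[t] -= lam_new(hour[t] - 1, strat[t] - 1)
                    - lambda(hour[t] - 1, strat[t] - 1);
        lambda = lam_new;
        nu = std::exp(up);
        hc = hc_n;
      }
      if (in_burn && adapt_burnin)
        ls_nu2 += std::pow((double)it, -0.6) * (a2 - target);
    }

    // ---- psi (conjugate Gamma given lambda, nu)
    if (!fix_psi) {
      double q = lambda_quad();
      psi = R::rgamma(psi_shape + 12.0 * m, 1.0 / (psi_rate + 0.5 * q));

      // non-centered rescaling move: random walk on log(psi) holding the
      // whitened effects sqrt(psi)*lambda fixed (lambda scales along),
      // which decouples the scale from the hour effects (funnel fix).
      // In whitened coordinates the MN prior term cancels; the ratio is
      // the Gamma prior (with log-scale Jacobian) times the likelihood
      // change from rescaling lambda.
      double lp = std::log(psi);
      double lp_new = lp + std::exp(ls_psi) * R::norm_rand();
      double psi_new = std::exp(lp_new);
      double sc = std::sqrt(psi / psi_new);
      double dll = 0;
      for (int t = 0; t < n; ++t) {
        double lam = lambda(hour[t] - 1, strat[t] - 1);
        double r_new = res[t] + (1.0 - sc) * lam;
        dll += (res[t] * res[t] - r_new * r_new) / (2.0 * sigma2);
      }
      double lr = dll + psi_shape * (lp_new - lp) - psi_rate * (psi_new - psi);
      double a = std::min(1.0, std::exp(lr));
      if (R::unif_rand() < a) {
        for (int t = 0; t < n; ++t)
          res[t] += (1.0 - sc) * lambda(hour[t] - 1, strat[t] - 1);
        lambda *= sc;
        psi = psi_new;
      }
      if (in_burn && adapt_burnin)
        ls_psi += std::pow((double)it, -0.6) * (a - target);
    }

    // ---- residual variance
    if (!fix_s2) {
      double ss = 0;
      for (int t = 0; t < n; ++t) ss += res[t] * res[t];
      sigma2 = 1.0 / R::rgamma(s2_shape + 0.5 * n, 1.0 / (s2_rate + 0.5 * ss));
    }

    if (it % 200 == 0) rebuild_res();            // keep incremental drift in check

    // ---- store
    if (!in_burn && ((it - burn) % thin == 0)) {
      int p = 0;
      for (int c = 0; c < m; ++c)
        for (int i = 0; i < 24; ++i) draws(row, p++) = lambda(i, c);
      for (int k = 0; k < K; ++k) draws(row, p++) = omega[k];
      draws(row, p++) = alpha;
      draws(row, p++) = rho2;
      for (int f = 0; f < nfix; ++f) draws(row, p++) = fixco[f];
      for (int g = 0; g < totG; ++g) draws(row, p++) = beta[g];
      for (int g = 0; g < totG; ++g) draws(row, p++) = phi[g];
      draws(row, p++) = nu;
      draws(row, p++) = psi;
      draws(row, p++) = sigma2;
      ++row;
    }
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc(1 + totG);
  acc[0] = try_nu > 0 ? acc_nu / try_nu : NA_REAL;
  for (int g = 0; g < totG; ++g)
    acc[g + 1] = try_phi[g] > 0 ? acc_phi[g] / try_phi[g] : NA_REAL;

  return List::create(_["draws"] = draws, _["accept"] = acc,
                      _["step_nu"] = std::exp(ls_nu));
}
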