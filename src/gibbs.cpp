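#include <RcppArmadillo.h>
#include <functional>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

arma::vec rnorm_vec(arma::uword n) {
  arma::vec z(n);
  for (arma::uword i = 0; i < n; ++i) z[i] = R::norm_rand();
  return z;
}

// Univariate slice sampler with shrinkage on a fixed bounded interval
// (lo, hi). Valid because the interval always contains the full slice.
double slice_bounded(const std::function<double(double)>& logf,
                     double x0, double lo, double hi) {
  const double ly = logf(x0) - R::exp_rand();  // log f(x0) + log U
  double L = lo, U = hi;
  for (int i = 0; i < 1000; ++i) {
    const double x1 = L + (U - L) * R::unif_rand();
    if (logf(x1) > ly) return x1;
    if (x1 < x0) L = x1; else U = x1;
  }
  return x0;  // pathological shrinkage; keep current value
}

}  // namespace

// Blocked Gibbs sampler for contrast-level NMA models.
//
// Likelihood: y ~ N(X d, V(tau)), V = Smat + tau^2 * Pmat (or, when all
// studies are two-arm, V = diag(s2 + tau^2)). Prior on the effect vector d:
// d ~ N(m, D C D) with C a fixed correlation matrix (identity, or 0.5
// within-class blocks for the symmetric models), D = diag(sd) where sd_j is
// either a fixed prior SD or a sampled class SD tau_d[g]. The prior mean m_j
// is 0, a fixed value, or a sampled class mean mu[g] ~ N(0, mu_prior_var).
//
// Updates per sweep: d | rest (conjugate MVN), mu | rest (conjugate normal),
// tau_d | rest and tau | rest (bounded slice on the SD scale).
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
arma::mat gibbs_nma_cpp(const arma::vec& y,
                        const arma::mat& X,
                        const arma::vec& s2,
                        const arma::mat& Smat,
                        const arma::mat& Pmat,
                        const bool diag_path,
                        const bool random_effects,
                        const double tau_upper,
                        const arma::mat& Cinv,
                        const arma::ivec& mu_map,
                        const double mu_prior_var,
                        const int n_mu,
                        const arma::ivec& tau_map,
                        const arma::vec& fixed_sd,
                        const arma::vec& fixed_mean,
                        const int n_tau,
                        const arma::ivec& tau_d_type,  // 0 unif, 1 half-normal, 2 fixed
                        const arma::vec& tau_d_par,
                        const int n_iter,
                        const int n_burn,
                        const int thin,
                        const arma::vec& d0,
                        const arma::vec& mu0,
                        const arma::vec& tau_d0,
                        const double tau0) {
  const arma::uword p = X.n_cols;
  const arma::uword n = y.n_elem;

  arma::vec d = d0;
  arma::vec mu = mu0;
  arma::vec tau_d = tau_d0;
  double tau = tau0;

  auto prior_sd = [&](arma::vec& sd) {
    for (arma::uword j = 0; j < p; ++j)
      sd[j] = (tau_map[j] >= 0) ? tau_d[tau_map[j]] : fixed_sd[j];
  };
  auto prior_mean = [&](arma::vec& m) {
    for (arma::uword j = 0; j < p; ++j)
      m[j] = (mu_map[j] >= 0) ? mu[mu_map[j]] : fixed_mean[j];
  };

  arma::mat A(p, p);   // X' V^-1 X
  arma::vec b(p);      // X' V^-1 y
  auto refresh_V = [&]() {
    if (diag_path) {
      const arma::vec vinv = 1.0 / (s2 + tau * tau);
      const arma::mat Xw = X.each_col() % vinv;
      A = X.t() * Xw;
      b = Xw.t() * y;
    } else {
      const arma::mat Vinv = arma::inv_sympd(Smat + tau * tau * Pmat);
      A = X.t() * Vinv * X;
      b = X.t() * Vinv * y;
    }
  };
  refresh_V();

  const int n_keep_iter = (n_iter - n_burn + thin - 1) / thin;
  const arma::uword ncol_out = p + n_mu + n_tau + (random_effects ? 1 : 0);
  arma::mat out(static_cast<arma::uword>(n_keep_iter), ncol_out);
  arma::uword row = 0;

  arma::vec sd(p), m(p);

  for (int iter = 0; iter < n_iter; ++iter) {
    // --- d | rest: conjugate multivariate normal ---------------------------
    prior_sd(sd);
    prior_mean(m);
    arma::mat Q = Cinv / (sd * sd.t());  // prior precision of d
    arma::mat Prec = A + Q;
    Prec = 0.5 * (Prec + Prec.t());
    const arma::mat L = arma::chol(Prec, "lower");
    const arma::vec rhs = b + Q * m;
    const arma::vec w = arma::solve(arma::trimatl(L), rhs);
    const arma::vec mean_d = arma::solve(arma::trimatu(L.t()), w);
    d = mean_d + arma::solve(arma::trimatu(L.t()), rnorm_vec(p));

    // --- class means mu | rest: conjugate normal ---------------------------
    // Q is block-diagonal across classes, so each mean only sees its block.
    for (int g = 0; g < n_mu; ++g) {
      const arma::uvec idx = arma::find(mu_map == g);
      const arma::mat Ag = Q.submat(idx, idx);
      const double prec = arma::accu(Ag) + 1.0 / mu_prior_var;
      const double lin = arma::accu(Ag * d.elem(idx));
      mu[g] = lin / prec + std::sqrt(1.0 / prec) * R::norm_rand();
      prior_mean(m);
    }

    // --- class prior SDs tau_d | rest: bounded slice -----------------------
    for (int g = 0; g < n_tau; ++g) {
      if (tau_d_type[g] == 2) continue;  // fixed
      const double par = tau_d_par[g];
      const double hi = (tau_d_type[g] == 0) ? par : 15.0 * par;
      auto logf = [&](double t) -> double {
        if (t < 1e-12 || t > hi) return -arma::datum::inf;
        arma::vec sdl = sd;
        for (arma::uword j = 0; j < p; ++j)
          if (tau_map[j] == g) sdl[j] = t;
        const arma::vec z = (d - m) / sdl;
        double lt = -0.5 * arma::as_scalar(z.t() * Cinv * z) -
                    arma::accu(arma::log(sdl));
        if (tau_d_type[g] == 1) lt += -0.5 * t * t / (par * par);
        return lt;
      };
      tau_d[g] = slice_bounded(logf, tau_d[g], 0.0, hi);
      prior_sd(sd);
    }

    // --- heterogeneity SD tau | rest: bounded slice ------------------------
    if (random_effects) {
      const arma::vec r = y - X * d;
      auto logf = [&](double t) -> double {
        if (t < 0.0 || t > tau_upper) return -arma::datum::inf;
        if (diag_path) {
          const arma::vec v = s2 + t * t;
          return -0.5 * arma::accu(arma::log(v)) -
                 0.5 * arma::accu(r % r / v);
        }
        const arma::mat V = Smat + t * t * Pmat;
        double ld, sign;
        arma::log_det(ld, sign, V);
        return -0.5 * ld - 0.5 * arma::as_scalar(r.t() * arma::solve(V, r));
      };
      tau = slice_bounded(logf, tau, 0.0, tau_upper);
      refresh_V();
    }

    // --- record ------------------------------------------------------------
    if (iter >= n_burn && (iter - n_burn) % thin == 0) {
      arma::uword c = 0;
      for (arma::uword j = 0; j < p; ++j) out(row, c++) = d[j];
      for (int g = 0; g < n_mu; ++g) out(row, c++) = mu[g];
      for (int g = 0; g < n_tau; ++g) out(row, c++) = tau_d[g];
      if (random_effects) out(row, c++) = tau;
      ++row;
    }
    (void)n;
  }
  return out.rows(0, row - 1);
}
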