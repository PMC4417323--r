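// Component-wise spike-and-slab Gibbs sampler core.
//
// Per sweep: for each SNP j, the inclusion indicator I_j is drawn from its
// full conditional with b_j integrated out (collapsed update), then
// b_j | I_j is drawn from its normal full conditional (exact zero, or a
// small-variance normal when spike_sd > 0); then the fixed effects, the two
// variances and the mixture probability. The residual r = y - X beta - W b
// is maintained incrementally, O(n) per SNP.
//
// All randomness goes through R's RNG so chains are reproducible with
// set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double VAR_MIN = 1e-12;
static const double VAR_MAX = 1e12;

static inline double rinvgamma(double shape, double rate) {
  double g = R::rgamma(shape, 1.0 / rate);   // R::rgamma takes scale
  double v = 1.0 / g;
  if (!std::isfinite(v) || v > VAR_MAX) v = VAR_MAX;
  if (v < VAR_MIN) v = VAR_MIN;
  return v;
}

// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
List gibbs_chain_cpp(const arma::vec& y,
                     const arma::mat& X,
                     const arma::mat& W,
                     List priors,
                     List cfg,
                     List init) {
  const int n = W.n_rows, N = W.n_cols, q = X.n_cols;

  const double p_alpha   = priors["p_alpha"];
  const double p_beta    = priors["p_beta"];
  const double a1        = priors["a1"], b1 = priors["b1"];
  const double a2        = priors["a2"], b2 = priors["b2"];
  const double beta_sd   = priors["beta_sd"];
  const double spike_sd  = priors["spike_sd"];
  const double spike_var = spike_sd * spike_sd;

  const int n_burnin  = cfg["n_burnin"];
  const int n_keep    = cfg["n_keep"];
  const int thinning  = cfg["thinning"];
  const bool random_scan = cfg["random_scan"];
  const bool fix_p        = cfg["fix_p"];
  const bool fix_sigma_b2 = cfg["fix_sigma_b2"];
  const bool fix_sigma_e2 = cfg["fix_sigma_e2"];
  const bool fix_beta     = cfg["fix_beta"];

  arma::vec beta = as<arma::vec>(init["beta"]);
  arma::vec b    = as<arma::vec>(init["b"]);
  arma::ivec I   = as<arma::ivec>(init["I"]);
  double p        = init["p"];
  double sigma_b2 = init["sigma_b2"];
  double sigma_e2 = init["sigma_e2"];

  arma::vec r = y - W * b;
  if (q > 0) r -= X * beta;

  arma::vec wtw(N);
  for (int j = 0; j < N; ++j) wtw[j] = arma::dot(W.col(j), W.col(j));

  arma::mat XtX;
  if (q > 0) XtX = X.t() * X;

  const int total = n_burnin + n_keep * thinning;
  arma::mat keep_b(N, n_keep);
  arma::imat keep_I(N, n_keep);
  arma::mat keep_beta(std::max(q, 1), n_keep, arma::fill::zeros);
  arma::vec keep_p(n_keep), keep_sb2(n_keep), keep_se2(n_keep),
            keep_k(n_keep), keep_varg(n_keep);

  arma::uvec order = arma::regspace<arma::uvec>(0, N - 1);
  int stored = 0;

  for (int it = 0; it < total; ++it) {
    if (random_scan) {
      // Fisher-Yates with R's RNG for reproducibility
      for (int j = N - 1; j > 0; --j) {
        int k = (int)std::floor(unif_rand() * (j + 1));
        if (k > j) k = j;
        std::swap(order[j], order[k]);
      }
    }

    // --- indicator and effect, component-wise ---
    const double log_prior_odds = std::log(p) - std::log1p(-p);
    for (int jj = 0; jj < N; ++jj) {
      const int j = order[jj];
      if (b[j] != 0.0) r += W.col(j) * b[j];   // partial residual incl. j
      const double z  = arma::dot(W.col(j), r) / sigma_e2;
      const double d1 = wtw[j] / sigma_e2 + 1.0 / sigma_b2;
      const double lm1 = -0.5 * std::log(sigma_b2 * d1) + 0.5 * z * z / d1;
      double lm0 = 0.0, d0 = 0.0;
      if (spike_var > 0.0) {
        d0 = wtw[j] / sigma_e2 + 1.0 / spike_var;
        lm0 = -0.5 * std::log(spike_var * d0) + 0.5 * z * z / d0;
      }
      const double logit = log_prior_odds + lm1 - lm0;
      double prob1;
      if (logit > 0) prob1 = 1.0 / (1.0 + std::exp(-logit));
      else           prob1 = std::exp(logit) / (1.0 + std::exp(logit));
      const bool active = unif_rand() < prob1;
      double bnew = 0.0;
      if (active) {
        bnew = z / d1 + norm_rand() / std::sqrt(d1);
        I[j] = 1;
      } else {
        I[j] = 0;
        if (spike_var > 0.0) bnew = z / d0 + norm_rand() / std::sqrt(d0);
      }
      if (bnew != 0.0) r -= W.col(j) * bnew;
      b[j] = bnew;
    }

    // --- fixed effects ---
    if (q > 0 && !fix_beta) {
      arma::vec rb = r + X * beta;             // y - W b
      arma::mat P = XtX / sigma_e2;
      P.diag() += 1.0 / (beta_sd * beta_sd);
      arma::vec m = arma::solve(P, X.t() * rb / sigma_e2,
                                arma::solve_opts::likely_sympd);
      arma::mat U = arma::chol(P);             // P = U'U
      arma::vec zq(q);
      for (int i = 0; i < q; ++i) zq[i] = norm_rand();
      beta = m + arma::solve(arma::trimatu(U), zq);
      r = rb - X * beta;
    }

    // --- variances ---
    int kact = 0; double ssb = 0.0;
    for (int j = 0; j < N; ++j)
      if (I[j] == 1) { ++kact; ssb += b[j] * b[j]; }
    if (!fix_sigma_b2)
      sigma_b2 = rinvgamma(a1 + 0.5 * kact, b1 + 0.5 * ssb);
    if (!fix_sigma_e2)
      sigma_e2 = rinvgamma(a2 + 0.5 * n, b2 + 0.5 * arma::dot(r, r));

    // --- mixture probability ---
    if (!fix_p) {
      p = R::rbeta(p_alpha + kact, p_beta + N - kact);
      if (p < 1e-12) p = 1e-12;
      if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    }

    if (it >= n_burnin && (it - n_burnin) % thinning == 0 && stored < n_keep) {
      keep_b.col(stored) = b;
      keep_I.col(stored) = I;
      if (q > 0) keep_beta.col(stored) = beta;
      keep_p[stored] = p;
      keep_sb2[stored] = sigma_b2;
      keep_se2[stored] = sigma_e2;
      keep_k[stored] = kact;
      arma::vec g = y - r;                     // X beta + W b
      if (q > 0) g -= X * beta;                // genetic values W b
      keep_varg[stored] = arma::var(g);
      ++stored;
    }
  }

  if (!r.is_finite() || !std::isfinite(sigma_e2))
    stop("non-finite state encountered in Gibbs sampler (sigma_e2 = %g)", sigma_e2);

  return List::create(
    _["b"] = keep_b, _["I"] = keep_I, _["beta"] = keep_beta,
    _["p"] = keep_p, _["sigma_b2"] = keep_sb2, _["sigma_e2"] = keep_se2,
    _["k_active"] = keep_k, _["var_g"] = keep_varg,
    _["final_r"] = r,
    _["final_state"] = List::create(
      _["beta"] = beta, _["b"] = b, _["I"] = I, _["p"] = p,
      _["sigma_b2"] = sigma_b2, _["sigma_e2"] = sigma_e2));
}
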