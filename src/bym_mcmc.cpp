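// Metropolis-within-Gibbs sampler for the Besag-York-Mollie model:
//   Y_i ~ Poisson(E_i * exp(mu + X_i beta + S_i + V_i))
//   S   ~ ICAR(sigma_S) with per-component sum-to-zero (recentred each sweep)
//   V_i ~ Normal(0, sigma_V^2)
//   mu, beta ~ Normal(0, prior sd^2); sigma_S, sigma_V ~ half-Normal(0, sd^2)
// Islands (regions with no neighbours) have S_i fixed at zero.
// Random-walk scales are adapted during burn-in (target acceptance 0.44).

#include <Rcpp.h>
using namespace Rcpp;

// log of the (unnormalised) conditional density of log-sigma given the
// quadratic form ss with the given rank, under a half-Normal(0, s0) prior
static inline double lsig_target(double theta, double ss, double rank,
                                 double s0) {
  double sig2 = std::exp(2.0 * theta);
  // -rank*log(sigma) - ss/(2 sigma^2) - sigma^2/(2 s0^2) + Jacobian theta
  return -rank * theta - 0.5 * ss / sig2 - 0.5 * sig2 / (s0 * s0) + theta;
}

// univariate slice sampler with stepping out (Neal 2003)
static double slice_lsig(double theta, double ss, double rank, double s0,
                         double w) {
  double ly = lsig_target(theta, ss, rank, s0) + std::log(R::runif(0.0, 1.0));
  double L = theta - w * R::runif(0.0, 1.0);
  double Rr = L + w;
  for (int k = 0; k < 50 && lsig_target(L, ss, rank, s0) > ly; ++k) L -= w;
  for (int k = 0; k < 50 && lsig_target(Rr, ss, rank, s0) > ly; ++k) Rr += w;
  for (int k = 0; k < 100; ++k) {
    double prop = R::runif(L, Rr);
    if (lsig_target(prop, ss, rank, s0) >= ly) return prop;
    if (prop < theta) L = prop; else Rr = prop;
  }
  return theta;
}

// [[Rcpp::export(name = ".bym_mcmc_cpp")]]
List bym_mcmc_cpp(IntegerVector Y, NumericVector logE, NumericMatrix X,
                  IntegerVector adj, IntegerVector adj_start,
                  IntegerVector comp,
                  int n_iter, int burn_in, int thin,
                  double mu_prior_sd, double beta_prior_sd,
                  double sigma_prior_sd,
                  double sigma_s_fixed, double sigma_v_fixed,
                  double mu_init, NumericVector beta_init) {
  const int n = Y.size();
  const int p = X.ncol();
  int n_comp = 0;
  for (int i = 0; i < n; ++i) if (comp[i] + 1 > n_comp) n_comp = comp[i] + 1;
  std::vector<int> comp_size(n_comp, 0);
  int n_free = 0;  // non-island regions
  for (int i = 0; i < n; ++i) {
    if (comp[i] >= 0) { comp_size[comp[i]]++; n_free++; }
  }
  double rank_s = n_free - n_comp;  // rank of the ICAR precision

  double mu = mu_init;
  NumericVector beta(p);
  for (int k = 0; k < p; ++k) beta[k] = beta_init[k];
  NumericVector S(n, 0.0), V(n, 0.0);
  bool fix_s = sigma_s_fixed > 0.0, fix_v = sigma_v_fixed > 0.0;
  double sig_s = fix_s ? sigma_s_fixed : 0.5;
  double sig_v = fix_v ? sigma_v_fixed : 0.5;

  NumericVector xb(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < p; ++k) s += X(i, k) * beta[k];
    xb[i] = s;
  }
  // eta_i = mu + xb_i + S_i + V_i maintained incrementally
  NumericVector eta(n);
  for (int i = 0; i < n; ++i) eta[i] = mu + xb[i] + S[i] + V[i];

  double sc_mu = 0.1, sc_s = 0.5, sc_v = 0.5;
  NumericVector sc_beta(p, 0.1);
  double acc_mu = 0, try_mu = 0, acc_s = 0, try_s = 0, acc_v = 0, try_v = 0;
  NumericVector acc_beta(p), try_beta(p);
  double acc_mu_all = 0, acc_s_all = 0, acc_v_all = 0;
  double try_mu_all = 0, try_s_all = 0, try_v_all = 0;

  int n_keep = (n_iter - burn_in + thin - 1) / thin;
  if (n_keep < 1) stop("n_iter must exceed burn_in");
  NumericVector out_mu(n_keep), out_sig_s(n_keep), out_sig_v(n_keep);
  NumericMatrix out_beta(n_keep, p), out_S(n_keep, n), out_V(n_keep, n);
  int keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- mu: random-walk Metropolis on the full likelihood
    {
      double d = R::rnorm(0.0, sc_mu);
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        dll += Y[i] * d - std::exp(logE[i] + eta[i]) * (std::exp(d) - 1.0);
      }
      double mu2 = mu + d;
      dll += (mu * mu - mu2 * mu2) / (2.0 * mu_prior_sd * mu_prior_sd);
      try_mu++; try_mu_all++;
      if (std::log(R::runif(0.0, 1.0)) < dll) {
        mu = mu2; acc_mu++; acc_mu_all++;
        for (int i = 0; i < n; ++i) eta[i] += d;
      }
    }
    // --- beta: coordinate-wise random walk
    for (int k = 0; k < p; ++k) {
      double d = R::rnorm(0.0, sc_beta[k]);
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        double dd = d * X(i, k);
        dll += Y[i] * dd -
          std::exp(logE[i] + eta[i]) * (std::exp(dd) - 1.0);
      }
      double b2 = beta[k] + d;
      dll += (beta[k] * beta[k] - b2 * b2) /
        (2.0 * beta_prior_sd * beta_prior_sd);
      try_beta[k]++;
      if (std::log(R::runif(0.0, 1.0)) < dll) {
        beta[k] = b2; acc_beta[k]++;
        for (int i = 0; i < n; ++i) {
          double dd = d * X(i, k);
          xb[i] += dd; eta[i] += dd;
        }
      }
    }
    // --- S: single-site random walk with ICAR full conditional
    for (int i = 0; i < n; ++i) {
      if (comp[i] < 0) continue;  // island: S_i = 0
      int a0 = adj_start[i], a1 = adj_start[i + 1];
      int di = a1 - a0;
      double nbr_sum = 0.0;
      for (int a = a0; a < a1; ++a) nbr_sum += S[adj[a]];
      double pm = nbr_sum / di;                 // conditional prior mean
      double pv = sig_s * sig_s / di;           // conditional prior variance
      double d = R::rnorm(0.0, sc_s * std::sqrt(pv));
      double s2 = S[i] + d;
      double dll = Y[i] * d -
        std::exp(logE[i] + eta[i]) * (std::exp(d) - 1.0) +
        ((S[i] - pm) * (S[i] - pm) - (s2 - pm) * (s2 - pm)) / (2.0 * pv);
      try_s++; try_s_all++;
      if (std::log(R::runif(0.0, 1.0)) < dll) {
        S[i] = s2; eta[i] += d; acc_s++; acc_s_all++;
      }
    }
    // recentre S within each connected component (sum-to-zero)
    {
      std::vector<double> m(n_comp, 0.0);
      for (int i = 0; i < n; ++i) if (comp[i] >= 0) m[comp[i]] += S[i];
      for (int c = 0; c < n_comp; ++c) m[c] /= comp_size[c];
      for (int i = 0; i < n; ++i) {
        if (comp[i] >= 0) { S[i] -= m[comp[i]]; eta[i] -= m[comp[i]]; }
      }
    }
    // --- V: per-site random walk (conditionally independent sites)
    for (int i = 0; i < n; ++i) {
      double d = R::rnorm(0.0, sc_v * sig_v);
      double v2 = V[i] + d;
      double dll = Y[i] * d -
        std::exp(logE[i] + eta[i]) * (std::exp(d) - 1.0) +
        (V[i] * V[i] - v2 * v2) / (2.0 * sig_v * sig_v);
      try_v++; try_v_all++;
      if (std::log(R::runif(0.0, 1.0)) < dll) {
        V[i] = v2; eta[i] += d; acc_v++; acc_v_all++;
      }
    }
    // --- variance parameters (slice sampling on log sigma)
    if (!fix_s) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int a = adj_start[i]; a < adj_start[i + 1]; ++a) {
          int j = adj[a];
          if (j > i) ss += (S[i] - S[j]) * (S[i] - S[j]);
        }
      }
      double th = slice_lsig(std::log(sig_s), ss, rank_s,
                             sigma_prior_sd, 1.0);
      sig_s = std::exp(th);
    }
    if (!fix_v) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += V[i] * V[i];
      double th = slice_lsig(std::log(sig_v), ss, (double) n,
                             sigma_prior_sd, 1.0);
      sig_v = std::exp(th);
    }
    // --- adapt proposal scales during burn-in
    if (it < burn_in && (it + 1) % 50 == 0) {
      auto tune = [](double &sc, double acc, double tries) {
        if (tries > 0) {
          double r = acc / tries;
          sc *= std::exp(r > 0.44 ? 0.1 : -0.1);
          sc = std::min(std::max(sc, 1e-4), 50.0);
        }
      };
      tune(sc_mu, acc_mu, try_mu);
      tune(sc_s, acc_s, try_s);
      tune(sc_v, acc_v, try_v);
      for (int k = 0; k < p; ++k) {
        tune(sc_beta[k], acc_beta[k], try_beta[k]);
        acc_beta[k] = try_beta[k] = 0;
      }
      acc_mu = try_mu = acc_s = try_s = acc_v = try_v = 0;
    }
    // --- store
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      out_mu[keep] = mu;
      out_sig_s[keep] = sig_s;
      out_sig_v[keep] = sig_v;
      for (int k = 0; k < p; ++k) out_beta(keep, k) = beta[k];
      for (int i = 0; i < n; ++i) {
        out_S(keep, i) = S[i];
        out_V(keep, i) = V[i];
      }
      keep++;
    }
  }

  return List::create(
    _["mu"] = out_mu, _["beta"] = out_beta,
    _["sigma_S"] = out_sig_s, _["sigma_V"] = out_sig_v,
    _["S"] = out_S, _["V"] = out_V,
    _["acc_rates"] = NumericVector::create(
      _["mu"] = try_mu_all > 0 ? acc_mu_all / try_mu_all : NA_REAL,
      _["S"] = try_s_all > 0 ? acc_s_all / try_s_all : NA_REAL,
      _["V"] = try_v_all > 0 ? acc_v_all / try_v_all : NA_REAL));
}
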