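#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for a GLM with an intrinsic CAR spatial
// effect:
//   eta_i = alpha + x_i' beta + phi_i
//   y_i ~ Bernoulli(logit^-1(eta_i))   (family = 0)
//   y_i ~ Poisson(exp(eta_i))          (family = 1)
// Priors: alpha improper uniform; beta_j ~ N(0, coef_prior_var);
// phi ~ ICAR(tau) with per-component sum-to-zero; tau ~ Gamma(shape, rate).
//
// tau has a conjugate Gamma full conditional with
//   shape = prior_shape + (n_eff - C)/2,
//   rate  = prior_rate + 0.5 * sum_{i~j} (phi_i - phi_j)^2
// (n_eff = non-isolated nodes, C = their number of connected components).
// phi_i is updated by single-site random-walk Metropolis around its full
// conditional (prior mean = neighbor average, prior variance 1/(tau m_i));
// alpha and beta by adaptive random-walk Metropolis. After every sweep phi
// is recentered: the global mean moves into alpha (likelihood-invariant
// when the graph is connected) and each component is centered.
// Isolated nodes carry phi = 0. Uses R's RNG, so set.seed() governs.

static inline double loglik_one(double eta, double y, int family) {
  if (family == 0) {
    // log Bernoulli-logit, stable for |eta| large
    if (eta > 0) return y * eta - eta - log1p(exp(-eta));
    return y * eta - log1p(exp(eta));
  }
  return y * eta - exp(eta); // Poisson-log, dropping log(y!)
}

static double loglik_all(const NumericVector& eta, const NumericVector& y,
                         int family) {
  double s = 0.0;
  for (int i = 0; i < eta.size(); ++i) s += loglik_one(eta[i], y[i], family);
  return s;
}

// [[Rcpp::export]]
List icar_mcmc_chain(NumericVector y, NumericMatrix X, int family,
                     IntegerVector adj, IntegerVector adj_ptr,
                     IntegerVector comp, int iterations, int burn_in,
                     int thin, double coef_prior_var, double tau_shape,
                     double tau_rate, double alpha0, NumericVector beta0,
                     double tau0, NumericVector phi0, bool phi_enabled,
                     int phi_store_thin) {
  int n = y.size();
  int p = X.ncol();

  NumericVector beta = clone(beta0);
  NumericVector phi = clone(phi0);
  double alpha = alpha0;
  double tau = tau0;

  IntegerVector m(n);
  for (int i = 0; i < n; ++i) m[i] = adj_ptr[i + 1] - adj_ptr[i];

  // components among non-isolated nodes, and their sizes
  int n_comp = 0;
  for (int i = 0; i < n; ++i) if (comp[i] + 1 > n_comp) n_comp = comp[i] + 1;
  std::vector<int> comp_size(n_comp, 0);
  int n_eff = 0, c_eff = 0;
  for (int i = 0; i < n; ++i) if (m[i] > 0) { comp_size[comp[i]]++; n_eff++; }
  for (int c = 0; c < n_comp; ++c) if (comp_size[c] > 0) c_eff++;

  NumericVector eta(n);
  for (int i = 0; i < n; ++i) {
    double xb = 0.0;
    for (int j = 0; j < p; ++j) xb += X(i, j) * beta[j];
    eta[i] = alpha + xb + (phi_enabled ? phi[i] : 0.0);
  }

  int n_keep = (iterations - burn_in) / thin;
  NumericMatrix samples(n_keep, p + 2); // alpha, beta..., tau
  int n_phi_keep = phi_enabled ? n_keep / std::max(phi_store_thin, 1) : 0;
  NumericMatrix phi_samples(std::max(n_phi_keep, 1), phi_enabled ? n : 1);

  // adaptive proposal scales
  double s_alpha = 0.1;
  NumericVector s_beta(p, 0.1);
  double s_phi = 0.5;
  double acc_alpha = 0, try_alpha = 0, acc_phi = 0, try_phi = 0;
  NumericVector acc_beta(p), try_beta(p);
  double tot_acc_alpha = 0, tot_try_alpha = 0, tot_acc_phi = 0, tot_try_phi = 0;
  double tot_acc_beta = 0, tot_try_beta = 0;

  int keep = 0, phi_keep = 0, kept_since_phi = 0;
  double cur_ll = loglik_all(eta, y, family);

  for (int it = 1; it <= iterations; ++it) {
    // alpha (flat prior)
    {
      double d = R::norm_rand() * s_alpha;
      double new_ll = 0.0;
      for (int i = 0; i < n; ++i) new_ll += loglik_one(eta[i] + d, y[i], family);
      try_alpha++;
      if (log(R::unif_rand()) < new_ll - cur_ll) {
        alpha += d;
        for (int i = 0; i < n; ++i) eta[i] += d;
        cur_ll = new_ll;
        acc_alpha++;
      }
    }
    // beta
    for (int j = 0; j < p; ++j) {
      double d = R::norm_rand() * s_beta[j];
      double new_ll = 0.0;
      for (int i = 0; i < n; ++i) new_ll += loglik_one(eta[i] + d * X(i, j), y[i], family);
      double bn = beta[j] + d;
      double dprior = (beta[j] * beta[j] - bn * bn) / (2.0 * coef_prior_var);
      try_beta[j]++;
      if (log(R::unif_rand()) < new_ll - cur_ll + dprior) {
        beta[j] = bn;
        for (int i = 0; i < n; ++i) eta[i] += d * X(i, j);
        cur_ll = new_ll;
        acc_beta[j]++;
      }
    }
    // phi: single-site Metropolis, alternating a random-walk proposal with
    // an independence proposal from the ICAR full conditional
    // N(neighbor mean, 1/(tau m_i)) — for the latter the prior terms cancel
    // and the acceptance ratio is the likelihood ratio alone.
    if (phi_enabled) {
      bool use_prior_prop = (it % 2 == 0);
      for (int i = 0; i < n; ++i) {
        if (m[i] == 0) continue; // isolated: phi fixed at 0
        double nbr_mean = 0.0;
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) nbr_mean += phi[adj[k]];
        nbr_mean /= m[i];
        double pn, logr;
        double dll;
        if (use_prior_prop) {
          // independence proposal N(nbr_mean, sd_p), sd_p the full-conditional
          // prior sd capped at 1 (the cap keeps proposals sane when tau is
          // small; the q-ratio term then pulls stray phi back to the mean)
          double sd_p = 1.0 / sqrt(tau * m[i]);
          if (sd_p > 1.0) sd_p = 1.0;
          pn = nbr_mean + R::norm_rand() * sd_p;
          dll = loglik_one(eta[i] + (pn - phi[i]), y[i], family) -
                loglik_one(eta[i], y[i], family);
          double dn = (pn - nbr_mean) * (pn - nbr_mean);
          double dold = (phi[i] - nbr_mean) * (phi[i] - nbr_mean);
          double dprior = -0.5 * tau * m[i] * (dn - dold);
          double dprop = 0.5 * (dn - dold) / (sd_p * sd_p);
          logr = dll + dprior + dprop;
        } else {
          pn = phi[i] + R::norm_rand() * s_phi;
          dll = loglik_one(eta[i] + (pn - phi[i]), y[i], family) -
                loglik_one(eta[i], y[i], family);
          double dprior = -0.5 * tau * m[i] *
            ((pn - nbr_mean) * (pn - nbr_mean) -
             (phi[i] - nbr_mean) * (phi[i] - nbr_mean));
          logr = dll + dprior;
          try_phi++;
        }
        if (log(R::unif_rand()) < logr) {
          eta[i] += pn - phi[i];
          phi[i] = pn;
          cur_ll += dll;
          if (!use_prior_prop) acc_phi++;
        }
      }
      // recenter: global mean into alpha, then per-component centering
      double gmean = 0.0;
      for (int i = 0; i < n; ++i) if (m[i] > 0) gmean += phi[i];
      gmean /= std::max(n_eff, 1);
      alpha += gmean;
      std::vector<double> cmean(n_comp, 0.0);
      for (int i = 0; i < n; ++i) if (m[i] > 0) cmean[comp[i]] += phi[i];
      for (int c = 0; c < n_comp; ++c)
        if (comp_size[c] > 0) cmean[c] /= comp_size[c];
      for (int i = 0; i < n; ++i)
        if (m[i] > 0) phi[i] -= cmean[comp[i]];
      // recompute eta exactly (also avoids numerical drift)
      for (int i = 0; i < n; ++i) {
        double xb = 0.0;
        for (int j = 0; j < p; ++j) xb += X(i, j) * beta[j];
        eta[i] = alpha + xb + (m[i] > 0 ? phi[i] : 0.0);
      }
      cur_ll = loglik_all(eta, y, family);

      // tau: conjugate Gamma full conditional
      double ssq = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
          int j = adj[k];
          if (j > i) { double df = phi[i] - phi[j]; ssq += df * df; }
        }
      tau = R::rgamma(tau_shape + 0.5 * (n_eff - c_eff), 1.0 / (tau_rate + 0.5 * ssq));
    }

    // adapt proposal scales during burn-in
    if (it <= burn_in && it % 100 == 0) {
      if (try_alpha > 0) {
        s_alpha *= exp(((acc_alpha / try_alpha) - 0.44) * 0.5);
        tot_acc_alpha += acc_alpha; tot_try_alpha += try_alpha;
        acc_alpha = try_alpha = 0;
      }
      for (int j = 0; j < p; ++j) if (try_beta[j] > 0) {
        s_beta[j] *= exp(((acc_beta[j] / try_beta[j]) - 0.44) * 0.5);
        tot_acc_beta += acc_beta[j]; tot_try_beta += try_beta[j];
        acc_beta[j] = try_beta[j] = 0;
      }
      if (try_phi > 0) {
        s_phi *= exp(((acc_phi / try_phi) - 0.44) * 0.5);
        tot_acc_phi += acc_phi; tot_try_phi += try_phi;
        acc_phi = try_phi = 0;
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      samples(keep, 0) = alpha;
      for (int j = 0; j < p; ++j) samples(keep, j + 1) = beta[j];
      samples(keep, p + 1) = tau;
      if (phi_enabled && n_phi_keep > 0) {
        kept_since_phi++;
        if (kept_since_phi == phi_store_thin && phi_keep < n_phi_keep) {
          for (int i = 0; i < n; ++i) phi_samples(phi_keep, i) = phi[i];
          phi_keep++;
          kept_since_phi = 0;
        }
      }
      keep++;
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  tot_acc_alpha += acc_alpha; tot_try_alpha += try_alpha;
  tot_acc_phi += acc_phi; tot_try_phi += try_phi;
  for (int j = 0; j < p; ++j) { tot_acc_beta += acc_beta[j]; tot_try_beta += try_beta[j]; }

  return List::create(
    _["samples"] = samples,
    _["phi_samples"] = phi_samples,
    _["n_phi_kept"] = phi_keep,
    _["accept"] = NumericVector::create(
      _["alpha"] = tot_try_alpha > 0 ? tot_acc_alpha / tot_try_alpha : NA_REAL,
      _["beta"] = tot_try_beta > 0 ? tot_acc_beta / tot_try_beta : NA_REAL,
      _["phi"] = tot_try_phi > 0 ? tot_acc_phi / tot_try_phi : NA_REAL));
}
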