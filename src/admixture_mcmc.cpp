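// Gibbs/Metropolis sampler for the admixture model with correlated allele
// frequencies (F-model): each cluster's frequencies are Dirichlet-distributed
// around inferred ancestral frequencies with cluster-specific drift F_k.
// Latent allele-copy origins z are Gibbs-sampled; q ~ Dirichlet(alpha + n_ik);
// p_kl ~ Dirichlet(pA_l (1-F_k)/F_k + counts); pA, F_k and alpha move by
// Metropolis. Uses R's RNG so results are reproducible via set.seed().
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int sample_cat(const double *w, int K, double tot) {
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
List admixture_mcmc_cpp(IntegerMatrix geno,   // n x 2L allele indices (1-based), NA = missing
                        IntegerVector n_alleles, // per-locus allele counts J_l
                        int K, int burnin, int iters, int thin,
                        double alpha_init, double lambda,
                        double alpha_step, double alpha_max,
                        double f_init, double f_prior_mean, double f_prior_sd,
                        double f_step, double pa_step) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("genotype matrix must be n x 2L");
  if (K < 1) stop("K must be >= 1");

  RNGScope scope;

  // state
  std::vector<std::vector<double>> P(L), pA(L); // P[l]: K*J_l (k-major), pA[l]: J_l
  std::vector<double> F(K, f_init);
  NumericMatrix q(n, K);
  IntegerMatrix z(n, 2 * L);
  double alpha = alpha_init;

  // init: pA from pooled counts + lambda; P = pA; q uniform; z random
  for (int l = 0; l < L; ++l) {
    int J = n_alleles[l];
    pA[l].assign(J, 0.0);
    double tot = 0.0;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 2; ++c) {
        int a = geno(i, 2 * l + c);
        if (a != NA_INTEGER) { pA[l][a - 1] += 1.0; }
      }
    for (int j = 0; j < J; ++j) { pA[l][j] += lambda; tot += pA[l][j]; }
    for (int j = 0; j < J; ++j) pA[l][j] /= tot;
    P[l].assign((size_t)K * J, 0.0);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j) P[l][(size_t)k * J + j] = pA[l][j];
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < 2 * L; ++m)
      z(i, m) = (int)(unif_rand() * K);

  // accumulators
  NumericMatrix q_sum(n, K);
  std::vector<std::vector<double>> p_sum(L);
  for (int l = 0; l < L; ++l) p_sum[l].assign((size_t)K * n_alleles[l], 0.0);
  std::vector<double> lnl_samples, alpha_samples, lnl_trace;
  int n_kept = 0;
  long acc_alpha = 0, try_alpha = 0, acc_f = 0, try_f = 0, acc_pa = 0, try_pa = 0;

  std::vector<double> w(K), nik((size_t)n * K);
  const int total_iters = burnin + iters;

  for (int it = 0; it < total_iters; ++it) {
    // --- z | q, P  and sufficient statistics ---
    std::fill(nik.begin(), nik.end(), 0.0);
    std::vector<std::vector<double>> counts(L);
    for (int l = 0; l < L; ++l) counts[l].assign((size_t)K * n_alleles[l], 0.0);
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int J = n_alleles[l];
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a == NA_INTEGER) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = q(i, k) * P[l][(size_t)k * J + (a - 1)];
            tot += w[k];
          }
          int k = (tot > 0) ? sample_cat(w.data(), K, tot) : (int)(unif_rand() * K);
          z(i, 2 * l + c) = k;
          nik[(size_t)i * K + k] += 1.0;
          counts[l][(size_t)k * J + (a - 1)] += 1.0;
        }
      }
    }

    // --- q | z ---
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + nik[(size_t)i * K + k], 1.0);
        if (g < 1e-300) g = 1e-300;
        q(i, k) = g; tot += g;
      }
      for (int k = 0; k < K; ++k) q(i, k) /= tot;
    }

    // --- P | z, pA, F ---
    for (int l = 0; l < L; ++l) {
      int J = n_alleles[l];
      for (int k = 0; k < K; ++k) {
        double r = (1.0 - F[k]) / F[k];
        double tot = 0.0;
        for (int j = 0; j < J; ++j) {
          double g = R::rgamma(pA[l][j] * r + counts[l][(size_t)k * J + j], 1.0);
          if (g < 1e-300) g = 1e-300;
          P[l][(size_t)k * J + j] = g; tot += g;
        }
        for (int j = 0; j < J; ++j) P[l][(size_t)k * J + j] /= tot;
      }
    }

    // --- pA | P, F: move mass between two random alleles per locus ---
    for (int l = 0; l < L; ++l) {
      int J = n_alleles[l];
      if (J < 2) continue;
      for (int rep = 0; rep < J; ++rep) {
        ++try_pa;
        int a = (int)(unif_rand() * J), b = (int)(unif_rand() * J);
        if (a == b) continue;
        double d = unif_rand() * pa_step;
        double na_ = pA[l][a] + d, nb_ = pA[l][b] - d;
        if (nb_ <= 1e-9 || na_ >= 1.0 - 1e-9) continue;
        double lr = (lambda - 1.0) * (std::log(na_) - std::log(pA[l][a]) +
                                      std::log(nb_) - std::log(pA[l][b]));
        for (int k = 0; k < K; ++k) {
          double r = (1.0 - F[k]) / F[k];
          double pka = P[l][(size_t)k * J + a], pkb = P[l][(size_t)k * J + b];
          lr += (na_ - pA[l][a]) * r * std::log(pka)
              + (nb_ - pA[l][b]) * r * std::log(pkb)
              - R::lgammafn(na_ * r) + R::lgammafn(pA[l][a] * r)
              - R::lgammafn(nb_ * r) + R::lgammafn(pA[l][b] * r);
        }
        if (std::log(unif_rand()) < lr) {
          pA[l][a] = na_; pA[l][b] = nb_; ++acc_pa;
        }
      }
    }

    // --- F_k | P, pA ---
    for (int k = 0; k < K; ++k) {
      ++try_f;
      double fp = F[k] + norm_rand() * f_step;
      if (fp <= 1e-5 || fp >= 1.0 - 1e-5) continue;
      double r_old = (1.0 - F[k]) / F[k], r_new = (1.0 - fp) / fp;
      double lr = R::dnorm(fp, f_prior_mean, f_prior_sd, 1)
                - R::dnorm(F[k], f_prior_mean, f_prior_sd, 1);
      for (int l = 0; l < L; ++l) {
        int J = n_alleles[l];
        double lg_new = 0.0, lg_old = 0.0, s_new = 0.0, s_old = 0.0;
        for (int j = 0; j < J; ++j) {
          double an = pA[l][j] * r_new, ao = pA[l][j] * r_old;
          double lp = std::log(P[l][(size_t)k * J + j]);
          lg_new += (an - 1.0) * lp - R::lgammafn(an); s_new += an;
          lg_old += (ao - 1.0) * lp - R::lgammafn(ao); s_old += ao;
        }
        lr += lg_new + R::lgammafn(s_new) - lg_old - R::lgammafn(s_old);
      }
      if (std::log(unif_rand()) < lr) { F[k] = fp; ++acc_f; }
    }

    // --- alpha | q ---
    if (K > 1) {
      ++try_alpha;
      double ap = alpha + (unif_rand() * 2.0 - 1.0) * alpha_step;
      if (ap > 1e-4 && ap < alpha_max) {
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) slq += std::log(q(i, k));
        double lr = n * (R::lgammafn(K * ap) - K * R::lgammafn(ap)
                       - R::lgammafn(K * alpha) + K * R::lgammafn(alpha))
                  + (ap - alpha) * slq;
        if (std::log(unif_rand()) < lr) { alpha = ap; ++acc_alpha; }
      }
    }

    // --- bookkeeping ---
    // data log-likelihood every post-burn-in iteration (the lnPD variance
    // penalty needs a stable variance estimate); thinned during burn-in
    bool want_lnl = (it >= burnin) || ((it + 1) % thin == 0);
    double lnl = 0.0;
    if (want_lnl) {
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l) {
          int J = n_alleles[l];
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a == NA_INTEGER) continue;
            double pr = 0.0;
            for (int k = 0; k < K; ++k)
              pr += q(i, k) * P[l][(size_t)k * J + (a - 1)];
            lnl += std::log(pr > 1e-300 ? pr : 1e-300);
          }
        }
      if (it >= burnin) lnl_samples.push_back(lnl);
    }
    if ((it + 1) % thin == 0) {
      lnl_trace.push_back(lnl);
      if (it >= burnin) {
        alpha_samples.push_back(alpha);
        ++n_kept;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) q_sum(i, k) += q(i, k);
        for (int l = 0; l < L; ++l)
          for (size_t m = 0; m < P[l].size(); ++m) p_sum[l][m] += P[l][m];
      }
    }
  }

  if (n_kept == 0) stop("no post-burn-in samples retained; increase iterations");
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) q_sum(i, k) /= n_kept;
  List p_out(L);
  for (int l = 0; l < L; ++l) {
    int J = n_alleles[l];
    NumericMatrix pm(K, J);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j) pm(k, j) = p_sum[l][(size_t)k * J + j] / n_kept;
    p_out[l] = pm;
  }

  return List::create(
    _["Q"] = q_sum, _["P"] = p_out,
    _["lnl"] = NumericVector(lnl_samples.begin(), lnl_samples.end()),
    _["lnl_trace"] = NumericVector(lnl_trace.begin(), lnl_trace.end()),
    _["alpha"] = NumericVector(alpha_samples.begin(), alpha_samples.end()),
    _["F"] = NumericVector(F.begin(), F.end()),
    _["accept"] = NumericVector::create(
      _["alpha"] = try_alpha ? (double)acc_alpha / try_alpha : NA_REAL,
      _["F"] = try_f ? (double)acc_f / try_f : NA_REAL,
      _["pA"] = try_pa ? (double)acc_pa / try_pa : NA_REAL));
}
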