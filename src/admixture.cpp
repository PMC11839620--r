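#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dirichlet log-density up to nothing (full normalizing constant included).
// p entries are assumed > 0 (the sampler floors them after each draw).
static double ddirichlet_log(const double *alpha, const double *p, int A) {
  double s = 0.0, lg = 0.0, kern = 0.0;
  for (int a = 0; a < A; ++a) {
    s += alpha[a];
    lg += R::lgammafn(alpha[a]);
    kern += (alpha[a] - 1.0) * std::log(p[a]);
  }
  return R::lgammafn(s) - lg + kern;
}

static void draw_dirichlet(const double *alpha, double *out, int A) {
  double tot = 0.0;
  for (int a = 0; a < A; ++a) {
    double g = R::rgamma(alpha[a], 1.0);
    if (g < 1e-300) g = 1e-300;
    out[a] = g;
    tot += g;
  }
  for (int a = 0; a < A; ++a) {
    out[a] /= tot;
    if (out[a] < 1e-12) out[a] = 1e-12; // keep logs finite
  }
  // renormalize after flooring
  tot = 0.0;
  for (int a = 0; a < A; ++a) tot += out[a];
  for (int a = 0; a < A; ++a) out[a] /= tot;
}

// Gibbs sampler for the admixture model with correlated allele frequencies.
// geno: n x 2L matrix of allele indices (1-based per locus), 0 = missing.
// Cluster frequencies P_{kl.} ~ Dirichlet(PA_l (1-F_k)/F_k); ancestry
// Q_i ~ Dirichlet(alpha); latent per-copy origins are integrated by
// resampling them each sweep. PA (ancestral frequencies), F_k (cluster
// drift) and alpha get Metropolis updates. Uses R's RNG throughout, so a
// set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
List admixture_gibbs(IntegerMatrix geno, IntegerVector n_alleles, int K,
                     int burnin, int iters, int thin, double lambda,
                     double f_prior_mean, double f_prior_sd,
                     double f_prop_sd, double alpha_init, double alpha_max,
                     double alpha_prop_sd) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("geno must have 2 columns per locus");
  int Amax = 0;
  for (int l = 0; l < L; ++l) Amax = std::max(Amax, (int)n_alleles[l]);

  auto idxP = [&](int k, int l) { return (k * L + l) * Amax; };

  std::vector<double> P((size_t)K * L * Amax, 0.0);
  std::vector<double> PA((size_t)L * Amax, 0.0);
  std::vector<double> F(K, 0.05);
  std::vector<double> Q((size_t)n * K, 1.0 / K);
  double alpha = alpha_init;

  for (int l = 0; l < L; ++l)
    for (int a = 0; a < n_alleles[l]; ++a) {
      PA[l * Amax + a] = 1.0 / n_alleles[l];
      for (int k = 0; k < K; ++k) P[idxP(k, l) + a] = 1.0 / n_alleles[l];
    }

  std::vector<double> countQ((size_t)n * K);
  std::vector<double> countP((size_t)K * L * Amax);
  std::vector<double> Qsum((size_t)n * K, 0.0);
  std::vector<double> Psum((size_t)K * L * Amax, 0.0);
  std::vector<double> Fsum(K, 0.0);
  double alphasum = 0.0;

  const int total = burnin + iters;
  const int n_rec = iters / thin;
  NumericVector trace(n_rec);
  int rec = 0;
  std::vector<double> w(K), prop(Amax), shape(Amax);

  for (int sweep = 0; sweep < total; ++sweep) {
    bool record = sweep >= burnin && ((sweep - burnin + 1) % thin == 0);
    std::fill(countQ.begin(), countQ.end(), 0.0);
    std::fill(countP.begin(), countP.end(), 0.0);
    double loglik = 0.0;

    // latent origins: sample z for every typed allele copy
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < 2 * L; ++c) {
        int a = geno(i, c);
        if (a == 0) continue;
        int l = c / 2;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          w[k] = Q[i * K + k] * P[idxP(k, l) + a - 1];
          tot += w[k];
        }
        if (record) loglik += std::log(tot);
        int k = K - 1;
        if (K > 1) {
          double u = unif_rand() * tot, acc = 0.0;
          for (int kk = 0; kk < K; ++kk) {
            acc += w[kk];
            if (u <= acc) { k = kk; break; }
          }
        } else k = 0;
        countQ[i * K + k] += 1.0;
        countP[idxP(k, l) + a - 1] += 1.0;
      }
    }

    // Q | z
    if (K > 1) {
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < K; ++k) shape[k] = alpha + countQ[i * K + k];
        draw_dirichlet(shape.data(), prop.data(), K);
        for (int k = 0; k < K; ++k) Q[i * K + k] = prop[k];
      }
    }

    // P | z, PA, F  (conjugate Dirichlet)
    for (int k = 0; k < K; ++k) {
      double sc = (1.0 - F[k]) / F[k];
      for (int l = 0; l < L; ++l) {
        int A = n_alleles[l];
        for (int a = 0; a < A; ++a)
          shape[a] = PA[l * Amax + a] * sc + countP[idxP(k, l) + a];
        draw_dirichlet(shape.data(), prop.data(), A);
        for (int a = 0; a < A; ++a) P[idxP(k, l) + a] = prop[a];
      }
    }

    // F_k | P, PA : Metropolis with truncated-normal prior on (0,1)
    for (int k = 0; k < K; ++k) {
      double fp = F[k] + norm_rand() * f_prop_sd;
      if (fp <= 1e-4 || fp >= 1.0 - 1e-4) continue;
      double lr = R::dnorm(fp, f_prior_mean, f_prior_sd, 1) -
                  R::dnorm(F[k], f_prior_mean, f_prior_sd, 1);
      double sc_new = (1.0 - fp) / fp, sc_old = (1.0 - F[k]) / F[k];
      for (int l = 0; l < L; ++l) {
        int A = n_alleles[l];
        for (int a = 0; a < A; ++a) shape[a] = PA[l * Amax + a] * sc_new;
        lr += ddirichlet_log(shape.data(), &P[idxP(k, l)], A);
        for (int a = 0; a < A; ++a) shape[a] = PA[l * Amax + a] * sc_old;
        lr -= ddirichlet_log(shape.data(), &P[idxP(k, l)], A);
      }
      if (std::log(unif_rand()) < lr) F[k] = fp;
    }

    // PA_l : Metropolis, move mass between two random alleles
    for (int l = 0; l < L; ++l) {
      int A = n_alleles[l];
      if (A < 2) continue;
      int a1 = (int)(unif_rand() * A), a2 = (int)(unif_rand() * (A - 1));
      if (a2 >= a1) ++a2;
      double d = norm_rand() * 0.05;
      double pa1 = PA[l * Amax + a1] + d, pa2 = PA[l * Amax + a2] - d;
      if (pa1 <= 1e-6 || pa2 <= 1e-6 || pa1 >= 1.0 || pa2 >= 1.0) continue;
      double lr = (lambda - 1.0) *
                  (std::log(pa1 / PA[l * Amax + a1]) +
                   std::log(pa2 / PA[l * Amax + a2]));
      std::vector<double> panew(PA.begin() + l * Amax,
                                PA.begin() + l * Amax + A);
      panew[a1] = pa1; panew[a2] = pa2;
      for (int k = 0; k < K; ++k) {
        double sc = (1.0 - F[k]) / F[k];
        for (int a = 0; a < A; ++a) shape[a] = panew[a] * sc;
        lr += ddirichlet_log(shape.data(), &P[idxP(k, l)], A);
        for (int a = 0; a < A; ++a) shape[a] = PA[l * Amax + a] * sc;
        lr -= ddirichlet_log(shape.data(), &P[idxP(k, l)], A);
      }
      if (std::log(unif_rand()) < lr) {
        PA[l * Amax + a1] = pa1;
        PA[l * Amax + a2] = pa2;
      }
    }

    // alpha | Q : Metropolis with uniform(0, alpha_max) prior
    if (K > 1) {
      double ap = alpha + norm_rand() * alpha_prop_sd;
      if (ap > 1e-4 && ap < alpha_max) {
        double lr = 0.0;
        double lc_new = R::lgammafn(K * ap) - K * R::lgammafn(ap);
        double lc_old = R::lgammafn(K * alpha) - K * R::lgammafn(alpha);
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int k = 0; k < K; ++k) s += std::log(Q[i * K + k]);
          lr += lc_new - lc_old + (ap - alpha) * s;
        }
        if (std::log(unif_rand()) < lr) alpha = ap;
      }
    }

    if (record) {
      trace[rec++] = loglik;
      for (size_t t = 0; t < Qsum.size(); ++t) Qsum[t] += Q[t];
      for (size_t t = 0; t < Psum.size(); ++t) Psum[t] += P[t];
      for (int k = 0; k < K; ++k) Fsum[k] += F[k];
      alphasum += alpha;
    }
  }

  NumericMatrix Qout(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qout(i, k) = Qsum[i * K + k] / n_rec;
  NumericVector Fout(K);
  for (int k = 0; k < K; ++k) Fout[k] = Fsum[k] / n_rec;
  List Pout(K);
  for (int k = 0; k < K; ++k) {
    NumericMatrix Pk(L, Amax);
    for (int l = 0; l < L; ++l)
      for (int a = 0; a < Amax; ++a) Pk(l, a) = Psum[idxP(k, l) + a] / n_rec;
    Pout[k] = Pk;
  }
  return List::create(_["Q"] = Qout, _["P"] = Pout, _["F"] = Fout,
                      _["alpha"] = alphasum / n_rec,
                      _["loglik_trace"] = trace);
}
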