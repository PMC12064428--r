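// Gibbs sampler for the admixture model: latent cluster-of-origin for every
// gene copy, Dirichlet-conjugate updates of cluster allele frequencies and
// individual membership vectors. Uses R's RNG so results are reproducible
// via set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static int sample_cat(const double* w, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += w[k];
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

static void rdirichlet_inplace(double* out, const double* conc, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) {
    double g = R::rgamma(conc[k] > 1e-12 ? conc[k] : 1e-12, 1.0);
    out[k] = g;
    tot += g;
  }
  if (tot <= 0.0) {
    for (int k = 0; k < K; ++k) out[k] = 1.0 / K;
    return;
  }
  for (int k = 0; k < K; ++k) out[k] /= tot;
}

// geno: n x 2L matrix of 0-based allele indices, -1 = missing.
// prior_conc: concatenated per-locus Dirichlet prior for allele frequencies
//   (length sum(n_alleles)); identical across clusters.
// pop_index: 0-based population index per individual for the location
//   prior, or empty for no locprior.
// [[Rcpp::export(name = ".gibbs_admixture")]]
List gibbs_admixture(IntegerMatrix geno, IntegerVector n_alleles, int K,
                     int burnin, int iters, int thin, double alpha,
                     NumericVector prior_conc, IntegerVector pop_index,
                     int n_pops, double loc_r, bool alpha_update) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  const bool locprior = pop_index.size() == n && n_pops > 0;
  std::vector<int> offset(L, 0);
  for (int l = 1; l < L; ++l) offset[l] = offset[l - 1] + n_alleles[l - 1];
  const int Atot = offset[L - 1] + n_alleles[L - 1];

  // state
  NumericMatrix q(n, K);
  std::fill(q.begin(), q.end(), 1.0 / K);
  std::vector<double> p((size_t)K * Atot);     // p[k*Atot + offset[l] + a]
  std::vector<double> cnt((size_t)K * Atot);   // allele-cluster counts
  NumericMatrix indCnt(n, K);
  std::vector<double> eta((size_t)n_pops * K, 1.0 / std::max(K, 1));
  std::vector<double> buf(K), conc(std::max(K, Atot));

  // init p from the prior
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l)
      rdirichlet_inplace(&p[(size_t)k * Atot + offset[l]],
                         &prior_conc[offset[l]], n_alleles[l]);

  const int total = burnin + iters;
  const int nstore = (thin > 0) ? iters / thin : 0;
  NumericVector loglik(nstore > 0 ? nstore : 1);
  NumericMatrix qsum(n, K);
  int stored = 0;

  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(indCnt.begin(), indCnt.end(), 0.0);
    // (i) latent origins
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < 2 * L; ++c) {
        int a = geno(i, c);
        if (a < 0) continue;
        int l = c / 2;
        for (int k = 0; k < K; ++k)
          buf[k] = q(i, k) * p[(size_t)k * Atot + offset[l] + a];
        int k = sample_cat(buf.data(), K);
        cnt[(size_t)k * Atot + offset[l] + a] += 1.0;
        indCnt(i, k) += 1.0;
      }
    }
    // (ii) frequencies | origins
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        for (int a = 0; a < n_alleles[l]; ++a)
          conc[a] = prior_conc[offset[l] + a] +
                    cnt[(size_t)k * Atot + offset[l] + a];
        rdirichlet_inplace(&p[(size_t)k * Atot + offset[l]], conc.data(),
                           n_alleles[l]);
      }
    // population-level mixture weights for the location prior
    if (locprior) {
      std::vector<double> popCnt((size_t)n_pops * K, 0.0);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k)
          popCnt[(size_t)pop_index[i] * K + k] += indCnt(i, k);
      for (int pp = 0; pp < n_pops; ++pp) {
        for (int k = 0; k < K; ++k) conc[k] = 1.0 + popCnt[(size_t)pp * K + k];
        rdirichlet_inplace(&eta[(size_t)pp * K], conc.data(), K);
      }
    }
    // (iii) q | origins
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) {
        double prior = locprior ? loc_r * K * eta[(size_t)pop_index[i] * K + k]
                                : alpha;
        conc[k] = prior + indCnt(i, k);
      }
      rdirichlet_inplace(buf.data(), conc.data(), K);
      for (int k = 0; k < K; ++k) q(i, k) = buf[k];
    }
    // optional Metropolis update of the admixture concentration alpha
    // (uniform prior on (0, 10], Gaussian random walk as in Structure)
    if (alpha_update && K > 1) {
      double prop = alpha + norm_rand() * 0.05;
      if (prop > 0.0 && prop <= 10.0) {
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) {
            double qi = q(i, k);
            slq += std::log(qi > 1e-12 ? qi : 1e-12);
          }
        double cur = n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                     (alpha - 1.0) * slq;
        double nxt = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) +
                     (prop - 1.0) * slq;
        if (std::log(unif_rand()) < nxt - cur) alpha = prop;
      }
    }
    // store
    if (sweep >= burnin && thin > 0 && (sweep - burnin) % thin == thin - 1 &&
        stored < nstore) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 2 * L; ++c) {
          int a = geno(i, c);
          if (a < 0) continue;
          int l = c / 2;
          double m = 0.0;
          for (int k = 0; k < K; ++k)
            m += q(i, k) * p[(size_t)k * Atot + offset[l] + a];
          ll += std::log(m > 1e-300 ? m : 1e-300);
        }
      loglik[stored] = ll;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) qsum(i, k) += q(i, k);
      ++stored;
    }
  }
  if (stored > 0)
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < K; ++k) qsum(i, k) /= stored;
  return List::create(_["q"] = qsum, _["loglik_trace"] = loglik,
                      _["n_stored"] = stored, _["alpha"] = alpha);
}
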