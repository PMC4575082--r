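#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Gibbs sampler for the admixture model on multi-allelic genotypes of mixed
// ploidy. Latent state: per-allele-copy cluster assignment z; cluster allele
// frequencies p (Dirichlet(lambda) prior, independent across loci); individual
// admixture proportions q (Dirichlet(alpha) prior). Missing copies are simply
// absent from the copy list. Flagged individuals (popflag mode) have their
// copies pinned to their labelled cluster and their q held at the indicator
// vector: they act as pure training members.
//
// Randomness comes from a self-contained xoshiro256++ generator seeded from
// the run seed, so a run is bit-reproducible for a given seed and input,
// independently of R's RNG state and platform.

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed + 0x9E3779B97f4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    // polar Box-Muller, spare discarded (branch-free determinism)
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    return u * std::sqrt(-2.0 * std::log(s2) / s2);
  }
  // Marsaglia-Tsang; valid for any shape > 0
  double gamma(double shape) {
    if (shape < 1.0) {
      double g = gamma(shape + 1.0);
      return g * std::pow(unif(), 1.0 / shape);
    }
    const double d = shape - 1.0 / 3.0;
    const double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = normal();
      double v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List gibbs_admixture(IntegerVector copy_ind, IntegerVector copy_loc,
                     IntegerVector copy_allele, int n_ind, int n_loci,
                     IntegerVector n_alleles, int K, IntegerVector flag,
                     double alpha, double lambda, int burn_in, int iters,
                     bool update_alpha, double alpha_prop_sd,
                     double alpha_max, int seed) {
  const int C = copy_ind.size();
  const int total_sweeps = burn_in + iters;
  Xoshiro rng((uint64_t)(unsigned int)seed);

  // q[i*K + k], p[l]: K x A_l row-major
  std::vector<double> q((size_t)n_ind * K, 1.0 / K);
  std::vector<std::vector<double>> p(n_loci);
  for (int l = 0; l < n_loci; ++l)
    p[l].assign((size_t)K * n_alleles[l], 1.0 / n_alleles[l]);

  for (int i = 0; i < n_ind; ++i) {
    if (flag[i] >= 0) {
      for (int k = 0; k < K; ++k) q[(size_t)i * K + k] = 0.0;
      q[(size_t)i * K + flag[i]] = 1.0;
    }
  }

  std::vector<double> Qsum((size_t)n_ind * K, 0.0);
  std::vector<std::vector<double>> Psum(n_loci);
  for (int l = 0; l < n_loci; ++l)
    Psum[l].assign((size_t)K * n_alleles[l], 0.0);
  NumericVector lnLtrace(iters);

  std::vector<double> probs(K);
  std::vector<int> qcount((size_t)n_ind * K);
  std::vector<std::vector<int>> pcount(n_loci);
  for (int l = 0; l < n_loci; ++l)
    pcount[l].assign((size_t)K * n_alleles[l], 0);

  double cur_alpha = alpha;

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    // (i) z | p, q
    std::fill(qcount.begin(), qcount.end(), 0);
    for (int l = 0; l < n_loci; ++l)
      std::fill(pcount[l].begin(), pcount[l].end(), 0);
    for (int c = 0; c < C; ++c) {
      const int i = copy_ind[c], l = copy_loc[c], a = copy_allele[c];
      int k;
      if (flag[i] >= 0) {
        k = flag[i];
      } else {
        double tot = 0.0;
        const int A = n_alleles[l];
        const double *qi = &q[(size_t)i * K];
        for (int j = 0; j < K; ++j) {
          probs[j] = qi[j] * p[l][(size_t)j * A + a];
          tot += probs[j];
        }
        double u = rng.unif() * tot;
        k = K - 1;
        double acc = 0.0;
        for (int j = 0; j < K; ++j) {
          acc += probs[j];
          if (u <= acc) { k = j; break; }
        }
      }
      qcount[(size_t)i * K + k] += 1;
      pcount[l][(size_t)k * n_alleles[l] + a] += 1;
    }

    // (ii) p | z ~ Dirichlet(lambda + counts), per locus and cluster
    for (int l = 0; l < n_loci; ++l) {
      const int A = n_alleles[l];
      for (int k = 0; k < K; ++k) {
        double tot = 0.0;
        for (int a = 0; a < A; ++a) {
          double g = rng.gamma(lambda + pcount[l][(size_t)k * A + a]);
          if (g < 1e-300) g = 1e-300;
          p[l][(size_t)k * A + a] = g;
          tot += g;
        }
        for (int a = 0; a < A; ++a) p[l][(size_t)k * A + a] /= tot;
      }
    }

    // (iii) q | z ~ Dirichlet(alpha + counts), unflagged individuals only
    for (int i = 0; i < n_ind; ++i) {
      if (flag[i] >= 0) continue;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = rng.gamma(cur_alpha + qcount[(size_t)i * K + k]);
        if (g < 1e-300) g = 1e-300;
        q[(size_t)i * K + k] = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) q[(size_t)i * K + k] /= tot;
    }

    // optional Metropolis step on alpha (uniform prior on (0, alpha_max));
    // the Dirichlet normalising constant is identical across individuals
    if (update_alpha && K > 1) {
      double prop = cur_alpha + rng.normal() * alpha_prop_sd;
      if (prop > 0.0 && prop < alpha_max) {
        int n_free = 0;
        double sum_log_q = 0.0;
        for (int i = 0; i < n_ind; ++i) {
          if (flag[i] >= 0) continue;
          ++n_free;
          for (int k = 0; k < K; ++k) {
            double qv = q[(size_t)i * K + k];
            if (qv < 1e-300) qv = 1e-300;
            sum_log_q += std::log(qv);
          }
        }
        double logr = n_free * (R::lgammafn(K * prop) - K * R::lgammafn(prop)
                      - R::lgammafn(K * cur_alpha)
                      + K * R::lgammafn(cur_alpha))
                    + (prop - cur_alpha) * sum_log_q;
        if (n_free > 0 && std::log(rng.unif()) < logr) cur_alpha = prop;
      }
    }

    // record
    if (sweep >= burn_in) {
      const int rec = sweep - burn_in;
      double lnL = 0.0;
      for (int c = 0; c < C; ++c) {
        const int i = copy_ind[c], l = copy_loc[c], a = copy_allele[c];
        const int A = n_alleles[l];
        const double *qi = &q[(size_t)i * K];
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += qi[k] * p[l][(size_t)k * A + a];
        if (s < 1e-300) s = 1e-300;
        lnL += std::log(s);
      }
      lnLtrace[rec] = lnL;
      for (size_t t = 0; t < Qsum.size(); ++t) Qsum[t] += q[t];
      for (int l = 0; l < n_loci; ++l)
        for (size_t t = 0; t < Psum[l].size(); ++t) Psum[l][t] += p[l][t];
    }
  }

  NumericMatrix Q(n_ind, K);
  for (int i = 0; i < n_ind; ++i)
    for (int k = 0; k < K; ++k)
      Q(i, k) = Qsum[(size_t)i * K + k] / iters;
  List P(n_loci);
  for (int l = 0; l < n_loci; ++l) {
    const int A = n_alleles[l];
    NumericMatrix pm(K, A);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < A; ++a)
        pm(k, a) = Psum[l][(size_t)k * A + a] / iters;
    P[l] = pm;
  }
  return List::create(_["Q"] = Q, _["P"] = P, _["lnL"] = lnLtrace,
                      _["alpha_final"] = cur_alpha);
}

// Log-likelihood of a (q, p) state: sum over observed allele copies of
// log sum_k q_ik p_k(allele). Exposed for testing against a brute-force
// re-implementation.
// [[Rcpp::export]]
double admixture_loglik(IntegerVector copy_ind, IntegerVector copy_loc,
                        IntegerVector copy_allele, NumericMatrix Q,
                        List P, double eps) {
  const int C = copy_ind.size();
  const int K = Q.ncol();
  double lnL = 0.0;
  for (int c = 0; c < C; ++c) {
    const int i = copy_ind[c], l = copy_loc[c], a = copy_allele[c];
    NumericMatrix pm = P[l];
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Q(i, k) * pm(k, a);
    if (s < eps) s = eps;
    lnL += std::log(s);
  }
  return lnL;
}
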