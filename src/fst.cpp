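#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Ploidy-aware Weir-Cockerham-style variance components for one locus.
// S: scored-individuals x alleles matrix of copy counts; ncop: copies per
// individual; grp: 1-based group code per individual; r: number of groups
// in the full grouping. Groups absent from the scored set are dropped;
// returns c(g, i, w) summed over alleles, or NAs when fewer than two
// groups remain or a remaining group has fewer than two scored
// individuals.
// [[Rcpp::export]]
NumericVector wc_components(IntegerMatrix S, IntegerVector ncop,
                            IntegerVector grp, int r) {
  const int M = S.nrow(), A = S.ncol();
  NumericVector out(3, NA_REAL);
  if (r < 1 || M < 1) return out;
  std::vector<int> count(r, 0);
  for (int i = 0; i < M; ++i) count[grp[i] - 1] += 1;
  // drop groups with no scored individuals; fail on singleton groups
  std::vector<int> remap(r, -1);
  int re = 0;
  for (int j = 0; j < r; ++j) {
    if (count[j] == 1) return out;
    if (count[j] >= 2) remap[j] = re++;
  }
  if (re < 2) return out;

  std::vector<int> m_j(re, 0);
  std::vector<double> n_j(re, 0.0), sum_n2_j(re, 0.0);
  double N = 0.0, sum_n2 = 0.0;
  for (int i = 0; i < M; ++i) {
    const int j = remap[grp[i] - 1];
    m_j[j] += 1;
    n_j[j] += ncop[i];
    sum_n2_j[j] += (double)ncop[i] * ncop[i];
    N += ncop[i];
    sum_n2 += (double)ncop[i] * ncop[i];
  }

  const double dfw = N - M, dfi = M - re, dfg = re - 1;
  double sumSj = 0.0, sum_nj2 = 0.0;
  for (int j = 0; j < re; ++j) {
    sumSj += sum_n2_j[j] / n_j[j];
    sum_nj2 += n_j[j] * n_j[j];
  }
  const double k1 = (N - sumSj) / dfi;
  const double k2 = (sumSj - sum_n2 / N) / dfg;
  const double k3 = (N - sum_nj2 / N) / dfg;

  double sg = 0.0, si = 0.0, sw = 0.0;
  std::vector<double> gsum(re);
  for (int a = 0; a < A; ++a) {
    double tsum = 0.0, s2n = 0.0;
    std::fill(gsum.begin(), gsum.end(), 0.0);
    for (int i = 0; i < M; ++i) {
      const double y = S(i, a);
      tsum += y;
      s2n += y * y / ncop[i];
      gsum[remap[grp[i] - 1]] += y;
    }
    double g2n = 0.0;
    for (int j = 0; j < re; ++j) g2n += gsum[j] * gsum[j] / n_j[j];
    const double ssw = tsum - s2n;
    const double ssi = s2n - g2n;
    const double ssg = g2n - tsum * tsum / N;
    const double msw = dfw > 0 ? ssw / dfw : 0.0;
    const double msi = ssi / dfi;
    const double msg = ssg / dfg;
    const double vi = (msi - msw) / k1;
    const double vg = (msg - msw - k2 * vi) / k3;
    sw += msw; si += vi; sg += vg;
  }
  out[0] = sg; out[1] = si; out[2] = sw;
  return out;
}
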