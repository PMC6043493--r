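#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exhaustive permutation null for the Steel-Dwass all-pairs comparison.
//
// Enumerates every assignment of the pooled observations to groups of the
// given sizes, computes for each arrangement the pairwise standardised
// rank-sum statistics (pairwise ranks, average ranks for ties, tie-corrected
// variance), and records the arrangement's maximum absolute statistic. The
// single-step adjusted p value of an observed pair is the proportion of
// arrangements whose maximum reaches that pair's observed |z|.
//
// values: pooled observations sorted ascending
// sizes:  group sizes (k groups)
// zobs:   |z| observed for each of the k*(k-1)/2 pairs (pair order (1,2),
//         (1,3), ..., (2,3), ...)
// returns adjusted p per pair
namespace {

struct Enumerator {
  const std::vector<double>& v;
  const std::vector<int>& sizes;
  const std::vector<double>& zobs;
  int N, k, npair;
  std::vector<int> label;     // group label per sorted position
  std::vector<double> ge;     // count of arrangements with max >= zobs[p]
  double total;

  Enumerator(const std::vector<double>& v_, const std::vector<int>& s_,
             const std::vector<double>& z_)
      : v(v_), sizes(s_), zobs(z_), N((int)v_.size()), k((int)s_.size()),
        npair(k * (k - 1) / 2), label(N, -1), ge(npair, 0.0), total(0.0) {}

  double pair_z(int a, int b) const {
    const int na = sizes[a], nb = sizes[b], n = na + nb;
    // walk sorted positions restricted to groups a/b; runs of equal values
    // share their average rank
    double wa = 0.0;
    double tie_sum = 0.0;  // sum over tie groups of t^3 - t
    int seen = 0;
    int i = 0;
    while (i < N) {
      if (label[i] != a && label[i] != b) { ++i; continue; }
      int j = i, run = 0, run_a = 0;
      const double val = v[i];
      while (j < N) {
        if (label[j] == a || label[j] == b) {
          if (v[j] != val) break;
          ++run;
          if (label[j] == a) ++run_a;
        } else if (v[j] != val) {
          break;
        }
        ++j;
      }
      const double avg_rank = seen + (run + 1) / 2.0;
      wa += run_a * avg_rank;
      if (run > 1) tie_sum += (double)run * run * run - run;
      seen += run;
      i = j;
    }
    const double E = na * (n + 1) / 2.0;
    const double V =
        (double)na * nb / 12.0 * ((n + 1) - tie_sum / ((double)n * (n - 1)));
    if (V <= 0) return 0.0;
    return (wa - E) / std::sqrt(V);
  }

  void visit() {
    double zmax = 0.0;
    for (int a = 0, p = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b, ++p) {
        const double z = std::fabs(pair_z(a, b));
        if (z > zmax) zmax = z;
      }
    total += 1.0;
    for (int p = 0; p < npair; ++p)
      if (zmax >= zobs[p] - 1e-9) ge[p] += 1.0;
  }

  // assign positions to group g, then recurse
  void recurse(int g, int from, int left) {
    if (g == k - 1) {
      for (int i = 0; i < N; ++i)
        if (label[i] < 0) label[i] = g;
      visit();
      for (int i = 0; i < N; ++i)
        if (label[i] == g) label[i] = -1;
      return;
    }
    if (left == 0) {
      recurse(g + 1, 0, sizes[g + 1]);
      return;
    }
    for (int i = from; i <= N - left; ++i) {
      if (label[i] >= 0) continue;
      label[i] = g;
      recurse(g, i + 1, left - 1);
      label[i] = -1;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector steel_dwass_exact_cpp(NumericVector values, IntegerVector sizes,
                                    NumericVector zobs) {
  std::vector<double> v(values.begin(), values.end());
  std::vector<int> s(sizes.begin(), sizes.end());
  std::vector<double> z(zobs.begin(), zobs.end());
  Enumerator e(v, s, z);
  e.recurse(0, 0, s[0]);
  NumericVector out(e.npair);
  for (int p = 0; p < e.npair; ++p) out[p] = e.ge[p] / e.total;
  return out;
}
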