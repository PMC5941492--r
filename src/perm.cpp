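#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Joint column-permutation null for pure-match fragment scores.
//
// One random permutation of the s polymorphic sites is shared by all pairs
// (columns are permuted jointly across sequences). Under pure-match scoring
// a pair's best fragment after the permutation is its longest run of
// matching sites, which depends only on where its mismatching sites land,
// so each permutation is evaluated from the permuted mismatch positions.
// Uses R's RNG, so results are reproducible under set.seed().
//
// s       number of polymorphic sites
// mism    per pair, 1-based indices (into the site list) of its mismatches
// obs     per pair, the observed best fragment score
// n_perm  number of permutations
//
// Returns, per pair, the count of permutations with null score >= obs.
// [[Rcpp::export]]
IntegerVector perm_exceed_counts(int s, List mism, NumericVector obs,
                                 int n_perm) {
  int n_pairs = mism.size();
  IntegerVector exceed(n_pairs);
  std::vector<int> perm(s), inv(s);
  std::vector<std::vector<int> > msites(n_pairs);
  for (int p = 0; p < n_pairs; ++p) {
    IntegerVector m = mism[p];
    msites[p].assign(m.begin(), m.end());
  }
  std::vector<int> pos;
  for (int r = 0; r < n_perm; ++r) {
    for (int i = 0; i < s; ++i) perm[i] = i;
    // Fisher-Yates with R's uniform RNG
    for (int i = s - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int i = 0; i < s; ++i) inv[perm[i]] = i + 1; // 1-based position
    for (int p = 0; p < n_pairs; ++p) {
      const std::vector<int> &m = msites[p];
      int k = m.size();
      int best;
      if (k == 0) {
        best = s;
      } else {
        pos.resize(k);
        for (int t = 0; t < k; ++t) pos[t] = inv[m[t] - 1];
        std::sort(pos.begin(), pos.end());
        best = pos[0] - 1;
        if (s - pos[k - 1] > best) best = s - pos[k - 1];
        for (int t = 1; t < k; ++t) {
          int run = pos[t] - pos[t - 1] - 1;
          if (run > best) best = run;
        }
      }
      if (best >= obs[p]) exceed[p]++;
    }
  }
  return exceed;
}
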