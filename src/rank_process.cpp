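#include <Rcpp.h>
using namespace Rcpp;

// Rank-driven occurrence process.
//
// `ranks` holds, for each time step, the rank drawn from the fixed
// step-probability profile (1-based). The element occupying that rank is
// found through a count-bucket index: elements are kept in an array `perm`
// ordered by occurrence count (descending), with equal-count elements
// forming one contiguous bucket. Drawing a concrete element uniformly from
// the bucket covering the drawn rank is distributionally identical to
// re-randomizing the order of tied elements at every step, and costs O(1).
// Tie randomization uses R's RNG, so results are reproducible via set.seed().
//
// [[Rcpp::export(name = ".rank_process")]]
IntegerVector rank_process(IntegerVector ranks, int pool) {
  const int T = ranks.size();
  std::vector<int> perm(pool), cnt(pool, 0);
  for (int i = 0; i < pool; ++i) perm[i] = i;
  // bucket boundaries indexed by count value (counts never exceed T)
  std::vector<int> bstart(T + 2, -1), bend(T + 2, -1);
  bstart[0] = 0; bend[0] = pool - 1;
  IntegerVector out(T);
  for (int s = 0; s < T; ++s) {
    int r = ranks[s] - 1;
    if (r < 0 || r >= pool) stop("rank out of range");
    int c = cnt[perm[r]];
    int lo = bstart[c], hi = bend[c];
    int u = lo + (int)(unif_rand() * (hi - lo + 1));
    if (u > hi) u = hi;
    std::swap(perm[lo], perm[u]);
    int el = perm[lo];
    cnt[el] = c + 1;
    bstart[c] = lo + 1;                      // bucket c shrinks (may empty)
    if (bstart[c + 1] == -1 || bstart[c + 1] > bend[c + 1]) {
      bstart[c + 1] = lo; bend[c + 1] = lo;  // bucket c+1 was empty
    } else {
      bend[c + 1] = lo;                      // bucket c+1 extends downward
    }
    out[s] = el + 1;
  }
  return out;
}
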