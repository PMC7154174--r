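#include <Rcpp.h>
using namespace Rcpp;

// Gene-wise permutation null for group mutual exclusivity.
//
// Each null draw places every gene's mutations uniformly at random
// across the n samples (partial Fisher-Yates, preserving the gene's
// mutation count) and computes ME = (#samples with exactly one mutated
// gene) / n. Draws stop early once `stop_exc` exceedances are reached
// (set stop_exc > B to disable). Uses R's RNG, so results are
// reproducible under set.seed().
//
// Returns c(exceedances, draws_done).

// [[Rcpp::export(name = ".null_exceedances")]]
IntegerVector null_exceedances(int n, IntegerVector m, int B, double obs,
                               int stop_exc) {
  std::vector<int> pool(n);
  std::vector<int> counts(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  int exc = 0, done = 0;
  const int k = m.size();
  for (int b = 0; b < B; ++b) {
    std::fill(counts.begin(), counts.end(), 0);
    for (int g = 0; g < k; ++g) {
      const int mm = m[g];
      for (int t = 0; t < mm; ++t) {
        int j = t + (int) R_unif_index(n - t);
        std::swap(pool[t], pool[j]);
        ++counts[pool[t]];
      }
    }
    int ones = 0;
    for (int i = 0; i < n; ++i)
      if (counts[i] == 1) ++ones;
    const double me = (double) ones / n;
    ++done;
    if (me >= obs - 1e-9) ++exc;
    if (exc >= stop_exc) break;
  }
  return IntegerVector::create(exc, done);
}
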