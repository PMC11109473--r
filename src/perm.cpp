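#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo null for two-group label permutation: draws B random
// subsets of size nA from x (without replacement, partial Fisher-Yates on
// R's RNG so results are reproducible under set.seed) and returns the sum
// of each subset. Every two-group permutation statistic used here
// (difference of means, rank sum) is a function of the subset sum, so the
// kernel stays statistic-agnostic.
// [[Rcpp::export]]
NumericVector perm_subset_sums(NumericVector x, int nA, int B) {
  int n = x.size();
  if (nA <= 0 || nA > n) stop("invalid subset size");
  NumericVector out(B);
  std::vector<double> pool(x.begin(), x.end());
  for (int b = 0; b < B; ++b) {
    double s = 0.0;
    // partial Fisher-Yates: after k swaps the first k entries are a
    // uniformly random k-subset
    for (int k = 0; k < nA; ++k) {
      int j = k + (int)(unif_rand() * (n - k));
      if (j >= n) j = n - 1; // guard unif_rand() == 1.0 edge
      std::swap(pool[k], pool[j]);
      s += pool[k];
    }
    out[b] = s;
  }
  return out;
}
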