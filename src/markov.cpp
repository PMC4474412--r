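#include <Rcpp.h>
using namespace Rcpp;

// Sample a base sequence from a 0th/1st-order Markov chain.
// u: pre-drawn uniforms (length n), so randomness stays under R's RNG.
// init_cum: cumulative initial probabilities (length 4, last == 1).
// trans_cum: 4x4 row-cumulative transition matrix (ignored for order 0).
// restart: 1-based positions that start a new chain (region starts).
// Returns integer base codes 1..4 (A,C,G,T).
// [[Rcpp::export]]
IntegerVector markov_sample_codes(NumericVector u, NumericVector init_cum,
                                  NumericMatrix trans_cum,
                                  IntegerVector restart, int order) {
  const int n = u.size();
  IntegerVector out(n);
  std::vector<bool> is_restart(n + 1, false);
  for (int i = 0; i < restart.size(); ++i) {
    int p = restart[i];
    if (p >= 1 && p <= n) is_restart[p] = true;
  }
  int prev = 0;
  for (int i = 0; i < n; ++i) {
    const double ui = u[i];
    int b;
    if (order == 0 || i == 0 || is_restart[i + 1]) {
      b = 1;
      while (b < 4 && ui > init_cum[b - 1]) ++b;
    } else {
      b = 1;
      while (b < 4 && ui > trans_cum(prev - 1, b - 1)) ++b;
    }
    out[i] = b;
    prev = b;
  }
  return out;
}
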