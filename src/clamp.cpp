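#include <Rcpp.h>
using namespace Rcpp;

// Componentwise clamp of an n x d matrix to per-column bounds. Hot path of
// the swarm update: called several times per island per generation, so it
// avoids R-level pmin/pmax dispatch on many tiny slices.
// [[Rcpp::export]]
NumericMatrix clamp_matrix(NumericMatrix m, NumericVector lower,
                           NumericVector upper) {
  const int n = m.nrow(), d = m.ncol();
  NumericMatrix out(n, d);
  for (int j = 0; j < d; ++j) {
    const double lo = lower[j], hi = upper[j];
    for (int i = 0; i < n; ++i) {
      double v = m(i, j);
      if (v < lo) v = lo;
      else if (v > hi) v = hi;
      out(i, j) = v;
    }
  }
  return out;
}
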