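#include <Rcpp.h>
using namespace Rcpp;

// Random 2x2 checkerboard flips on a binary incidence matrix. Each accepted
// flip replaces [[1,0],[0,1]] with [[0,1],[1,0]] (or vice versa) in a randomly
// chosen pair of rows/columns, so row and column sums are invariant. `attempts`
// counts attempted swaps, accepted or not. Uses R's RNG (unif_rand), so the
// caller's set.seed() governs the chain.
// [[Rcpp::export]]
IntegerMatrix cpp_independent_swap(const IntegerMatrix& m, const int attempts) {
  IntegerMatrix x = clone(m);
  const int nr = x.nrow(), nc = x.ncol();
  if (nr < 2 || nc < 2) return x;
  for (int t = 0; t < attempts; ++t) {
    int r1 = (int)(unif_rand() * nr);
    if (r1 >= nr) r1 = nr - 1;
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= nr - 1) r2 = nr - 2;
    if (r2 >= r1) ++r2;
    int c1 = (int)(unif_rand() * nc);
    if (c1 >= nc) c1 = nc - 1;
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= nc - 1) c2 = nc - 2;
    if (c2 >= c1) ++c2;
    const int a = x(r1, c1), b = x(r1, c2), c = x(r2, c1), d = x(r2, c2);
    if (a == 1 && d == 1 && b == 0 && c == 0) {
      x(r1, c1) = 0; x(r2, c2) = 0; x(r1, c2) = 1; x(r2, c1) = 1;
    } else if (a == 0 && d == 0 && b == 1 && c == 1) {
      x(r1, c1) = 1; x(r2, c2) = 1; x(r1, c2) = 0; x(r2, c1) = 0;
    }
  }
  return x;
}
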