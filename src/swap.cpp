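#include <Rcpp.h>
using namespace Rcpp;

// 2x2 checkerboard swaps on a binary matrix, drawing from R's RNG so that
// set.seed() at the R level makes whole chains reproducible.
//
// A "successful" swap finds a submatrix [[1,0],[0,1]] or [[0,1],[1,0]] on
// two random rows x two random columns and flips it to the other
// checkerboard; row and column sums are invariant under every such move.

static inline int rand_index(int n) {
  int k = (int)(unif_rand() * n);
  return (k == n) ? n - 1 : k;
}

// Run the chain in place; returns number of successful swaps performed
// before either reaching `target` successes or exhausting `max_attempts`.
static long run_swaps(IntegerMatrix m, long target, long max_attempts) {
  int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2) return 0;
  long done = 0, attempts = 0;
  while (done < target && attempts < max_attempts) {
    ++attempts;
    int r1 = rand_index(nr), r2 = rand_index(nr - 1);
    if (r2 >= r1) ++r2;
    int c1 = rand_index(nc), c2 = rand_index(nc - 1);
    if (c2 >= c1) ++c2;
    int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
    if ((a == 1 && b == 0 && c == 0 && d == 1) ||
        (a == 0 && b == 1 && c == 1 && d == 0)) {
      m(r1, c1) = 1 - a; m(r1, c2) = 1 - b;
      m(r2, c1) = 1 - c; m(r2, c2) = 1 - d;
      ++done;
    }
  }
  return done;
}

// [[Rcpp::export]]
List cpp_independent_swap(IntegerMatrix mat, double n_swaps, double max_attempts) {
  IntegerMatrix m = clone(mat);
  long done = run_swaps(m, (long)n_swaps, (long)max_attempts);
  return List::create(_["matrix"] = m, _["swaps_done"] = (double)done);
}

// Generate `n_null` null matrices from one chain: burn in for `interval`
// successful swaps, then record the state every `interval` further
// successes. Returns matrices stacked along the third dimension.
// [[Rcpp::export]]
List cpp_swap_series(IntegerMatrix mat, int n_null, double interval, double max_attempts) {
  IntegerMatrix m = clone(mat);
  int nr = m.nrow(), nc = m.ncol();
  IntegerVector out(Dimension(nr, nc, n_null));
  bool short_chain = false;
  long burn = run_swaps(m, (long)interval, (long)max_attempts);
  if (burn < (long)interval) short_chain = true;
  for (int k = 0; k < n_null; ++k) {
    long done = run_swaps(m, (long)interval, (long)max_attempts);
    if (done < (long)interval) short_chain = true;
    std::copy(m.begin(), m.end(), out.begin() + (R_xlen_t)k * nr * nc);
  }
  return List::create(_["nulls"] = out, _["short_chain"] = short_chain);
}
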