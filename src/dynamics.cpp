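#include <Rcpp.h>
using namespace Rcpp;

// h += W[, i] * d ; relies on column-major storage
static inline void add_col(NumericVector &h, const NumericMatrix &W, int i,
                           double d) {
  const int N = h.size();
  const double *col = &W(0, i);
  double *hp = REAL(h);
  for (int j = 0; j < N; ++j) hp[j] += col[j] * d;
}

// local fields h = W x for a ternary state (zeros contribute nothing)
static NumericVector field(const NumericMatrix &W, const IntegerVector &x) {
  const int N = x.size();
  NumericVector h(N);
  for (int j = 0; j < N; ++j)
    if (x[j] != 0) add_col(h, W, j, (double)x[j]);
  return h;
}

// One asynchronous sweep of the classical +/-1 dynamics x_i <- sign(h_i),
// visiting nodes in `order` (1-based). A zero field keeps the current state.
// [[Rcpp::export]]
List cpp_sweep_classic(const NumericMatrix &W, const IntegerVector &state,
                       const IntegerVector &order) {
  IntegerVector x = clone(state);
  NumericVector h = field(W, x);
  int flips = 0;
  for (int k = 0; k < order.size(); ++k) {
    const int i = order[k] - 1;
    const double hi = h[i];
    int nx = x[i];
    if (hi > 0) nx = 1;
    else if (hi < 0) nx = -1;
    if (nx != x[i]) {
      add_col(h, W, i, (double)(nx - x[i]));
      x[i] = nx;
      ++flips;
    }
  }
  return List::create(_["state"] = x, _["flips"] = flips);
}

// Run classical asynchronous dynamics to a fixed point (or max_sweeps),
// drawing a fresh uniformly random visiting order per sweep from R's RNG.
// Fields are maintained incrementally across sweeps.
// [[Rcpp::export]]
List cpp_evolve_classic(const NumericMatrix &W, const IntegerVector &state,
                        int max_sweeps) {
  const int N = state.size();
  IntegerVector x = clone(state);
  NumericVector h = field(W, x);
  int sweeps = 0;
  bool fixed = false;
  while (sweeps < max_sweeps && !fixed) {
    IntegerVector order = sample(N, N, false);
    int flips = 0;
    for (int k = 0; k < N; ++k) {
      const int i = order[k] - 1;
      const double hi = h[i];
      int nx = x[i];
      if (hi > 0) nx = 1;
      else if (hi < 0) nx = -1;
      if (nx != x[i]) {
        add_col(h, W, i, (double)(nx - x[i]));
        x[i] = nx;
        ++flips;
      }
    }
    ++sweeps;
    if (flips == 0) fixed = true;
  }
  return List::create(_["state"] = x, _["sweeps"] = sweeps,
                      _["fixed_point"] = fixed);
}

// One asynchronous sweep of the asymmetric diluted dynamics:
//   x_i = -1 and h_i > 0  ->  x_i := +1
//   x_i = +1 and h_i < 0  ->  x_i := 0   (elimination, permanent)
//   x_i = 0               ->  never updated
//   h_i = 0               ->  no change
// [[Rcpp::export]]
List cpp_sweep_asym(const NumericMatrix &W, const IntegerVector &state,
                    const IntegerVector &order) {
  IntegerVector x = clone(state);
  NumericVector h = field(W, x);
  int changed = 0, eliminated = 0;
  for (int k = 0; k < order.size(); ++k) {
    const int i = order[k] - 1;
    if (x[i] == 0) continue;
    const double hi = h[i];
    if (x[i] == -1 && hi > 0) {
      add_col(h, W, i, 2.0);
      x[i] = 1;
      ++changed;
    } else if (x[i] == 1 && hi < 0) {
      add_col(h, W, i, -1.0);
      x[i] = 0;
      ++changed;
      ++eliminated;
    }
  }
  return List::create(_["state"] = x, _["changed"] = changed,
                      _["eliminated"] = eliminated);
}
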