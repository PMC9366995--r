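#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Adaptive finite-context-model mixture with ideal code-length accounting.
//
// Symbols are base indices 0..3 (A,C,G,T).  Each model m keeps a sparse
// count table over (context, symbol) pairs; contexts are the preceding
// order_k symbols packed 2 bits per base (earliest base most significant),
// initialized to the all-A context.  Estimator: Laplace-style smoothing by
// alpha.  Mixing: performance-weighted experts, w <- w^gamma * P(observed),
// renormalized; weights floored at 1e-15 to avoid underflow on long inputs.
//
// ir_mode per model: 0 = forward counts only, 1 = forward plus
// reverse-complement counts, 2 = reverse-complement counts only.  The
// reverse-complement update takes the (k+1)-mer window x[i-k..i], reverse
// complements it, and counts (first k symbols -> last symbol) in the same
// table; lookups are always by the forward context, which is what lets an
// inverted repeat of earlier text score the seeded counts.

// [[Rcpp::export(name = ".fcm_compress")]]
List fcm_compress(IntegerVector seq, IntegerVector orders, NumericVector alphas,
                  NumericVector gammas, IntegerVector ir_modes) {
  const int M = orders.size();
  const R_xlen_t n = seq.size();
  if (M < 1) stop("at least one model is required");
  if (alphas.size() != M || gammas.size() != M || ir_modes.size() != M)
    stop("model parameter vectors must have equal length");
  if (n < 1) stop("sequence must contain at least one symbol");

  std::vector< std::unordered_map<uint64_t, double> > counts(M);
  std::vector<uint64_t> ctx(M, 0), mask(M, 0);
  std::vector<double> w(M, 1.0 / M);
  for (int m = 0; m < M; ++m) {
    const int k = orders[m];
    if (k < 0 || k > 16) stop("context order must lie in [0, 16]");
    mask[m] = (k == 0) ? 0 : ((uint64_t(1) << (2 * k)) - 1);
    if (!(alphas[m] > 0)) stop("alpha must be positive");
    if (gammas[m] < 0 || gammas[m] > 0.99) stop("gamma must lie in [0, 0.99]");
    const int mode = ir_modes[m];
    if (mode < 0 || mode > 2) stop("ir_mode must be 0, 1 or 2");
  }

  NumericVector bits(n);
  std::vector<double> P(4 * M);
  double total = 0.0;

  for (R_xlen_t i = 0; i < n; ++i) {
    const int sym = seq[i];
    if (sym == NA_INTEGER || sym < 0 || sym > 3)
      stop("symbol outside the {A,C,G,T} alphabet at position %td; sanitize first",
           (ptrdiff_t)(i + 1));

    double pmix[4] = {0.0, 0.0, 0.0, 0.0};
    for (int m = 0; m < M; ++m) {
      const double a = alphas[m];
      double cnt[4], tot = 0.0;
      const uint64_t base = ctx[m] * 4;
      for (int s = 0; s < 4; ++s) {
        std::unordered_map<uint64_t, double>::const_iterator it =
            counts[m].find(base + s);
        cnt[s] = (it == counts[m].end()) ? 0.0 : it->second;
        tot += cnt[s];
      }
      const double denom = tot + 4.0 * a;
      for (int s = 0; s < 4; ++s) {
        const double p = (cnt[s] + a) / denom;
        P[4 * m + s] = p;
        pmix[s] += w[m] * p;
      }
    }
    bits[i] = -std::log2(pmix[sym]);
    total += bits[i];

    double wsum = 0.0;
    for (int m = 0; m < M; ++m) {
      w[m] = std::pow(w[m], gammas[m]) * P[4 * m + sym];
      wsum += w[m];
    }
    if (!(wsum > 0.0) || !std::isfinite(wsum))
      stop("mixer weights degenerated (all zero or non-finite)");
    double wsum2 = 0.0;
    for (int m = 0; m < M; ++m) {
      w[m] /= wsum;
      if (w[m] < 1e-15) w[m] = 1e-15;
      wsum2 += w[m];
    }
    for (int m = 0; m < M; ++m) w[m] /= wsum2;

    for (int m = 0; m < M; ++m) {
      const int k = orders[m];
      const int mode = ir_modes[m];
      if (mode != 2) counts[m][ctx[m] * 4 + sym] += 1.0;
      if (mode != 0) {
        uint64_t irc = 0;
        for (int t = 0; t < k; ++t) {
          const R_xlen_t j = i - t;
          const int b = (j >= 0) ? seq[j] : 0;  // positions before start read as A
          irc = (irc << 2) | uint64_t(3 - b);
        }
        const R_xlen_t j = i - k;
        const int irs = 3 - ((j >= 0) ? seq[j] : 0);
        counts[m][irc * 4 + irs] += 1.0;
      }
      ctx[m] = ((ctx[m] << 2) | uint64_t(sym)) & mask[m];
    }
  }

  return List::create(_["total_bits"] = total, _["per_symbol_bits"] = bits);
}
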