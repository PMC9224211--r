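#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cumulative GC counts over a DNA string.
// cum[i] = number of G/C bases among the first i characters (cum[0] = 0).
// Non-ACGT characters count as non-GC and are tallied.
// [[Rcpp::export]]
List cpp_gc_profile(const std::string& seq) {
  R_xlen_t n = (R_xlen_t)seq.size();
  IntegerVector cum(n + 1);
  int amb = 0, acc = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    char b = seq[i];
    switch (b) {
      case 'G': case 'g': case 'C': case 'c': ++acc; break;
      case 'A': case 'a': case 'T': case 't': break;
      default: ++amb; break;
    }
    cum[i + 1] = acc;
  }
  return List::create(_["cum"] = cum, _["length"] = (double)n,
                      _["ambiguous"] = amb);
}

// Table of x * log2(x) for x = 0..n (0 at x = 0). Shared across scans so the
// Jensen-Shannon statistic needs only integer-indexed lookups per position.
// [[Rcpp::export]]
NumericVector cpp_xlog2x_table(int n) {
  if (n < 0) stop("n must be non-negative");
  NumericVector t(n + 1);
  t[0] = 0.0;
  for (int x = 1; x <= n; ++x) t[x] = (double)x * std::log2((double)x);
  return t;
}

// n * H(c/n) in bits, via the xlog2x identity n*H = L(n) - L(c) - L(n-c).
static inline double nH(const double* L, int c, int n) {
  return L[n] - L[c] - L[n - c];
}

// Maximal Jensen-Shannon split of the interval [from, to) (0-based, half-open)
// given cumulative GC counts. Scans every split offset s in
// [min_len, n - min_len]; ties broken by the leftmost position.
// Returns position (offset from segment start) and d_js in bits.
// [[Rcpp::export]]
List cpp_best_split(const IntegerVector& cum, int from, int to, int min_len,
                    const NumericVector& xlogx) {
  int n = to - from;
  if (from < 0 || to > cum.size() - 1 || n <= 0)
    stop("invalid interval [from, to)");
  if (n < 2 * min_len)
    return List::create(_["position"] = R_NilValue, _["d_js"] = R_NilValue);
  if (xlogx.size() < n + 1) stop("xlog2x table too short for this segment");
  const double* L = REAL(xlogx);
  const int* cu = INTEGER(cum);
  int c = cu[to] - cu[from];
  double whole = nH(L, c, n);
  double best = -1.0;
  int bestpos = -1;
  for (int s = min_len; s <= n - min_len; ++s) {
    int c1 = cu[from + s] - cu[from];
    double v = whole - nH(L, c1, s) - nH(L, c - c1, n - s);
    if (v > best) { best = v; bestpos = s; }
  }
  return List::create(_["position"] = bestpos, _["d_js"] = best / (double)n);
}

// Null distribution of the max-JS statistic: n_null homogeneous sequences of
// length n with iid GC probability gc, each reduced to its best_split value.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_null_max_js(int n, double gc, int n_null, int min_len,
                              const NumericVector& xlogx) {
  if (n < 2 * min_len) stop("n must be at least 2 * min_len");
  if (gc < 0.0 || gc > 1.0) stop("gc must lie in [0, 1]");
  if (xlogx.size() < n + 1) stop("xlog2x table too short for this length");
  const double* L = REAL(xlogx);
  NumericVector out(n_null);
  std::vector<int> cum((size_t)n + 1);
  for (int r = 0; r < n_null; ++r) {
    cum[0] = 0;
    int acc = 0;
    for (int i = 0; i < n; ++i) {
      if (unif_rand() < gc) ++acc;
      cum[(size_t)i + 1] = acc;
    }
    int c = cum[(size_t)n];
    double whole = nH(L, c, n);
    double best = -1.0;
    for (int s = min_len; s <= n - min_len; ++s) {
      int c1 = cum[(size_t)s];
      double v = whole - nH(L, c1, s) - nH(L, c - c1, n - s);
      if (v > best) best = v;
    }
    out[r] = best / (double)n;
  }
  return out;
}

// Shuffled domain codes (1=A, 2=C, 3=G, 4=T): fill by count, then
// Fisher-Yates using R's RNG (deterministic under set.seed()).
// [[Rcpp::export]]
IntegerVector cpp_domain_codes(int nA, int nC, int nG, int nT) {
  int n = nA + nC + nG + nT;
  IntegerVector v(n);
  int* p = INTEGER(v);
  int k = 0;
  for (int i = 0; i < nG; ++i) p[k++] = 3;
  for (int i = 0; i < nC; ++i) p[k++] = 2;
  for (int i = 0; i < nA; ++i) p[k++] = 1;
  for (int i = 0; i < nT; ++i) p[k++] = 4;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    int tmp = p[i]; p[i] = p[j]; p[j] = tmp;
  }
  return v;
}

// Codes to DNA string in one pass.
// [[Rcpp::export]]
String cpp_codes_to_dna(const IntegerVector& codes) {
  static const char map[5] = {'?', 'A', 'C', 'G', 'T'};
  R_xlen_t n = codes.size();
  std::string s((size_t)n, 'A');
  const int* p = INTEGER(codes);
  for (R_xlen_t i = 0; i < n; ++i) s[(size_t)i] = map[p[i]];
  return String(s);
}
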