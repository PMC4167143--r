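// Sliding-window Monte Carlo engine.
//
// Residues arrive as integer class codes: 0 = neutral (ambiguity codes,
// and gaps under ambiguous gap handling), 1..k = canonical states indexing
// the score matrix (GAP is the last state under fifth-state coding).
// A neutral code against anything contributes 0.
//
// Reproducibility contract: every (pair, window) gets its own RNG stream,
// seeded by a splitmix64 hash of (master seed, canonical pair index,
// window start). Results are therefore independent of the order in which
// pairs or windows are evaluated (serial == parallel).

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Stream {  // xorshift128+
  uint64_t s0, s1;
  Stream(uint64_t master, uint64_t pair_index, uint64_t win_start) {
    uint64_t x = master ^ (pair_index * 0xC2B2AE3D27D4EB4FULL)
                        ^ (win_start * 0x165667B19E3779F9ULL);
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t next() {
    uint64_t a = s0, b = s1;
    s0 = b;
    a ^= a << 23;
    a ^= a >> 17;
    a ^= b ^ (b >> 26);
    s1 = a;
    return a + b;
  }
  // uniform on {0, ..., n-1}; rejection sampling, no modulo bias
  inline int below(int n) {
    uint64_t bound = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t r;
    do { r = next(); } while (r >= bound);
    return (int)(r % (uint64_t)n);
  }
};

static inline double site_sc(int a, int b, const double *m, int k) {
  if (a == 0 || b == 0) return 0.0;
  return m[(a - 1) + (b - 1) * k];
}

// one permutation score: w draws for X, then w draws for Y
static inline double perm_score(Stream &rng, const int *x, const int *y,
                                int lo, int len, int w,
                                const double *m, int k) {
  int ax[64], ay[64];  // w is validated <= 64 on the R side
  for (int j = 0; j < w; ++j) ax[j] = x[lo + rng.below(len)];
  for (int j = 0; j < w; ++j) ay[j] = y[lo + rng.below(len)];
  double s = 0.0;
  for (int j = 0; j < w; ++j) s += site_sc(ax[j], ay[j], m, k);
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_null_scores(IntegerVector xcodes, IntegerVector ycodes,
                              NumericMatrix smat, int win_start, int w, int f,
                              int nperm, double master_seed,
                              double pair_index) {
  const int M = xcodes.size();
  const int k = smat.nrow();
  const int lo = std::max(0, win_start - f);
  const int hi = std::min(M, win_start + w + f);
  const int len = hi - lo;
  const int *x = INTEGER(xcodes);
  const int *y = INTEGER(ycodes);
  const double *m = REAL(smat);
  Stream rng((uint64_t)(int64_t)master_seed, (uint64_t)(int64_t)pair_index,
             (uint64_t)win_start);
  NumericVector out(nperm);
  for (int p = 0; p < nperm; ++p)
    out[p] = perm_score(rng, x, y, lo, len, w, m, k);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pair_profile(IntegerVector xcodes, IntegerVector ycodes,
                               NumericMatrix smat, int w, int f, int nperm,
                               double alpha, double master_seed,
                               double pair_index, bool coverage_norm) {
  const int M = xcodes.size();
  const int k = smat.nrow();
  const int *x = INTEGER(xcodes);
  const int *y = INTEGER(ycodes);
  const double *m = REAL(smat);
  const double thr = (1.0 - alpha) * (double)nperm - 1e-9;

  NumericVector profile(M);
  double *prof = REAL(profile);
  for (int i = 0; i < M; ++i) prof[i] = 0.0;

  // rolling observed score
  double observed = 0.0;
  for (int j = 0; j < w; ++j) observed += site_sc(x[j], y[j], m, k);

  for (int i = 0; i <= M - w; ++i) {
    if (i > 0) {
      observed -= site_sc(x[i - 1], y[i - 1], m, k);
      observed += site_sc(x[i + w - 1], y[i + w - 1], m, k);
    }
    const int lo = std::max(0, i - f);
    const int hi = std::min(M, i + w + f);
    const int len = hi - lo;
    Stream rng((uint64_t)(int64_t)master_seed, (uint64_t)(int64_t)pair_index,
               (uint64_t)i);
    int cnt = 0;
    for (int p = 0; p < nperm; ++p) {
      if (observed > perm_score(rng, x, y, lo, len, w, m, k)) ++cnt;
    }
    const double sign = ((double)cnt >= thr) ? 1.0 : -1.0;
    for (int j = i; j < i + w; ++j) prof[j] += sign;
  }

  if (coverage_norm) {
    const int nwin = M - w + 1;
    for (int i = 0; i < M; ++i) {
      int cov = std::min(i, nwin - 1) - std::max(0, i - w + 1) + 1;
      prof[i] /= (double)cov;
    }
  } else {
    for (int i = 0; i < M; ++i) prof[i] /= (double)w;
  }
  return profile;
}
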