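#include <Rcpp.h>
#include <stdint.h>
using namespace Rcpp;

// Leave-one-out bootstrap peak probability.
// For held-out value v and the k-1 remaining values, draw n_boot groups of
// size k-1 with replacement; the probability is the fraction of groups
// whose mean is strictly below v.
//
// The resampling indices come from a xorshift128+ generator seeded from
// R's RNG, so results are fully controlled by set.seed() while avoiding
// the per-draw overhead of unif_rand() (the hot loop runs ~10^9 times in
// a full experiment).

namespace {

struct XorShift128 {
  uint64_t s0, s1;
  explicit XorShift128() {
    // derive 128 bits of state from R's RNG stream
    s0 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
         (uint64_t)(unif_rand() * 4294967296.0);
    s1 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
         (uint64_t)(unif_rand() * 4294967296.0);
    if (s0 == 0 && s1 == 0) s1 = 0x9E3779B97F4A7C15ULL;
  }
  inline uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform index in [0, m): 64-bit multiply-shift, bias < 2^-32 for small m
  inline int index(int m) {
    return (int)(((__uint128_t)next() * (unsigned)m) >> 64);
  }
};

double boot_prob_impl(const double *rest, int m, double held, int n_boot,
                      XorShift128 &rng) {
  int hits = 0;
  const double thresh = held * m;
  for (int b = 0; b < n_boot; ++b) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += rest[rng.index(m)];
    if (s < thresh) ++hits;
  }
  return (double)hits / n_boot;
}

}  // namespace

// [[Rcpp::export]]
double boot_prob_cpp(NumericVector rest, double held, int n_boot) {
  XorShift128 rng;
  return boot_prob_impl(REAL(rest), rest.size(), held, n_boot, rng);
}

// Probabilities for every held-out index of one probe group.
// [[Rcpp::export]]
NumericVector boot_group_cpp(NumericVector values, int n_boot) {
  XorShift128 rng;
  int k = values.size();
  NumericVector out(k);
  std::vector<double> rest(k - 1);
  for (int i = 0; i < k; ++i) {
    int p = 0;
    for (int j = 0; j < k; ++j) if (j != i) rest[p++] = values[j];
    out[i] = boot_prob_impl(&rest[0], k - 1, values[i], n_boot, rng);
  }
  return out;
}
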