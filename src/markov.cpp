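#include <Rcpp.h>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

// Minimal PCG32 generator for the simulation inner loop; seeded from R's RNG
// on entry to each exported routine, so set.seed() fully determines output.
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  inline uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  inline double runif() { return next() * 2.3283064365386963e-10; }
};

static Pcg32 rng_from_R() {
  // two R draws -> 64-bit seed, two more -> stream id
  uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t c = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t d = (uint64_t)(unif_rand() * 4294967296.0);
  return Pcg32((a << 32) | b, (c << 32) | d);
}

// Sample an index from a cumulative probability row of length n (last entry 1).
static inline int sample_cum(Pcg32 &rng, const double *cum, int n) {
  double u = rng.runif();
  for (int i = 0; i < n - 1; ++i) {
    if (u < cum[i]) return i;
  }
  return n - 1;
}

// Generate one sequence of length L from an order-m chain into out (codes 0..3).
// init_cum: cumulative distribution over 4^m initial m-mers (length 4^m).
// trans_cum: 4^m x 4 cumulative transition rows, flattened row-major; rows with
// trans_ok[ctx] == 0 fall back to base_cum (order-0 distribution).
static void sim_one(Pcg32 &rng, int *out, int L, int order,
                    const double *init_cum, const double *trans_cum,
                    const int *trans_ok, const double *base_cum) {
  int m = order;
  int nctx = 1;
  for (int i = 0; i < m; ++i) nctx *= 4;
  int pos = 0;
  int ctx = 0;
  if (m > 0) {
    int start = sample_cum(rng, init_cum, nctx);
    // emit the m symbols of the sampled initial m-mer (most significant first)
    int shift = nctx / 4;
    int code = start;
    for (int j = 0; j < m && pos < L; ++j) {
      int b = code / shift;
      code -= b * shift;
      shift /= 4;
      out[pos++] = b;
    }
    ctx = start;
  }
  int mask = nctx - 1;  // nctx is a power of 4
  while (pos < L) {
    int b;
    if (m == 0) {
      b = sample_cum(rng, trans_cum, 4);
    } else if (trans_ok[ctx]) {
      b = sample_cum(rng, trans_cum + 4 * ctx, 4);
    } else {
      b = sample_cum(rng, base_cum, 4);
    }
    out[pos++] = b;
    if (m > 0) ctx = ((ctx * 4) + b) & mask;
  }
}

// [[Rcpp::export]]
CharacterVector cpp_sim_markov(int order, NumericVector init_cum,
                               NumericVector trans_cum, IntegerVector trans_ok,
                               NumericVector base_cum, IntegerVector lengths) {
  static const char *bases = "ACGT";
  int n = lengths.size();
  CharacterVector out(n);
  Pcg32 rng = rng_from_R();
  for (int s = 0; s < n; ++s) {
    int L = lengths[s];
    std::vector<int> codes(L);
    sim_one(rng, codes.data(), L, order, init_cum.begin(), trans_cum.begin(),
            trans_ok.begin(), base_cum.begin());
    std::string str(L, 'A');
    for (int i = 0; i < L; ++i) str[i] = bases[codes[i]];
    out[s] = str;
  }
  return out;
}

// Simulate B replicate sequence sets and count all 4^h words in each
// (overlapping windows, never spanning sequence boundaries). Returns the
// per-word sample mean and sd (denominator B-1) over replicates; if
// word_codes is non-empty only those words are accumulated/returned.
// [[Rcpp::export]]
List cpp_markov_null(int order, NumericVector init_cum, NumericVector trans_cum,
                     IntegerVector trans_ok, NumericVector base_cum,
                     IntegerVector lengths, int h, int B,
                     IntegerVector word_codes) {
  int nwords = 1;
  for (int i = 0; i < h; ++i) nwords *= 4;
  int wmask = nwords - 1;
  bool subset = word_codes.size() > 0;
  int nout = subset ? word_codes.size() : nwords;
  std::vector<double> sum(nout, 0.0), sumsq(nout, 0.0);
  std::vector<double> counts(nwords);
  int nseq = lengths.size();
  Pcg32 rng = rng_from_R();
  int m = order;
  int nctx = 1;
  for (int i = 0; i < m; ++i) nctx *= 4;
  int cmask = nctx - 1;
  const double *initc = init_cum.begin(), *transc = trans_cum.begin();
  const double *basec = base_cum.begin();
  const int *okv = trans_ok.begin();
  for (int b = 0; b < B; ++b) {
    std::memset(counts.data(), 0, nwords * sizeof(double));
    for (int s = 0; s < nseq; ++s) {
      int L = lengths[s];
      // simulate and count in one pass (no sequence materialized)
      int pos = 0, ctx = 0, widx = 0;
      if (m > 0) {
        int start = sample_cum(rng, initc, nctx);
        int shift = nctx / 4, code = start;
        for (int j = 0; j < m && pos < L; ++j) {
          int bb = code / shift;
          code -= bb * shift;
          shift /= 4;
          widx = ((widx * 4) + bb) & wmask;
          if (pos >= h - 1) counts[widx] += 1.0;
          ++pos;
        }
        ctx = start;
      }
      while (pos < L) {
        int bb;
        if (m == 0) {
          bb = sample_cum(rng, transc, 4);
        } else if (okv[ctx]) {
          bb = sample_cum(rng, transc + 4 * ctx, 4);
        } else {
          bb = sample_cum(rng, basec, 4);
        }
        widx = ((widx * 4) + bb) & wmask;
        if (pos >= h - 1) counts[widx] += 1.0;
        ++pos;
        if (m > 0) ctx = ((ctx * 4) + bb) & cmask;
      }
    }
    if (subset) {
      for (int j = 0; j < nout; ++j) {
        double c = counts[word_codes[j]];
        sum[j] += c;
        sumsq[j] += c * c;
      }
    } else {
      for (int j = 0; j < nwords; ++j) {
        sum[j] += counts[j];
        sumsq[j] += counts[j] * counts[j];
      }
    }
    if (b % 16 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector mean(nout), sd(nout);
  for (int j = 0; j < nout; ++j) {
    double mu = sum[j] / B;
    double var = (sumsq[j] - B * mu * mu) / (B - 1);
    if (var < 0) var = 0;
    mean[j] = mu;
    sd[j] = std::sqrt(var);
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}
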