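#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Deterministic xorshift64* RNG so training does not depend on R's RNG state
// and is bit-reproducible for a fixed seed on a given platform.
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}
static inline double runif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling and subword composition (fastText-style).
// sentences: list of integer vectors of 0-based word ids.
// subwords:  per word, 0-based row indices into the input matrix (the word's
//            own row plus its character n-gram rows).
// Returns the trained input matrix (n_rows x dim); output (context) vectors
// are discarded, as only input representations are used downstream.
// [[Rcpp::export(name = ".skipgram_train_cpp")]]
NumericMatrix skipgram_train_cpp(List sentences, List subwords, int n_rows,
                                 int vocab_size, IntegerVector word_count,
                                 int dim, int window, int epochs, int negative,
                                 double lr_start, double lr_end, int seed) {
  uint64_t rng = 0x9E3779B97F4A7C15ULL ^ (uint64_t)(seed + 1);
  for (int i = 0; i < 8; ++i) xorshift64(rng);  // warm up

  std::vector<double> in((size_t)n_rows * dim);
  std::vector<double> out((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < in.size(); ++i)
    in[i] = (runif01(rng) - 0.5) / dim;

  // unigram^0.75 negative-sampling table
  const int TABLE = 100000;
  std::vector<int> table(TABLE);
  {
    double z = 0.0;
    std::vector<double> pw(vocab_size);
    for (int w = 0; w < vocab_size; ++w) {
      pw[w] = std::pow((double)word_count[w], 0.75);
      z += pw[w];
    }
    int w = 0;
    double cum = pw[0] / z;
    for (int t = 0; t < TABLE; ++t) {
      table[t] = w;
      if ((t + 1.0) / TABLE > cum && w < vocab_size - 1) {
        ++w;
        cum += pw[w] / z;
      }
    }
  }

  // flatten sentences and subword lists
  int n_sent = sentences.size();
  std::vector<std::vector<int> > sent(n_sent);
  for (int s = 0; s < n_sent; ++s)
    sent[s] = as<std::vector<int> >(sentences[s]);
  std::vector<std::vector<int> > subs(vocab_size);
  for (int w = 0; w < vocab_size; ++w)
    subs[w] = as<std::vector<int> >(subwords[w]);

  long long total_tokens = 0;
  for (int s = 0; s < n_sent; ++s) total_tokens += (long long)sent[s].size();
  long long budget = total_tokens * (long long)epochs;
  long long done = 0;

  std::vector<double> hidden(dim), grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int> &sn = sent[s];
      int len = (int)sn.size();
      for (int c = 0; c < len; ++c) {
        double lr = lr_start - (lr_start - lr_end) * ((double)done / (double)budget);
        ++done;
        int center = sn[c];
        const std::vector<int> &sw = subs[center];
        double inv = 1.0 / (double)sw.size();
        for (int d = 0; d < dim; ++d) {
          double h = 0.0;
          for (size_t q = 0; q < sw.size(); ++q) h += in[(size_t)sw[q] * dim + d];
          hidden[d] = h * inv;
        }
        for (int off = -window; off <= window; ++off) {
          if (off == 0) continue;
          int cx = c + off;
          if (cx < 0 || cx >= len) continue;
          for (int d = 0; d < dim; ++d) grad[d] = 0.0;
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = sn[cx];
              label = 1.0;
            } else {
              target = table[(int)(runif01(rng) * TABLE)];
              if (target == sn[cx]) continue;
              label = 0.0;
            }
            double *ov = &out[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += hidden[d] * ov[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * ov[d];
              ov[d] += g * hidden[d];
            }
          }
          for (size_t q = 0; q < sw.size(); ++q) {
            double *iv = &in[(size_t)sw[q] * dim];
            for (int d = 0; d < dim; ++d) iv[d] += grad[d] * inv;
          }
        }
      }
    }
  }

  NumericMatrix res(n_rows, dim);
  for (int r = 0; r < n_rows; ++r)
    for (int d = 0; d < dim; ++d)
      res(r, d) = in[(size_t)r * dim + d];
  return res;
}
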