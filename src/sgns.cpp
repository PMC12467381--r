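#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Deterministic 64-bit xorshift RNG so training does not depend on R's
// RNG state and is bit-reproducible under a fixed seed.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static inline double fast_sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling (word2vec SGNS). `sentences` holds
// 0-based token ids; `counts` the unigram counts per vocabulary entry.
// Sentences are visited in order (no shuffling) so the run is
// deterministic given the seed.
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, IntegerVector counts, int dim,
                         int window, int epochs, int negative,
                         double lr, double lr_min, int seed) {
  const int V = counts.size();
  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);

  std::vector<double> syn0((size_t)V * dim);
  std::vector<double> syn1((size_t)V * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // unigram^0.75 table for negative sampling
  const int tab_size = 100000;
  std::vector<int> table(tab_size);
  {
    double z = 0.0;
    for (int v = 0; v < V; ++v) z += std::pow((double)counts[v], 0.75);
    int v = 0;
    double cum = std::pow((double)counts[0], 0.75) / z;
    for (int i = 0; i < tab_size; ++i) {
      table[i] = v;
      if ((double)(i + 1) / tab_size > cum && v < V - 1) {
        ++v;
        cum += std::pow((double)counts[v], 0.75) / z;
      }
    }
  }

  // total positions for linear learning-rate decay
  long total = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total += LENGTH(sentences[s]);
  total *= epochs;
  long done = 0;

  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int n = sent.size();
      for (int pos = 0; pos < n; ++pos) {
        double alpha = lr + (lr_min - lr) * ((double)done / (double)total);
        ++done;
        int b = rng.below(window); // dynamic window shrink, word2vec style
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= n) continue;
          int center = sent[pos];
          int context = sent[cpos];
          double *v_in = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int tgt;
            double label;
            if (d == 0) { tgt = context; label = 1.0; }
            else {
              tgt = table[rng.below(tab_size)];
              if (tgt == context) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)tgt * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v_in[k] * v_out[k];
            double g = (label - fast_sigmoid(f)) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
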