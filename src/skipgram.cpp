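#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// Skip-gram with negative sampling over a corpus of random walks
// (word2vec-style SGD, single-threaded so a fixed seed gives identical
// output). Walk node ids are 1-based; returns a vocab_size x dim matrix
// of input vectors.
//
// Notes: the effective window is shrunk uniformly per center token as in
// word2vec; negatives are drawn from the unigram distribution raised to
// 0.75; the learning rate decays linearly to alpha/10^4.
// [[Rcpp::export]]
NumericMatrix sgns_train(List walks, int vocab_size, int dim, int window,
                         int negative, double alpha, int epochs, int seed) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> cnt(vocab_size, 0.0);
  long long total_tokens = 0;
  for (int w = 0; w < walks.size(); ++w) {
    IntegerVector walk = walks[w];
    total_tokens += walk.size();
    for (int i = 0; i < walk.size(); ++i) cnt[walk[i] - 1] += 1.0;
  }
  if (total_tokens == 0) stop("empty walk corpus");

  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  double total_pow = 0.0;
  for (int v = 0; v < vocab_size; ++v) total_pow += std::pow(cnt[v], 0.75);
  {
    int v = 0;
    double cum = std::pow(cnt[0], 0.75) / total_pow;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if ((double)(i + 1) / table_size > cum && v < vocab_size - 1) {
        ++v;
        cum += std::pow(cnt[v], 0.75) / total_pow;
      }
    }
  }

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) syn0[i] = (unif(rng) - 0.5) / dim;

  long long processed = 0;
  const long long planned = total_tokens * (long long)epochs;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < walks.size(); ++w) {
      IntegerVector walk = walks[w];
      const int L = walk.size();
      for (int i = 0; i < L; ++i) {
        double lr = alpha * (1.0 - (double)processed / (double)(planned + 1));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        ++processed;
        const int shrink = (int)(unif(rng) * window);
        const size_t c0 = (size_t)(walk[i] - 1) * dim;
        for (int j = i - window + shrink; j <= i + window - shrink; ++j) {
          if (j == i || j < 0 || j >= L) continue;
          const int ctx = walk[j] - 1;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s <= negative; ++s) {
            int target;
            double label;
            if (s == 0) {
              target = ctx;
              label = 1.0;
            } else {
              target = table[(int)(unif(rng) * table_size)];
              if (target == ctx) continue;
              label = 0.0;
            }
            const size_t c1 = (size_t)target * dim;
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += syn0[c0 + k] * syn1[c1 + k];
            if (dot > 8.0) dot = 8.0;
            if (dot < -8.0) dot = -8.0;
            const double g = (label - 1.0 / (1.0 + std::exp(-dot))) * lr;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * syn1[c1 + k];
              syn1[c1 + k] += g * syn0[c0 + k];
            }
          }
          for (int k = 0; k < dim; ++k) syn0[c0 + k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k) out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
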