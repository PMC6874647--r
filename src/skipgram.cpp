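#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Skip-gram with negative sampling (word2vec-style), single-threaded and
// deterministic under a fixed seed. Sentences arrive as 0-based vocabulary
// index vectors; out-of-vocabulary tokens have already been dropped.

static inline unsigned long long next_rand(unsigned long long &s) {
  s = s * 25214903917ULL + 11ULL;
  return s;
}

// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sentences, int vocab_size,
                             NumericVector counts, int dim, int window,
                             int negative, int epochs, double alpha,
                             double sample, int seed) {
  const int table_size = 1000000;
  std::vector<int> table(table_size);
  // unigram^0.75 negative-sampling table
  double norm = 0.0;
  for (int i = 0; i < vocab_size; ++i) norm += std::pow(counts[i], 0.75);
  {
    int i = 0;
    double cum = std::pow(counts[0], 0.75) / norm;
    for (int a = 0; a < table_size; ++a) {
      table[a] = i;
      if ((double)a / table_size > cum && i < vocab_size - 1) {
        ++i;
        cum += std::pow(counts[i], 0.75) / norm;
      }
    }
  }

  unsigned long long rng = (unsigned long long)(unsigned int)seed + 1ULL;
  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t a = 0; a < syn0.size(); ++a) {
    syn0[a] = (((next_rand(rng) & 0xFFFF) / 65536.0) - 0.5) / dim;
  }

  long long total_words = 0;
  int n_sent = sentences.size();
  std::vector<IntegerVector> sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    sents[s] = sentences[s];
    total_words += sents[s].size();
  }

  // word2vec-style subsampling of frequent tokens: keep probability
  // (sqrt(f/sample) + 1) * sample / f with f the corpus frequency fraction
  std::vector<double> keep_prob(vocab_size, 1.0);
  if (sample > 0) {
    for (int i = 0; i < vocab_size; ++i) {
      const double f = counts[i] / (double)total_words;
      if (f > sample) {
        double kp = (std::sqrt(f / sample) + 1.0) * sample / f;
        keep_prob[i] = kp < 1.0 ? kp : 1.0;
      }
    }
  }
  std::vector<int> kept;
  const long long train_total = total_words * (long long)epochs + 1;
  long long processed = 0;
  const double min_alpha = alpha * 1e-4;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const IntegerVector &sen0 = sents[s];
      kept.clear();
      for (int i = 0; i < sen0.size(); ++i) {
        ++processed;
        if (keep_prob[sen0[i]] >= 1.0 ||
            (next_rand(rng) & 0xFFFF) / 65536.0 < keep_prob[sen0[i]]) {
          kept.push_back(sen0[i]);
        }
      }
      const std::vector<int> &sen = kept;
      const int len = (int)sen.size();
      for (int i = 0; i < len; ++i) {
        double lr = alpha * (1.0 - (double)processed / train_total);
        if (lr < min_alpha) lr = min_alpha;
        const int center = sen[i];
        const int b = (int)(next_rand(rng) % (unsigned long long)window);
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j == i || j < 0 || j >= len) continue;
          const int context = sen[j];
          double *v_in = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = context;
              label = 1.0;
            } else {
              target = table[next_rand(rng) % table_size];
              if (target == context) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int c = 0; c < dim; ++c) dot += v_in[c] * v_out[c];
            const double pred = 1.0 / (1.0 + std::exp(-dot));
            const double g = (label - pred) * lr;
            for (int c = 0; c < dim; ++c) {
              grad[c] += g * v_out[c];
              v_out[c] += g * v_in[c];
            }
          }
          for (int c = 0; c < dim; ++c) v_in[c] += grad[c];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int c = 0; c < dim; ++c) out(i, c) = syn0[(size_t)i * dim + c];
  return out;
}
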