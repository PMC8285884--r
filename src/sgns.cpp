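// Skip-gram with negative sampling, single-threaded and driven by R's RNG
// so that set.seed() gives bit-reproducible embeddings run-to-run.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// sentences: list of 0-based integer vectors over a vocabulary of size V
// counts:    token frequencies, used for the 0.75-power unigram table
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sentences, int vocab_size,
                             NumericVector counts, int dim, int window,
                             int iter, int negative, double alpha0) {
  const int V = vocab_size;
  RNGScope scope;

  // input vectors ~ U(-0.5/dim, 0.5/dim), output vectors zero
  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t k = 0; k < syn0.size(); ++k)
    syn0[k] = (unif_rand() - 0.5) / dim;

  // cumulative unigram^0.75 distribution for negative sampling
  std::vector<double> cum(V);
  double tot = 0.0;
  for (int v = 0; v < V; ++v) { tot += std::pow(counts[v], 0.75); cum[v] = tot; }

  long long total_tokens = 0;
  for (int si = 0; si < sentences.size(); ++si)
    total_tokens += Rf_length(VECTOR_ELT(sentences, si));
  const double train_words = (double)total_tokens * iter + 1.0;
  const double alpha_min = alpha0 * 1e-4;

  std::vector<double> neu1e(dim);
  long long processed = 0;

  for (int ep = 0; ep < iter; ++ep) {
    for (int si = 0; si < sentences.size(); ++si) {
      IntegerVector sent = sentences[si];
      const int len = sent.size();
      for (int t = 0; t < len; ++t) {
        double alpha = alpha0 * (1.0 - (double)processed / train_words);
        if (alpha < alpha_min) alpha = alpha_min;
        ++processed;
        const int center = sent[t];
        for (int off = -window; off <= window; ++off) {
          if (off == 0) continue;
          const int c = t + off;
          if (c < 0 || c >= len) continue;
          // input = context token, output target = center token
          const int input = sent[c];
          double *l1 = &syn0[(size_t)input * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = center;
              label = 1.0;
            } else {
              double u = unif_rand() * tot;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                             cum.begin());
              if (target >= V) target = V - 1;
              if (target == center) continue;
              label = 0.0;
            }
            double *l2 = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += l1[d] * l2[d];
            const double g = (label - sigmoid(f)) * alpha;
            for (int d = 0; d < dim; ++d) neu1e[d] += g * l2[d];
            for (int d = 0; d < dim; ++d) l2[d] += g * l1[d];
          }
          for (int d = 0; d < dim; ++d) l1[d] += neu1e[d];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
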