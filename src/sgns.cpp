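#include <Rcpp.h>
#include <random>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Skip-gram with negative sampling over a walk corpus.
//
// walks: list of 0-based integer token vectors (node ids).
// counts: per-token corpus frequency, used for the unigram^0.75 negative-
//         sampling distribution.
// Single-threaded; all randomness from one seeded mt19937, so training is
// bit-reproducible for a fixed corpus, seed and hyperparameters.
// Window is dynamic per position as in the reference word2vec scheme: the
// effective half-window is drawn uniformly from 1..window.
// Returns the input-side vectors (vocab_size x dim).
// [[Rcpp::export]]
NumericMatrix cpp_sgns_train(const List& walks, int vocab_size, int dim,
                             int window, int negative, int epochs,
                             double alpha, double min_alpha, int seed) {
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> u01(0.0, 1.0);

  const size_t V = static_cast<size_t>(vocab_size);
  const size_t D = static_cast<size_t>(dim);
  std::vector<double> syn0(V * D), syn1(V * D, 0.0);
  for (size_t i = 0; i < V * D; ++i)
    syn0[i] = (u01(rng) - 0.5) / dim;

  // corpus frequencies -> cumulative unigram^0.75 table
  std::vector<double> cnt(V, 0.0);
  long long total_tokens = 0;
  const R_xlen_t nw = walks.size();
  for (R_xlen_t iw = 0; iw < nw; ++iw) {
    IntegerVector wk = walks[iw];
    total_tokens += wk.size();
    for (int t : wk) cnt[t] += 1.0;
  }
  std::vector<double> cum(V);
  double acc = 0.0;
  for (size_t v = 0; v < V; ++v) {
    acc += std::pow(cnt[v], 0.75);
    cum[v] = acc;
  }
  const double cum_tot = acc;

  const double total_work =
      static_cast<double>(total_tokens) * static_cast<double>(epochs);
  long long done = 0;
  std::vector<double> grad_in(D);

  for (int ep = 0; ep < epochs; ++ep) {
    for (R_xlen_t iw = 0; iw < nw; ++iw) {
      IntegerVector wk = walks[iw];
      const int L = wk.size();
      for (int i = 0; i < L; ++i) {
        double lr = alpha - (alpha - min_alpha) * (static_cast<double>(done) / total_work);
        if (lr < min_alpha) lr = min_alpha;
        ++done;

        const int center = wk[i];
        const int b = static_cast<int>(u01(rng) * window);  // 0..window-1
        const int lo = std::max(0, i - window + b);
        const int hi = std::min(L - 1, i + window - b);
        double* vin = &syn0[static_cast<size_t>(center) * D];

        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          const int ctx = wk[j];
          std::fill(grad_in.begin(), grad_in.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = ctx;
              label = 1.0;
            } else {
              const double x = u01(rng) * cum_tot;
              target = static_cast<int>(
                  std::upper_bound(cum.begin(), cum.end(), x) - cum.begin());
              if (target >= vocab_size) target = vocab_size - 1;
              if (target == ctx) continue;
              label = 0.0;
            }
            double* vout = &syn1[static_cast<size_t>(target) * D];
            double f = 0.0;
            for (size_t k = 0; k < D; ++k) f += vin[k] * vout[k];
            const double sig = 1.0 / (1.0 + std::exp(-std::max(-12.0, std::min(12.0, f))));
            const double g = (label - sig) * lr;
            for (size_t k = 0; k < D; ++k) {
              grad_in[k] += g * vout[k];
              vout[k] += g * vin[k];
            }
          }
          for (size_t k = 0; k < D; ++k) vin[k] += grad_in[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = syn0[static_cast<size_t>(v) * D + k];
  return out;
}
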