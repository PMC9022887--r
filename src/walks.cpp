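#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

// Second-order (node2vec-style) random walks over an undirected graph.
//
// adj: adjacency as a list of 0-based integer vectors, each sorted ascending
//      (sortedness is required: the in-out bias uses binary search).
// Walk order is round-major: for each round r in 1..num_walks, every node is
// used once as a source, so the corpus has num_walks * n walks. A walk stops
// early only at a dead end (node with no neighbours).
// Randomness comes from a private mt19937 stream, independent of R's RNG.
// [[Rcpp::export]]
List cpp_node2vec_walks(const List& adj, int num_walks, int walk_length,
                        double p, double q, int seed) {
  const int n = adj.size();
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> u01(0.0, 1.0);

  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nbr[i].assign(v.begin(), v.end());
  }

  const bool unbiased = (p == 1.0 && q == 1.0);
  List out(static_cast<R_xlen_t>(num_walks) * n);
  R_xlen_t idx = 0;
  std::vector<int> walk;
  std::vector<double> w;

  for (int r = 0; r < num_walks; ++r) {
    for (int s = 0; s < n; ++s) {
      walk.clear();
      walk.push_back(s);
      while (static_cast<int>(walk.size()) < walk_length) {
        const int cur = walk.back();
        const std::vector<int>& nb = nbr[cur];
        if (nb.empty()) break;
        int nxt;
        if (unbiased || walk.size() == 1) {
          std::uniform_int_distribution<int> pick(0, static_cast<int>(nb.size()) - 1);
          nxt = nb[pick(rng)];
        } else {
          const int prev = walk[walk.size() - 2];
          const std::vector<int>& pn = nbr[prev];
          w.resize(nb.size());
          double tot = 0.0;
          for (size_t k = 0; k < nb.size(); ++k) {
            double wt;
            if (nb[k] == prev)
              wt = 1.0 / p;
            else if (std::binary_search(pn.begin(), pn.end(), nb[k]))
              wt = 1.0;
            else
              wt = 1.0 / q;
            w[k] = wt;
            tot += wt;
          }
          double x = u01(rng) * tot, acc = 0.0;
          size_t k = 0;
          for (; k + 1 < nb.size(); ++k) {
            acc += w[k];
            if (x <= acc) break;
          }
          nxt = nb[k];
        }
        walk.push_back(nxt);
      }
      out[idx++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return out;
}
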