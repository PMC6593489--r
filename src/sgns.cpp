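// Single-threaded skip-gram / negative-sampling SGD over a walk corpus.
// Two-matrix model (input vectors exposed, output vectors internal);
// deterministic for a fixed seed.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static inline double unif01(std::mt19937_64 &g) {
  return (g() >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoidc(double x) {
  if (x > 35.0) x = 35.0;
  if (x < -35.0) x = -35.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
NumericMatrix cpp_train_sgns(List walks, int n_nodes, int dim, int window,
                             int negative, double lr0, int epochs,
                             NumericVector neg_probs, int seed) {
  // Enumerate (center, context) pairs once; shuffled per epoch.
  std::vector<int> centers, contexts;
  for (int wi = 0; wi < walks.size(); ++wi) {
    IntegerVector walk = walks[wi];
    int L = walk.size();
    for (int i = 0; i < L; ++i) {
      int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
      for (int j = lo; j <= hi; ++j) {
        if (j == i) continue;
        centers.push_back(walk[i] - 1);
        contexts.push_back(walk[j] - 1);
      }
    }
  }
  const long long n_pairs = (long long)centers.size();
  if (n_pairs == 0) stop("walk corpus yields no context pairs");

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
                      3ULL);

  // cumulative distribution for non-uniform negative sampling
  const bool uniform = neg_probs.size() == 0;
  std::vector<double> cdf;
  if (!uniform) {
    cdf.resize(neg_probs.size());
    double acc = 0.0;
    for (int i = 0; i < neg_probs.size(); ++i) {
      acc += neg_probs[i];
      cdf[i] = acc;
    }
    cdf.back() = 1.0;
  }
  auto draw_node = [&]() -> int {
    if (uniform) {
      int u = (int)(unif01(rng) * n_nodes);
      return u >= n_nodes ? n_nodes - 1 : u;
    }
    double u = unif01(rng);
    return (int)(std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
  };

  std::vector<double> in((size_t)n_nodes * dim), out((size_t)n_nodes * dim,
                                                     0.0);
  for (size_t i = 0; i < in.size(); ++i)
    in[i] = (unif01(rng) - 0.5) / dim;

  std::vector<long long> order(n_pairs);
  for (long long i = 0; i < n_pairs; ++i) order[i] = i;
  std::vector<double> neu1e(dim);

  const double lr_min = lr0 * 1e-4;
  const long long total = (long long)epochs * n_pairs;
  long long step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle with the package RNG stream
    for (long long i = n_pairs - 1; i > 0; --i) {
      long long j = (long long)(unif01(rng) * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (long long oi = 0; oi < n_pairs; ++oi) {
      long long pi = order[oi];
      int v = centers[pi], t = contexts[pi];
      double lr = lr0 * (1.0 - (double)step / (double)total);
      if (lr < lr_min) lr = lr_min;
      double *fv = &in[(size_t)v * dim];
      std::fill(neu1e.begin(), neu1e.end(), 0.0);
      for (int s = 0; s < negative + 1; ++s) {
        int target;
        double label;
        if (s == 0) {
          target = t;
          label = 1.0;
        } else {
          do {
            target = draw_node();
          } while (target == t);
          label = 0.0;
        }
        double *ft = &out[(size_t)target * dim];
        double f = 0.0;
        for (int d = 0; d < dim; ++d) f += fv[d] * ft[d];
        double g = (label - sigmoidc(f)) * lr;
        for (int d = 0; d < dim; ++d) neu1e[d] += g * ft[d];
        for (int d = 0; d < dim; ++d) ft[d] += g * fv[d];
      }
      for (int d = 0; d < dim; ++d) fv[d] += neu1e[d];
      ++step;
    }
  }

  NumericMatrix emb(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) emb(i, d) = in[(size_t)i * dim + d];
  return emb;
}
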