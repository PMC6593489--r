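// Biased second-order random walks on a typed multigraph.
//
// The graph arrives flattened as CSR-style incidence arrays (0-based):
// for node v, its incident edges occupy slots ptr[v]..ptr[v+1]-1 of
// nbr/type/weight. Candidate enumeration is per incident edge, so
// parallel edges of different types are distinct candidates.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

// Portable uniform double in [0,1) from the fully specified mt19937_64
// stream (std::uniform_real_distribution is implementation-defined).
static inline double unif01(std::mt19937_64 &g) {
  return (g() >> 11) * (1.0 / 9007199254740992.0);
}

static inline int sample_cdf(const std::vector<double> &w, double total,
                             std::mt19937_64 &g) {
  double u = unif01(g) * total;
  double acc = 0.0;
  int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (u < acc) return i;
  }
  return n - 1;
}

// [[Rcpp::export]]
List cpp_generate_walks(IntegerVector ptr, IntegerVector nbr,
                        IntegerVector type, NumericVector weight,
                        NumericMatrix M, IntegerVector starts,
                        int walk_length, double p, double q, int seed) {
  const int n = ptr.size() - 1;
  // Sorted neighbor arrays for O(log deg) adjacency queries (distance to
  // the previous node).
  std::vector<std::vector<int>> sorted_nbr(n);
  for (int v = 0; v < n; ++v) {
    sorted_nbr[v].assign(nbr.begin() + ptr[v], nbr.begin() + ptr[v + 1]);
    std::sort(sorted_nbr[v].begin(), sorted_nbr[v].end());
  }
  auto adjacent = [&](int u, int k) {
    const std::vector<int> &s = sorted_nbr[u];
    return std::binary_search(s.begin(), s.end(), k);
  };

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
                      1ULL);
  const int n_walks = starts.size();
  List out_nodes(n_walks), out_types(n_walks);
  std::vector<double> score;

  for (int wi = 0; wi < n_walks; ++wi) {
    int cur = starts[wi];
    std::vector<int> wnodes, wtypes;
    wnodes.push_back(cur);
    int deg = ptr[cur + 1] - ptr[cur];
    if (deg > 0 && walk_length >= 2) {
      // first step: no previous edge, weight-proportional
      score.assign(weight.begin() + ptr[cur], weight.begin() + ptr[cur + 1]);
      double tot = 0.0;
      for (double s : score) tot += s;
      int pick = ptr[cur] + sample_cdf(score, tot, rng);
      int prev = cur, prev_type = type[pick];
      cur = nbr[pick];
      wnodes.push_back(cur);
      wtypes.push_back(prev_type);
      while ((int)wnodes.size() < walk_length) {
        int d0 = ptr[cur], d1 = ptr[cur + 1];
        if (d1 - d0 <= 0) break;  // dead end: truncate
        score.resize(d1 - d0);
        double total = 0.0;
        for (int e = d0; e < d1; ++e) {
          int k = nbr[e];
          double a = (k == prev) ? 1.0 / p
                     : (adjacent(prev, k) ? 1.0 : 1.0 / q);
          double s = weight[e] * M(prev_type, type[e]) * a;
          score[e - d0] = s;
          total += s;
        }
        if (total <= 0.0) break;
        int pe = d0 + sample_cdf(score, total, rng);
        prev = cur;
        prev_type = type[pe];
        cur = nbr[pe];
        wnodes.push_back(cur);
        wtypes.push_back(prev_type);
      }
    }
    IntegerVector nv(wnodes.size()), tv(wtypes.size());
    for (size_t i = 0; i < wnodes.size(); ++i) nv[i] = wnodes[i] + 1;
    for (size_t i = 0; i < wtypes.size(); ++i) tv[i] = wtypes[i] + 1;
    out_nodes[wi] = nv;
    out_types[wi] = tv;
  }
  return List::create(_["nodes"] = out_nodes, _["types"] = out_types);
}
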