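// Random-walk corpus + skip-gram with negative sampling, trained on the fly.
// Second-order walks use the return bias p and in-out bias q; with
// p == q == 1 the walk is a plain uniform random walk.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <random>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix node2vec_core(IntegerVector adj, IntegerVector ptr, int dims,
                            int walks_per_node, int walk_length, int window,
                            double p, double q, int negative, double lr0,
                            int seed) {
  const int n = ptr.size() - 1;
  std::mt19937 rng(static_cast<unsigned>(seed));
  auto runif01 = [&]() { return (rng() + 0.5) / 4294967296.0; };

  // precomputed logistic table (word2vec-style) over [-MAX_EXP, MAX_EXP]
  const int EXP_TABLE_SIZE = 1024;
  const float MAX_EXP = 6.0f;
  std::vector<float> sigm(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    float x = (i * 2.0f / EXP_TABLE_SIZE - 1.0f) * MAX_EXP;
    sigm[i] = 1.0f / (1.0f + std::exp(-x));
  }
  auto sigmoid = [&](float x) {
    if (x >= MAX_EXP) return 1.0f;
    if (x <= -MAX_EXP) return 0.0f;
    int i = static_cast<int>((x + MAX_EXP) * (EXP_TABLE_SIZE / (2.0f * MAX_EXP)));
    if (i < 0) i = 0;
    if (i >= EXP_TABLE_SIZE) i = EXP_TABLE_SIZE - 1;
    return sigm[i];
  };

  std::vector<float> emb(static_cast<size_t>(n) * dims);
  std::vector<float> ctx(static_cast<size_t>(n) * dims, 0.0f);
  for (auto& x : emb) x = static_cast<float>((runif01() - 0.5) / dims);

  const bool unbiased = (p == 1.0 && q == 1.0);
  std::vector<double> wts;
  std::vector<int> walk(walk_length);
  std::vector<float> grad(dims);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  const double total = static_cast<double>(walks_per_node) * n;
  double done = 0.0;

  auto degree = [&](int v) { return ptr[v + 1] - ptr[v]; };
  auto has_edge = [&](int a, int b) {
    return std::binary_search(adj.begin() + ptr[a], adj.begin() + ptr[a + 1],
                              b);  // adjacency lists arrive sorted
  };

  for (int w = 0; w < walks_per_node; ++w) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi) {
      int s = order[oi];
      double lr = lr0 * (1.0 - done / total);
      if (lr < lr0 * 0.0001) lr = lr0 * 0.0001;
      done += 1.0;
      if (degree(s) == 0) continue;
      // generate one walk
      int len = 0;
      walk[len++] = s;
      int prev = -1, cur = s;
      while (len < walk_length) {
        int d = degree(cur);
        if (d == 0) break;
        int nxt;
        if (unbiased || prev < 0) {
          nxt = adj[ptr[cur] + static_cast<int>(rng() % d)];
        } else {
          wts.resize(d);
          double tot = 0.0;
          for (int e = 0; e < d; ++e) {
            int cand = adj[ptr[cur] + e];
            double wt = (cand == prev) ? 1.0 / p
                        : (has_edge(prev, cand) ? 1.0 : 1.0 / q);
            tot += wt;
            wts[e] = tot;
          }
          double r = runif01() * tot;
          int e = static_cast<int>(std::lower_bound(wts.begin(), wts.end(), r)
                                   - wts.begin());
          if (e >= d) e = d - 1;
          nxt = adj[ptr[cur] + e];
        }
        walk[len++] = nxt;
        prev = cur;
        cur = nxt;
      }
      // skip-gram with negative sampling over the walk
      for (int i = 0; i < len; ++i) {
        int b = static_cast<int>(rng() % window);  // word2vec window shrink
        int lo = std::max(0, i - window + b);
        int hi = std::min(len - 1, i + window - b);
        int center = walk[i];
        float* vin = &emb[static_cast<size_t>(center) * dims];
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          std::fill(grad.begin(), grad.end(), 0.0f);
          for (int k = 0; k <= negative; ++k) {
            int target; float label;
            if (k == 0) { target = walk[j]; label = 1.0f; }
            else {
              target = static_cast<int>(rng() % n);
              if (target == walk[j]) continue;
              label = 0.0f;
            }
            float* __restrict vout = &ctx[static_cast<size_t>(target) * dims];
            float dot = 0.0f;
            for (int d2 = 0; d2 < dims; ++d2) dot += vin[d2] * vout[d2];
            float pred = sigmoid(dot);
            float g = static_cast<float>(lr) * (label - pred);
            for (int d2 = 0; d2 < dims; ++d2) {
              grad[d2] += g * vout[d2];
              vout[d2] += g * vin[d2];
            }
          }
          for (int d2 = 0; d2 < dims; ++d2) vin[d2] += grad[d2];
        }
      }
    }
  }
  NumericMatrix out(n, dims);
  for (int i = 0; i < n; ++i)
    for (int d2 = 0; d2 < dims; ++d2)
      out(i, d2) = emb[static_cast<size_t>(i) * dims + d2];
  return out;
}
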