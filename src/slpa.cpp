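// Speaker-listener label propagation (SLPA) core, with optional pairwise
// constraint guidance (PC-SLPA). Memories are per-node label histories; a
// speaker emits a uniformly sampled memory entry (i.e. proportional to label
// frequency) and the listener stores the highest-weight received label.
// Per-node label counts are maintained incrementally so the cannot-link
// repair step stays cheap.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <random>
using namespace Rcpp;

typedef std::unordered_map<int, int> LabelCounts;

static inline int mode_label(const LabelCounts& cnt, int& count_out) {
  int best = -1, bc = 0;
  for (auto& kv : cnt)
    if (kv.second > bc || (kv.second == bc && kv.first < best)) {
      best = kv.first; bc = kv.second;
    }
  count_out = bc;
  return best;
}

// most frequent label distinct from `exclude`; -1 when none exists
static inline int second_label(const LabelCounts& cnt, int exclude) {
  int best = -1, bc = 0;
  for (auto& kv : cnt) {
    if (kv.first == exclude) continue;
    if (kv.second > bc || (kv.second == bc && kv.first < best)) {
      best = kv.first; bc = kv.second;
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerMatrix slpa_core(IntegerVector adj, IntegerVector ptr, int rounds,
                        int seed, IntegerMatrix ml, IntegerMatrix cl,
                        double ml_weight) {
  const int n = ptr.size() - 1;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<std::vector<int>> mem(n);
  std::vector<LabelCounts> cnt(n);
  for (int i = 0; i < n; ++i) {
    mem[i].reserve(rounds + 1);
    mem[i].push_back(i);
    cnt[i][i] = 1;
  }

  // must-link partner lists (sorted) per node
  std::vector<std::vector<int>> mlp(n);
  for (int r = 0; r < ml.nrow(); ++r) {
    mlp[ml(r, 0)].push_back(ml(r, 1));
    mlp[ml(r, 1)].push_back(ml(r, 0));
  }
  for (int i = 0; i < n; ++i) std::sort(mlp[i].begin(), mlp[i].end());

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::unordered_map<int, double> received;
  received.reserve(64);

  for (int t = 0; t < rounds; ++t) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi) {
      int v = order[oi];
      received.clear();
      const std::vector<int>& mls = mlp[v];
      // neighbors speak with weight 1; must-link partners (neighbors or
      // not) speak with doubled weight
      for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
        int u = adj[e];
        if (std::binary_search(mls.begin(), mls.end(), u)) continue;
        const std::vector<int>& m = mem[u];
        received[m[rng() % m.size()]] += 1.0;
      }
      for (int u : mls) {
        const std::vector<int>& m = mem[u];
        received[m[rng() % m.size()]] += ml_weight;
      }
      int chosen;
      if (received.empty()) {  // isolated, unconstrained node
        chosen = mem[v][0];
      } else {
        double bw = -1.0; int ties = 0; chosen = -1;
        for (auto& kv : received) {
          if (kv.second > bw + 1e-12) {
            bw = kv.second; chosen = kv.first; ties = 1;
          } else if (kv.second > bw - 1e-12) {  // tie: reservoir sample
            ++ties;
            if (rng() % ties == 0) chosen = kv.first;
          }
        }
      }
      mem[v].push_back(chosen);
      cnt[v][chosen]++;
    }
    // cannot-link repair: if both endpoints currently agree on their top
    // label, the weaker attachment swaps one copy of it for its runner-up
    for (int r = 0; r < cl.nrow(); ++r) {
      int a = cl(r, 0), b = cl(r, 1);
      int ca, cb;
      int la = mode_label(cnt[a], ca);
      int lb = mode_label(cnt[b], cb);
      if (la != lb) continue;
      int weak = (ca < cb) ? a : (cb < ca ? b : (rng() % 2 ? a : b));
      int repl = second_label(cnt[weak], la);
      if (repl < 0) repl = weak;  // memory is pure: seed with own id
      for (auto it = mem[weak].rbegin(); it != mem[weak].rend(); ++it)
        if (*it == la) { *it = repl; break; }
      if (--cnt[weak][la] == 0) cnt[weak].erase(la);
      cnt[weak][repl]++;
    }
  }
  IntegerMatrix out(n, rounds + 1);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t <= rounds; ++t) out(i, t) = mem[i][t];
  return out;
}
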