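// Boykov-Kolmogorov max-flow / min-cut on sparse graphs, the standard
// solver for grid-structured vision problems (augmenting paths found by two
// search trees grown from source and sink, with orphan adoption).
//
// Terminal arcs are folded into per-node terminal capacities:
// tr_cap[i] > 0 means residual capacity from the source, < 0 toward the
// sink. Inner arcs are passed as from/to/cap triples (directed; the
// reverse residual arc is created automatically with capacity 0).
#include <Rcpp.h>
#include <vector>
#include <deque>
#include <queue>
#include <cstdint>
using namespace Rcpp;

namespace {

const int TERMINAL = -2;  // parent is a terminal
const int ORPHAN = -3;    // no parent (pending adoption)
const char FREE_T = 0, S_T = 1, T_T = 2;

struct BK {
  int n;
  std::vector<double> tr_cap;
  // CSR adjacency of directed residual arcs (stored in twin pairs)
  std::vector<int> head;      // arc target node
  std::vector<int> twin;      // index of reverse arc
  std::vector<double> rcap;   // residual capacity
  std::vector<int> first, nxt;  // linked adjacency: first[node], nxt[arc]
  std::vector<int> parent;    // arc from node toward its parent, or TERMINAL/ORPHAN/-1
  std::vector<char> tree;
  std::vector<int> ts, dist;
  std::deque<int> active;
  std::vector<char> in_active;
  std::deque<int> orphans;
  double flow = 0.0;
  int time = 0;

  BK(int n_) : n(n_), tr_cap(n_, 0.0), first(n_, -1), parent(n_, -1),
               tree(n_, FREE_T), ts(n_, 0), dist(n_, 0), in_active(n_, 0) {}

  void add_arc(int u, int v, double cap_uv, double cap_vu) {
    int a = (int)head.size(), b = a + 1;
    head.push_back(v); head.push_back(u);
    twin.push_back(b); twin.push_back(a);
    rcap.push_back(cap_uv); rcap.push_back(cap_vu);
    nxt.push_back(first[u]); first[u] = a;
    nxt.push_back(first[v]); first[v] = b;
  }

  void activate(int i) {
    if (!in_active[i]) { in_active[i] = 1; active.push_back(i); }
  }

  int next_active() {
    while (!active.empty()) {
      int i = active.front();
      if (tree[i] == FREE_T) { active.pop_front(); in_active[i] = 0; continue; }
      return i;
    }
    return -1;
  }

  // walk to the terminal to verify the origin of i; mark timestamps
  bool has_origin(int i) {
    int j = i, d = 0;
    while (true) {
      if (ts[j] == time) { d += dist[j]; break; }
      int pa = parent[j];
      if (pa == TERMINAL) { ++d; break; }
      if (pa == ORPHAN || pa == -1) return false;
      j = head[pa];
      ++d;
    }
    // second pass: set ts/dist along the verified chain
    int dd = d;
    j = i;
    while (ts[j] != time) {
      ts[j] = time;
      dist[j] = dd--;
      int pa = parent[j];
      if (pa == TERMINAL) break;
      j = head[pa];
    }
    return true;
  }

  void augment(int a_st) {
    // a_st: arc from an S-tree node to a T-tree node with rcap > 0
    double bottleneck = rcap[a_st];
    // source side
    int i = head[twin[a_st]];
    while (parent[i] != TERMINAL) {
      int pa = parent[i];                 // arc i -> parent
      double c = rcap[twin[pa]];          // residual parent -> i
      if (c < bottleneck) bottleneck = c;
      i = head[pa];
    }
    if (tr_cap[i] < bottleneck) bottleneck = tr_cap[i];
    // sink side
    int j = head[a_st];
    while (parent[j] != TERMINAL) {
      int pa = parent[j];                 // arc j -> parent (toward sink)
      double c = rcap[pa];
      if (c < bottleneck) bottleneck = c;
      j = head[pa];
    }
    if (-tr_cap[j] < bottleneck) bottleneck = -tr_cap[j];

    // push
    rcap[a_st] -= bottleneck; rcap[twin[a_st]] += bottleneck;
    i = head[twin[a_st]];
    while (parent[i] != TERMINAL) {
      int pa = parent[i];
      rcap[twin[pa]] -= bottleneck;
      rcap[pa] += bottleneck;
      if (rcap[twin[pa]] <= 0) { parent[i] = ORPHAN; orphans.push_back(i); }
      i = head[pa];
    }
    tr_cap[i] -= bottleneck;
    if (tr_cap[i] <= 0) { parent[i] = ORPHAN; orphans.push_back(i); }
    j = head[a_st];
    while (parent[j] != TERMINAL) {
      int pa = parent[j];
      rcap[pa] -= bottleneck;
      rcap[twin[pa]] += bottleneck;
      if (rcap[pa] <= 0) { parent[j] = ORPHAN; orphans.push_back(j); }
      j = head[pa];
    }
    tr_cap[j] += bottleneck;
    if (tr_cap[j] >= 0) { parent[j] = ORPHAN; orphans.push_back(j); }
    flow += bottleneck;
  }

  void process_orphan(int i) {
    char tr = tree[i];
    int best_arc = -1, best_d = INT32_MAX;
    for (int a = first[i]; a != -1; a = nxt[a]) {
      // need residual from neighbour j toward i (S) or i toward j (T)
      double c = (tr == S_T) ? rcap[twin[a]] : rcap[a];
      if (c <= 0) continue;
      int j = head[a];
      if (tree[j] != tr || parent[j] == -1) continue;
      if (parent[j] == ORPHAN) continue;
      if (!has_origin(j)) continue;
      int d = dist[j] + 1;
      if (d < best_d) { best_d = d; best_arc = a; }
    }
    if (best_arc != -1) {
      parent[i] = best_arc;
      ts[i] = time;
      dist[i] = best_d;
    } else {
      // i becomes free; invalidate children, activate potential parents
      for (int a = first[i]; a != -1; a = nxt[a]) {
        int j = head[a];
        if (tree[j] != tr) continue;
        double c = (tr == S_T) ? rcap[twin[a]] : rcap[a];
        if (c > 0) activate(j);
        int pa = parent[j];
        if (pa >= 0 && head[pa] == i) {
          parent[j] = ORPHAN;
          orphans.push_back(j);
        }
      }
      tree[i] = FREE_T;
      in_active[i] = 0;  // lazily skipped in next_active
    }
  }

  double run() {
    for (int i = 0; i < n; ++i) {
      if (tr_cap[i] > 0) {
        tree[i] = S_T; parent[i] = TERMINAL; dist[i] = 1; ts[i] = 0;
        activate(i);
      } else if (tr_cap[i] < 0) {
        tree[i] = T_T; parent[i] = TERMINAL; dist[i] = 1; ts[i] = 0;
        activate(i);
      }
    }
    while (true) {
      int i = next_active();
      if (i < 0) break;
      int found_arc = -1;
      char tr = tree[i];
      for (int a = first[i]; a != -1; a = nxt[a]) {
        double c = (tr == S_T) ? rcap[a] : rcap[twin[a]];
        if (c <= 0) continue;
        int j = head[a];
        if (tree[j] == FREE_T) {
          tree[j] = tr;
          parent[j] = twin[a];  // arc j -> i
          ts[j] = ts[i];
          dist[j] = dist[i] + 1;
          activate(j);
        } else if (tree[j] != tr) {
          found_arc = (tr == S_T) ? a : twin[a];
          break;
        } else if (ts[j] <= ts[i] && dist[j] > dist[i] + 1) {
          // heuristic: shorter path to the terminal
          parent[j] = twin[a];
          ts[j] = ts[i];
          dist[j] = dist[i] + 1;
        }
      }
      ++time;
      if (found_arc < 0) {
        active.pop_front();
        in_active[i] = 0;
        continue;
      }
      augment(found_arc);
      while (!orphans.empty()) {
        int o = orphans.front();
        orphans.pop_front();
        process_orphan(o);
      }
      // i stays active (front of the queue)
    }
    return flow;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_maxflow(int n, IntegerVector from, IntegerVector to,
                 NumericVector cap, NumericVector terminal_cap) {
  BK g(n);
  double base = 0.0;
  for (int i = 0; i < n; ++i) {
    double t = terminal_cap[i];
    g.tr_cap[i] = t;
  }
  (void)base;
  int m = from.size();
  for (int e = 0; e < m; ++e) {
    g.add_arc(from[e] - 1, to[e] - 1, cap[e], 0.0);
  }
  double f = g.run();
  LogicalVector source_side(n);
  for (int i = 0; i < n; ++i) source_side[i] = (g.tree[i] == S_T);
  return List::create(_["flow"] = f, _["source_side"] = source_side);
}
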