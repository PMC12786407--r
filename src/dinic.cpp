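// Dinic maximum-flow on an explicit arc list with paired reverse arcs.
// Vertices and arc endpoints arrive 0-based from the R wrappers.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

static std::vector<std::vector<int> > build_adj(int n, const IntegerVector &from) {
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < from.size(); ++i) adj[from[i]].push_back(i);
  return adj;
}

static std::vector<int> bfs_levels_impl(int n,
                                        const std::vector<std::vector<int> > &adj,
                                        const IntegerVector &to,
                                        const std::vector<double> &res,
                                        int s, double tol) {
  std::vector<int> lev(n, -1);
  std::queue<int> q;
  lev[s] = 0;
  q.push(s);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int a = adj[v][k];
      int w = to[a];
      if (res[a] > tol && lev[w] < 0) { lev[w] = lev[v] + 1; q.push(w); }
    }
  }
  return lev;
}

// Current-arc DFS with an explicit stack: each phase is O(V * E).
static double blocking_flow_impl(int n,
                                 const std::vector<std::vector<int> > &adj,
                                 const IntegerVector &from,
                                 const IntegerVector &to,
                                 const IntegerVector &pair_idx,
                                 std::vector<double> &res,
                                 std::vector<int> &lev,
                                 int s, int t, double tol) {
  std::vector<size_t> it(n, 0);
  std::vector<int> path;   // arc indices of the current s -> v path
  double total = 0.0;
  const double INF = std::numeric_limits<double>::infinity();
  int v = s;
  for (;;) {
    if (v == t) {
      double f = INF;
      for (size_t k = 0; k < path.size(); ++k)
        if (res[path[k]] < f) f = res[path[k]];
      for (size_t k = 0; k < path.size(); ++k) {
        int a = path[k];
        res[a] -= f;
        res[pair_idx[a]] += f;
      }
      total += f;
      // retreat to the tail of the first saturated arc
      size_t k = 0;
      while (k < path.size() && res[path[k]] > tol) ++k;
      if (k == path.size()) k = path.size() - 1;  // defensive; bottleneck saturates
      v = from[path[k]];
      path.resize(k);
      continue;
    }
    bool advanced = false;
    while (it[v] < adj[v].size()) {
      int a = adj[v][it[v]];
      if (res[a] > tol && lev[to[a]] == lev[v] + 1) {
        path.push_back(a);
        v = to[a];
        advanced = true;
        break;
      }
      ++it[v];
    }
    if (advanced) continue;
    if (v == s) break;
    lev[v] = -1;             // dead end: prune from the level graph
    int a = path.back();
    path.pop_back();
    v = from[a];
    ++it[v];
  }
  return total;
}

// [[Rcpp::export]]
IntegerVector cpp_bfs_levels(int n, IntegerVector from, IntegerVector to,
                             NumericVector res, int s, double tol) {
  std::vector<std::vector<int> > adj = build_adj(n, from);
  std::vector<double> r(res.begin(), res.end());
  std::vector<int> lev = bfs_levels_impl(n, adj, to, r, s, tol);
  return IntegerVector(lev.begin(), lev.end());
}

// [[Rcpp::export]]
List cpp_blocking_flow(int n, IntegerVector from, IntegerVector to,
                       IntegerVector pair_idx, NumericVector res,
                       IntegerVector level, int s, int t, double tol) {
  std::vector<std::vector<int> > adj = build_adj(n, from);
  std::vector<double> r(res.begin(), res.end());
  std::vector<int> lev(level.begin(), level.end());
  double inc = 0.0;
  if (t >= 0 && t < n && lev[t] >= 0)
    inc = blocking_flow_impl(n, adj, from, to, pair_idx, r, lev, s, t, tol);
  return List::create(_["res"] = NumericVector(r.begin(), r.end()),
                      _["increment"] = inc);
}

// [[Rcpp::export]]
List cpp_dinic(int n, IntegerVector from, IntegerVector to,
               IntegerVector pair_idx, NumericVector res,
               int s, int t, double tol) {
  std::vector<std::vector<int> > adj = build_adj(n, from);
  std::vector<double> r(res.begin(), res.end());
  double flow = 0.0;
  std::vector<int> t_levels;  // level(t) at the start of each phase
  for (;;) {
    std::vector<int> lev = bfs_levels_impl(n, adj, to, r, s, tol);
    if (lev[t] < 0) break;
    t_levels.push_back(lev[t]);
    double inc = blocking_flow_impl(n, adj, from, to, pair_idx, r, lev, s, t, tol);
    if (inc <= tol) break;   // numerically exhausted
    flow += inc;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["flow"] = flow,
                      _["res"] = NumericVector(r.begin(), r.end()),
                      _["t_levels"] = IntegerVector(t_levels.begin(), t_levels.end()));
}

// [[Rcpp::export]]
LogicalVector cpp_reachable(int n, IntegerVector from, IntegerVector to,
                            NumericVector res, int s, double tol) {
  std::vector<std::vector<int> > adj = build_adj(n, from);
  std::vector<double> r(res.begin(), res.end());
  std::vector<int> lev = bfs_levels_impl(n, adj, to, r, s, tol);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = lev[i] >= 0;
  return out;
}
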