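#include <Rcpp.h>
using namespace Rcpp;

// BFS connectivity on a dense 0/1 adjacency matrix.
static bool connected(const IntegerMatrix& adj, int n) {
  std::vector<int> stack;
  std::vector<bool> seen(n, false);
  stack.push_back(0);
  seen[0] = true;
  int found = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (int w = 0; w < n; ++w) {
      if (adj(v, w) && !seen[w]) {
        seen[w] = true;
        ++found;
        stack.push_back(w);
      }
    }
  }
  return found == n;
}

// Constrained connected double-edge swap. Each attempt draws two edge
// indices and two orientation bits (4 uniform draws from R's RNG, in that
// order, matching the pure-R reference implementation). The attempt
// succeeds only if the proposed replacement edges are absent, non-forbidden,
// create no self-loop, and leave the graph connected.
// [[Rcpp::export]]
List cpp_shuffle(IntegerMatrix adjacency, IntegerMatrix edges,
                 LogicalMatrix forbidden, int attempts) {
  IntegerMatrix adj = clone(adjacency);
  IntegerMatrix el = clone(edges); // m x 2, 1-based vertex indices
  int n = adj.nrow();
  int m = el.nrow();
  int successes = 0;
  RNGScope scope;
  for (int t = 0; t < attempts; ++t) {
    int e1 = (int)std::floor(unif_rand() * m);
    int e2 = (int)std::floor(unif_rand() * m);
    bool f1 = unif_rand() < 0.5;
    bool f2 = unif_rand() < 0.5;
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int i = el(e1, f1 ? 1 : 0) - 1;
    int j = el(e1, f1 ? 0 : 1) - 1;
    int v = el(e2, f2 ? 1 : 0) - 1;
    int u = el(e2, f2 ? 0 : 1) - 1;
    // propose (i,v) and (j,u) replacing (i,j) and (v,u)
    if (i == v || j == u) continue;          // self-loops
    if (adj(i, v) || adj(j, u)) continue;    // duplicates (covers shared nodes)
    if (forbidden(i, v) || forbidden(j, u)) continue;
    adj(i, j) = adj(j, i) = 0;
    adj(v, u) = adj(u, v) = 0;
    adj(i, v) = adj(v, i) = 1;
    adj(j, u) = adj(u, j) = 1;
    if (connected(adj, n)) {
      el(e1, 0) = i + 1; el(e1, 1) = v + 1;
      el(e2, 0) = j + 1; el(e2, 1) = u + 1;
      ++successes;
    } else {
      adj(i, v) = adj(v, i) = 0;
      adj(j, u) = adj(u, j) = 0;
      adj(i, j) = adj(j, i) = 1;
      adj(v, u) = adj(u, v) = 1;
    }
  }
  return List::create(_["adjacency"] = adj, _["edges"] = el,
                      _["n_success"] = successes);
}
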