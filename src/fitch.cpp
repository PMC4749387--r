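#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fitch downpass step counts per character for an unordered multistate
// matrix encoded as bitmasks (bit s set <=> state s in the cell's set;
// missing cells carry the full mask). The tree is given as an undirected
// edge list over nodes 1..M with tips 1..nTip; it may be unrooted (internal
// degree 3) or rooted (one internal of degree 2). Polytomies are combined
// sequentially, which equals the binary Fitch count on binary trees.
// [[Rcpp::export]]
IntegerVector fitch_steps_cpp(IntegerMatrix edge, int nTip, IntegerMatrix masks) {
  const int m = edge.nrow();
  const int nChar = masks.ncol();
  int M = 0;
  for (int i = 0; i < m; ++i) {
    if (edge(i, 0) > M) M = edge(i, 0);
    if (edge(i, 1) > M) M = edge(i, 1);
  }
  // adjacency (CSR)
  std::vector<int> deg(M + 1, 0);
  for (int i = 0; i < m; ++i) { deg[edge(i, 0)]++; deg[edge(i, 1)]++; }
  std::vector<int> start(M + 2, 0);
  for (int v = 1; v <= M; ++v) start[v + 1] = start[v] + deg[v];
  std::vector<int> adj(2 * m);
  std::vector<int> fill(M + 1, 0);
  for (int i = 0; i < m; ++i) {
    int a = edge(i, 0), b = edge(i, 1);
    adj[start[a] + fill[a]++] = b;
    adj[start[b] + fill[b]++] = a;
  }
  // root at any internal node actually present (ids need not be contiguous)
  int root = 0;
  for (int i = 0; i < m && !root; ++i) {
    if (edge(i, 0) > nTip) root = edge(i, 0);
    else if (edge(i, 1) > nTip) root = edge(i, 1);
  }
  if (!root) root = 1;  // degenerate: tips only
  // iterative DFS to get parent + postorder
  std::vector<int> parent(M + 1, 0), order; order.reserve(M);
  std::vector<int> stack; stack.reserve(M);
  stack.push_back(root); parent[root] = -1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    for (int k = start[v]; k < start[v + 1]; ++k) {
      int w = adj[k];
      if (w != parent[v]) { parent[w] = v; stack.push_back(w); }
    }
  }
  // postorder = reverse of preorder for trees
  IntegerVector steps(nChar);
  std::vector<int> state(M + 1);
  for (int c = 0; c < nChar; ++c) {
    int s = 0;
    for (int oi = (int)order.size() - 1; oi >= 0; --oi) {
      int v = order[oi];
      if (v <= nTip) { state[v] = masks(v - 1, c); continue; }
      int acc = 0;
      for (int k = start[v]; k < start[v + 1]; ++k) {
        int w = adj[k];
        if (w == parent[v]) continue;
        if (acc == 0) { acc = state[w]; continue; }
        int inter = acc & state[w];
        if (inter) acc = inter; else { acc |= state[w]; ++s; }
      }
      state[v] = acc;
    }
    steps[c] = s;
  }
  return steps;
}
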