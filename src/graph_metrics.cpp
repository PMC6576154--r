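#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// All-pairs shortest-path hop counts on a binary undirected graph by
// breadth-first search from every source. Unreachable pairs get +Inf.
// [[Rcpp::export(name = ".bfs_distances")]]
NumericMatrix bfs_distances(IntegerMatrix A) {
  const int n = A.nrow();
  std::vector< std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0 && i != j) adj[i].push_back(j);

  NumericMatrix D(n, n);
  std::fill(D.begin(), D.end(), R_PosInf);
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; queue[tail++] = w; }
      }
    }
    for (int j = 0; j < n; ++j)
      if (dist[j] >= 0) D(s, j) = dist[j];
  }
  return D;
}

// Brandes (2001) betweenness centrality for binary undirected graphs.
// Accumulates over unordered source-target pairs (endpoints excluded),
// unnormalized: the ordered-pair sum is halved at the end.
// [[Rcpp::export(name = ".brandes_betweenness")]]
NumericVector brandes_betweenness(IntegerMatrix A) {
  const int n = A.nrow();
  std::vector< std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0 && i != j) adj[i].push_back(j);

  NumericVector bc(n, 0.0);
  std::vector<int> dist(n), order(n);
  std::vector<double> sigma(n), delta(n);
  std::vector< std::vector<int> > pred(n);

  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < n; ++i) { dist[i] = -1; sigma[i] = 0.0; pred[i].clear(); }
    dist[s] = 0; sigma[s] = 1.0;
    int head = 0, tail = 0;
    order[tail++] = s;
    while (head < tail) {
      int v = order[head++];
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; order[tail++] = w; }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int k = tail - 1; k >= 0; --k) {
      int w = order[k];
      for (size_t q = 0; q < pred[w].size(); ++q) {
        int v = pred[w][q];
        delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;  // unordered pairs
  return bc;
}

// Maximum connected-component size (in edges) of the graph formed by the
// given edge list, via union-find. Edges are 0-based node indices.
// [[Rcpp::export(name = ".max_component_edges")]]
int max_component_edges(IntegerVector ei, IntegerVector ej, int n_nodes) {
  const int m = ei.size();
  if (m == 0) return 0;
  std::vector<int> parent(n_nodes);
  for (int i = 0; i < n_nodes; ++i) parent[i] = i;
  // find with path halving
  #define FIND(x, r) { r = x; while (parent[r] != r) { parent[r] = parent[parent[r]]; r = parent[r]; } }
  for (int k = 0; k < m; ++k) {
    int a, b;
    FIND(ei[k], a);
    FIND(ej[k], b);
    if (a != b) parent[a] = b;
  }
  std::vector<int> count(n_nodes, 0);
  int best = 0;
  for (int k = 0; k < m; ++k) {
    int a;
    FIND(ei[k], a);
    if (++count[a] > best) best = count[a];
  }
  #undef FIND
  return best;
}
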