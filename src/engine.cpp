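#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Weighted union-find with path halving. Nodes are 0-based.
struct UnionFind {
  std::vector<int> parent;
  std::vector<int> size;
  explicit UnionFind(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    int ra = find(a), rb = find(b);
    if (ra == rb) return;
    if (size[ra] < size[rb]) std::swap(ra, rb);
    parent[rb] = ra;
    size[ra] += size[rb];
  }
};

// Canonical labels: each node gets the smallest node id of its component,
// so equal partitions compare equal element-wise.
static IntegerVector canonical_labels(UnionFind &uf, int n) {
  IntegerVector labels(n);
  std::vector<int> rep(n, -1);
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (rep[r] < 0) rep[r] = i;  // first (smallest) node seen for this root
    labels[i] = rep[r];
  }
  return labels;
}

// [[Rcpp::export]]
IntegerVector cc_labels_cpp(IntegerMatrix edges, int n_nodes) {
  UnionFind uf(n_nodes);
  int m = edges.nrow();
  for (int e = 0; e < m; ++e) uf.unite(edges(e, 0), edges(e, 1));
  return canonical_labels(uf, n_nodes);
}

// One generation: connected components of the subgraph formed by layer
// edges whose endpoints share a cluster label.
// [[Rcpp::export]]
IntegerVector apply_layer_cpp(IntegerVector labels, IntegerMatrix edges) {
  int n = labels.size();
  UnionFind uf(n);
  int m = edges.nrow();
  for (int e = 0; e < m; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    if (labels[u] == labels[v]) uf.unite(u, v);
  }
  return canonical_labels(uf, n);
}

static void partition_stats(const IntegerVector &labels, int n,
                            double &largest, double &second,
                            int &n_clusters, std::vector<int> &sizes_out,
                            bool want_sizes) {
  std::vector<int> count(n, 0);
  for (int i = 0; i < n; ++i) count[labels[i]]++;
  largest = 0; second = 0; n_clusters = 0;
  if (want_sizes) sizes_out.clear();
  for (int i = 0; i < n; ++i) {
    int c = count[i];
    if (c == 0) continue;
    n_clusters++;
    if (want_sizes) sizes_out.push_back(c);
    if (c > largest) { second = largest; largest = c; }
    else if (c > second) second = c;
  }
  if (want_sizes) std::sort(sizes_out.begin(), sizes_out.end(), std::greater<int>());
}

// Full generational percolation. Layers are used cyclically; C^0 is the
// universal cluster. Steady state for L = 2: one unchanged application at
// generation >= 2 (idempotence makes it sufficient); for L > 2 a full
// unchanged cycle of L applications is required.
// [[Rcpp::export]]
List percolate_cpp(List layers, int n_nodes, int max_generations,
                   bool stop_at_steady, bool record_sizes) {
  int L = layers.size();
  int needed = (L == 2) ? 1 : L;
  IntegerVector labels(n_nodes, 0);  // universal cluster
  std::vector<double> psi, n2;
  std::vector<int> nclust;
  List sizes_list(record_sizes ? max_generations : 0);
  int streak = 0;
  int n_c = NA_INTEGER;
  bool converged = false;
  int gen = 0;
  std::vector<int> sizes;
  for (gen = 1; gen <= max_generations; ++gen) {
    IntegerMatrix layer = layers[(gen - 1) % L];
    IntegerVector next = apply_layer_cpp(labels, layer);
    bool same = true;
    if (gen >= 2) {
      for (int i = 0; i < n_nodes; ++i)
        if (next[i] != labels[i]) { same = false; break; }
    } else same = false;
    double largest, second;
    int nc;
    partition_stats(next, n_nodes, largest, second, nc, sizes, record_sizes);
    psi.push_back(largest / n_nodes);
    n2.push_back(second);
    nclust.push_back(nc);
    if (record_sizes) sizes_list[gen - 1] = wrap(sizes);
    labels = next;
    streak = same ? streak + 1 : 0;
    if (streak >= needed && !converged) {
      converged = true;
      n_c = gen - needed;
    }
    if (converged && stop_at_steady) break;
  }
  int n_gen = psi.size();
  List out = List::create(
    _["psi"] = wrap(psi),
    _["second_largest"] = wrap(n2),
    _["n_clusters"] = wrap(nclust),
    _["n_c"] = n_c,
    _["converged"] = converged,
    _["n_generations"] = n_gen,
    _["labels"] = labels);
  if (record_sizes) {
    List trimmed(n_gen);
    for (int i = 0; i < n_gen; ++i) trimmed[i] = sizes_list[i];
    out["sizes"] = trimmed;
  }
  return out;
}
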