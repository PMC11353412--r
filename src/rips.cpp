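#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Vietoris-Rips persistence in dimensions 0 and 1 over the Euclidean metric.
//
// Dimension 0 is single-linkage: deaths are the weights of the edges that
// merge union-find components, processed in filtration order. Dimension 1
// uses the standard boundary-matrix reduction over GF(2): columns are
// triangle boundaries (3 edge indices) processed in filtration order;
// a reduced column's pivot edge is the positive edge whose cycle the
// triangle kills. Triangles are never stored globally: a triangle is
// enumerated at its maximal edge, so processing edges in sorted order
// visits triangle columns in a valid refinement of the filtration order.

namespace {

struct Edge {
  double w;
  int u, v;
};

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  // returns false if already same component
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[a] = b;
    return true;
  }
};

// symmetric difference of two ascending int vectors
void symdiff(const std::vector<int>& a, const std::vector<int>& b,
             std::vector<int>& out) {
  out.clear();
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) out.push_back(a[i++]);
    else if (b[j] < a[i]) out.push_back(b[j++]);
    else { ++i; ++j; }
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
}

}  // namespace

// [[Rcpp::export]]
List cpp_rips(NumericMatrix pts, double max_radius, int max_dim) {
  const int n = pts.nrow();
  const int d = pts.ncol();
  if (n < 2) stop("need at least 2 points");

  // pairwise Euclidean distances, edge list truncated at max_radius
  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(n) * 8);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = pts(i, c) - pts(j, c);
        s += diff * diff;
      }
      double w = std::sqrt(s);
      if (w <= max_radius) edges.push_back({w, i, j});
    }
  }
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.u != b.u) return a.u < b.u;
    return a.v < b.v;
  });
  const int m = static_cast<int>(edges.size());

  UnionFind uf(n);
  std::vector<double> h0_deaths;
  h0_deaths.reserve(n - 1);

  // dim-1 bookkeeping
  std::vector<char> is_cycle_edge(m, 0);
  std::vector<int> claim(m, -1);          // pivot edge -> reduced column id
  std::vector<std::vector<int>> cols;     // claimed reduced columns
  std::vector<double> h1_birth, h1_death;

  // incremental adjacency: adj[v] holds (neighbour, edge index) for all
  // edges with index < current, so common neighbours give exactly the
  // triangles whose maximal edge is the current one
  std::vector<std::vector<std::pair<int, int>>> adj;
  std::vector<int> mark, mark_edge;
  if (max_dim >= 1) {
    adj.assign(n, {});
    mark.assign(n, -1);
    mark_edge.assign(n, -1);
  }

  std::vector<int> colbuf, tmp;
  for (int e = 0; e < m; ++e) {
    const int u = edges[e].u, v = edges[e].v;
    const double w = edges[e].w;
    if (uf.unite(u, v)) {
      h0_deaths.push_back(w);
    } else if (max_dim >= 1) {
      is_cycle_edge[e] = 1;
    }

    if (max_dim >= 1) {
      for (const auto& p : adj[u]) { mark[p.first] = e; mark_edge[p.first] = p.second; }
      for (const auto& p : adj[v]) {
        if (mark[p.first] != e) continue;
        // triangle (u, v, p.first) with maximal edge e
        int a = mark_edge[p.first], b = p.second;
        colbuf.clear();
        if (a > b) std::swap(a, b);
        colbuf.push_back(a); colbuf.push_back(b); colbuf.push_back(e);
        // reduce
        while (!colbuf.empty()) {
          int piv = colbuf.back();
          int owner = claim[piv];
          if (owner < 0) {
            claim[piv] = static_cast<int>(cols.size());
            cols.push_back(colbuf);
            if (edges[piv].w < w) {  // zero-persistence pairs are dropped
              h1_birth.push_back(edges[piv].w);
              h1_death.push_back(w);
            }
            break;
          }
          symdiff(colbuf, cols[owner], tmp);
          colbuf.swap(tmp);
        }
      }
      adj[u].push_back({v, e});
      adj[v].push_back({u, e});
    }
    if ((e & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // essential dim-1 classes: cycle edges never claimed by a triangle
  if (max_dim >= 1) {
    for (int e = 0; e < m; ++e) {
      if (is_cycle_edge[e] && claim[e] < 0) {
        h1_birth.push_back(edges[e].w);
        h1_death.push_back(R_PosInf);
      }
    }
  }

  int n_components = n - static_cast<int>(h0_deaths.size());
  NumericMatrix h1(static_cast<int>(h1_birth.size()), 2);
  for (size_t i = 0; i < h1_birth.size(); ++i) {
    h1(static_cast<int>(i), 0) = h1_birth[i];
    h1(static_cast<int>(i), 1) = h1_death[i];
  }
  return List::create(_["h0_deaths"] = wrap(h0_deaths),
                      _["n_components"] = n_components,
                      _["h1"] = h1);
}
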