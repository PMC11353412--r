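#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Matching distances between finite persistence diagrams.
//
// Ground metric on the persistence plane is L-infinity; a point may be
// matched to its orthogonal projection on the diagonal at cost
// (death - birth) / 2. Wasserstein-q solves a square assignment problem
// (points of each diagram plus one diagonal slot per opposite point) by
// the Jonker-Volgenant shortest-augmenting-path algorithm; bottleneck
// binary-searches the candidate costs, testing feasibility with Kuhn's
// bipartite matching.

namespace {

const double INF = std::numeric_limits<double>::infinity();

inline double linf(double b1, double d1, double b2, double d2) {
  return std::max(std::fabs(b1 - b2), std::fabs(d1 - d2));
}

inline double diag_cost(double b, double d) { return (d - b) / 2.0; }

// minimal-cost perfect matching on a square cost matrix (rows assigned to
// columns); O(n^3) shortest augmenting paths with dual potentials
double hungarian(const std::vector<std::vector<double>>& cost) {
  const int n = static_cast<int>(cost.size());
  if (n == 0) return 0.0;
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost[i0 - 1][j - 1] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  double total = 0.0;
  for (int j = 1; j <= n; ++j) total += cost[p[j] - 1][j - 1];
  return total;
}

// Kuhn's augmenting-path matching on adjacency lists
bool try_kuhn(int left, const std::vector<std::vector<int>>& g,
              std::vector<int>& match_l, std::vector<int>& match_r,
              std::vector<int>& visited, int stamp) {
  for (int r : g[left]) {
    if (visited[r] == stamp) continue;
    visited[r] = stamp;
    if (match_r[r] < 0 ||
        try_kuhn(match_r[r], g, match_l, match_r, visited, stamp)) {
      match_l[left] = r;
      match_r[r] = left;
      return true;
    }
  }
  return false;
}

// feasibility of a bottleneck value t: perfect matching where every point
// is matched to an opposite point at L-inf cost <= t or to the diagonal at
// cost <= t (diagonal slots for the opposite diagram absorb the rest)
bool feasible(const NumericMatrix& A, const NumericMatrix& B, double t) {
  const int na = A.nrow(), nb = B.nrow();
  const int nl = na + nb;  // left: A points then nb diagonal slots
  std::vector<std::vector<int>> g(nl);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j)
      if (linf(A(i, 0), A(i, 1), B(j, 0), B(j, 1)) <= t) g[i].push_back(j);
    if (diag_cost(A(i, 0), A(i, 1)) <= t)
      for (int j = nb; j < na + nb; ++j) g[i].push_back(j);
  }
  for (int j = 0; j < nb; ++j) {
    if (diag_cost(B(j, 0), B(j, 1)) <= t) g[na + j].push_back(j);
    for (int r = nb; r < na + nb; ++r) g[na + j].push_back(r);
  }
  std::vector<int> match_l(nl, -1), match_r(na + nb, -1), visited(na + nb, -1);
  int matched = 0;
  for (int l = 0; l < nl; ++l)
    if (try_kuhn(l, g, match_l, match_r, visited, l)) ++matched;
  return matched == nl;
}

}  // namespace

// [[Rcpp::export]]
double cpp_wasserstein(NumericMatrix A, NumericMatrix B, double q) {
  const int na = A.nrow(), nb = B.nrow();
  const int n = na + nb;
  if (n == 0) return 0.0;
  std::vector<std::vector<double>> cost(n, std::vector<double>(n, 0.0));
  for (int i = 0; i < na; ++i) {
    double dc = std::pow(diag_cost(A(i, 0), A(i, 1)), q);
    for (int j = 0; j < nb; ++j)
      cost[i][j] = std::pow(linf(A(i, 0), A(i, 1), B(j, 0), B(j, 1)), q);
    for (int j = nb; j < n; ++j) cost[i][j] = dc;
  }
  for (int i = na; i < n; ++i) {
    for (int j = 0; j < nb; ++j)
      cost[i][j] = std::pow(diag_cost(B(j, 0), B(j, 1)), q);
  }
  double total = hungarian(cost);
  if (total < 0) total = 0;  // guard tiny negative round-off
  return std::pow(total, 1.0 / q);
}

// [[Rcpp::export]]
double cpp_bottleneck(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  if (na == 0 && nb == 0) return 0.0;
  std::vector<double> cand;
  cand.push_back(0.0);
  for (int i = 0; i < na; ++i) {
    cand.push_back(diag_cost(A(i, 0), A(i, 1)));
    for (int j = 0; j < nb; ++j)
      cand.push_back(linf(A(i, 0), A(i, 1), B(j, 0), B(j, 1)));
  }
  for (int j = 0; j < nb; ++j) cand.push_back(diag_cost(B(j, 0), B(j, 1)));
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  int lo = 0, hi = static_cast<int>(cand.size()) - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (feasible(A, B, cand[mid])) hi = mid;
    else lo = mid + 1;
  }
  return cand[lo];
}
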