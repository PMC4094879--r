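#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Single-source Dijkstra over a CSR adjacency (0-based). Weights are
// positive integers, so exact double comparison of path sums is safe
// (all sums are small integers representable in a double).
static void dijkstra_core(const IntegerVector& ptr, const IntegerVector& nbr,
                          const IntegerVector& wt, int n, int source,
                          std::vector<double>& dist) {
  dist.assign(n, R_PosInf);
  typedef std::pair<double, int> P;
  std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
  dist[source] = 0.0;
  pq.push(P(0.0, source));
  while (!pq.empty()) {
    P top = pq.top();
    pq.pop();
    double d = top.first;
    int u = top.second;
    if (d > dist[u]) continue;  // stale heap entry
    for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
      int v = nbr[k];
      double nd = d + wt[k];
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(P(nd, v));
      }
    }
  }
}

// Canonical predecessor of v: the smallest-index neighbour u satisfying
// dist[u] + w(u,v) == dist[v]. Node indices follow the lexicographic
// order of node identifiers, so "smallest index" == "lexicographically
// smallest ID". Defined from final distances only, hence independent of
// relaxation order.
static void canonical_pred(const IntegerVector& ptr, const IntegerVector& nbr,
                           const IntegerVector& wt, int n, int source,
                           const std::vector<double>& dist,
                           std::vector<int>& pred) {
  pred.assign(n, -1);
  for (int v = 0; v < n; ++v) {
    if (v == source || dist[v] == R_PosInf) continue;
    int best = -1;
    for (int k = ptr[v]; k < ptr[v + 1]; ++k) {
      int u = nbr[k];
      if (dist[u] + wt[k] == dist[v] && (best < 0 || u < best)) best = u;
    }
    pred[v] = best;
  }
}

// [[Rcpp::export]]
List cpp_dijkstra(IntegerVector ptr, IntegerVector nbr, IntegerVector wt,
                  int n, int source) {
  std::vector<double> dist;
  std::vector<int> pred;
  dijkstra_core(ptr, nbr, wt, n, source, dist);
  canonical_pred(ptr, nbr, wt, n, source, dist, pred);
  NumericVector d(n);
  IntegerVector p(n);
  for (int i = 0; i < n; ++i) {
    d[i] = dist[i];
    p[i] = (pred[i] < 0) ? NA_INTEGER : pred[i] + 1;  // 1-based for R
  }
  return List::create(_["dist"] = d, _["pred"] = p);
}

// Betweenness of every node with respect to a seed set: the number of
// seed-pair shortest paths on which the node lies as an inner node.
// `seeds` are 0-based node indices sorted increasingly (lexicographic
// order of IDs); each unordered pair {s, t} with s < t contributes via
// the canonical path rooted at s (canonical mode), or via membership in
// any shortest s-t path (all-paths mode, where a pair counts at most
// once per node).
// [[Rcpp::export]]
List cpp_seed_betweenness(IntegerVector ptr, IntegerVector nbr,
                          IntegerVector wt, int n, IntegerVector seeds,
                          bool all_paths) {
  int k = seeds.size();
  IntegerVector counts(n);
  int pairs_connected = 0;
  int pairs_total = k * (k - 1) / 2;
  double inner_total = 0.0;

  if (!all_paths) {
    std::vector<double> dist;
    std::vector<int> pred;
    for (int i = 0; i < k - 1; ++i) {
      int s = seeds[i];
      dijkstra_core(ptr, nbr, wt, n, s, dist);
      canonical_pred(ptr, nbr, wt, n, s, dist, pred);
      for (int j = i + 1; j < k; ++j) {
        int t = seeds[j];
        if (dist[t] == R_PosInf) continue;
        ++pairs_connected;
        for (int v = pred[t]; v >= 0 && v != s; v = pred[v]) {
          ++counts[v];
          inner_total += 1.0;
        }
      }
    }
  } else {
    std::vector<std::vector<double> > D(k);
    for (int i = 0; i < k; ++i)
      dijkstra_core(ptr, nbr, wt, n, seeds[i], D[i]);
    for (int i = 0; i < k - 1; ++i) {
      for (int j = i + 1; j < k; ++j) {
        double dst = D[i][seeds[j]];
        if (dst == R_PosInf) continue;
        ++pairs_connected;
        for (int v = 0; v < n; ++v) {
          if (v == seeds[i] || v == seeds[j]) continue;
          if (D[i][v] + D[j][v] == dst) {
            ++counts[v];
            inner_total += 1.0;
          }
        }
      }
    }
  }
  return List::create(_["counts"] = counts,
                      _["pairs_connected"] = pairs_connected,
                      _["pairs_total"] = pairs_total,
                      _["inner_total"] = inner_total);
}
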