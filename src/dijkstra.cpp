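#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
using namespace Rcpp;

// Multi-source Dijkstra over an undirected graph with Euclidean edge
// lengths, restricted to an admissible node set.  Each source carries a
// cell id; ties in geodesic distance are broken toward the smaller cell
// id.  Distances above `cutoff` are not expanded.

// [[Rcpp::export]]
List dijkstra_multisource_cpp(int n, IntegerVector eu, IntegerVector ev,
                              NumericVector elen, IntegerVector sources,
                              IntegerVector source_ids, LogicalVector allowed,
                              double cutoff) {
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int e = 0; e < eu.size(); ++e) {
    adj[eu[e]].push_back(std::make_pair(ev[e], elen[e]));
    adj[ev[e]].push_back(std::make_pair(eu[e], elen[e]));
  }
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> best(n, NA_INTEGER);
  typedef std::tuple<double, int, int> Item; // dist, cell id, node
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  for (int s = 0; s < sources.size(); ++s) {
    int u = sources[s];
    if (!allowed[u]) continue;
    int id = source_ids[s];
    if (0.0 < dist[u] || (dist[u] == 0.0 && id < best[u])) {
      dist[u] = 0.0;
      best[u] = id;
      pq.push(Item(0.0, id, u));
    }
  }
  while (!pq.empty()) {
    Item it = pq.top();
    pq.pop();
    double d = std::get<0>(it);
    int id = std::get<1>(it), u = std::get<2>(it);
    if (d > dist[u] || (d == dist[u] && id > best[u])) continue;
    for (size_t t = 0; t < adj[u].size(); ++t) {
      int v = adj[u][t].first;
      if (!allowed[v]) continue;
      double nd = d + adj[u][t].second;
      if (nd > cutoff) continue;
      if (nd < dist[v] || (nd == dist[v] && id < best[v])) {
        dist[v] = nd;
        best[v] = id;
        pq.push(Item(nd, id, v));
      }
    }
  }
  return List::create(Named("dist") = NumericVector(dist.begin(), dist.end()),
                      Named("cell") = IntegerVector(best.begin(), best.end()));
}
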