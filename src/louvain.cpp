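#include <Rcpp.h>
#include <random>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

// Louvain community detection with landmark ("cell node") constraints:
// communities may never contain more than one cell node, at any stage of
// any pass.  Only positively weighted edges are supplied by the caller.
//
// Conventions: distinct undirected edges carry weight w; self-loops (which
// appear after aggregation) carry weight counted once in m; the degree of a
// node counts its loop twice.  Modularity is
//   Q = sum_c [ in_c / m - (tot_c / 2m)^2 ]
// with in_c the internal distinct-pair weight plus loops, tot_c the summed
// degree.  This equals the edge-sum form of the modularity over ordered
// node pairs.

struct LvGraph {
  int n;
  std::vector<std::vector<std::pair<int, double> > > adj; // no loops
  std::vector<double> loop;
  std::vector<bool> cell;
};

static double graph_m(const LvGraph& g) {
  double m = 0.0;
  for (int u = 0; u < g.n; ++u) {
    m += g.loop[u];
    for (size_t t = 0; t < g.adj[u].size(); ++t)
      if (g.adj[u][t].first > u) m += g.adj[u][t].second;
  }
  return m;
}

static double partition_q(const LvGraph& g, const std::vector<int>& comm,
                          double m) {
  int nc = 0;
  for (int u = 0; u < g.n; ++u) nc = std::max(nc, comm[u] + 1);
  std::vector<double> in(nc, 0.0), tot(nc, 0.0);
  for (int u = 0; u < g.n; ++u) {
    double k = 2.0 * g.loop[u];
    in[comm[u]] += g.loop[u];
    for (size_t t = 0; t < g.adj[u].size(); ++t) {
      k += g.adj[u][t].second;
      int v = g.adj[u][t].first;
      if (v > u && comm[v] == comm[u]) in[comm[u]] += g.adj[u][t].second;
    }
    tot[comm[u]] += k;
  }
  double q = 0.0;
  for (int c = 0; c < nc; ++c)
    q += in[c] / m - (tot[c] / (2.0 * m)) * (tot[c] / (2.0 * m));
  return q;
}

// One local-moving phase; returns true if any strictly improving move was
// made.  Sweep order is reshuffled from rng before every sweep; ties in
// modularity gain are broken toward the smallest community id.
static bool local_phase(const LvGraph& g, std::vector<int>& comm,
                        std::mt19937& rng, double m) {
  std::vector<double> k(g.n, 0.0), tot(g.n, 0.0);
  std::vector<int> ncell(g.n, 0);
  for (int u = 0; u < g.n; ++u) {
    k[u] = 2.0 * g.loop[u];
    for (size_t t = 0; t < g.adj[u].size(); ++t) k[u] += g.adj[u][t].second;
    tot[comm[u]] += k[u];
    if (g.cell[u]) ncell[comm[u]] += 1;
  }
  std::vector<int> order(g.n);
  for (int u = 0; u < g.n; ++u) order[u] = u;
  std::map<int, double> kuc;
  bool any_improved = false;
  bool sweep_improved = true;
  const double eps = 1e-12;
  while (sweep_improved) {
    sweep_improved = false;
    // Fisher-Yates with explicit draws: deterministic across platforms
    for (int t = g.n - 1; t > 0; --t) {
      std::uniform_int_distribution<int> d(0, t);
      std::swap(order[t], order[d(rng)]);
    }
    for (int s = 0; s < g.n; ++s) {
      int u = order[s];
      int c0 = comm[u];
      // remove u from its community
      tot[c0] -= k[u];
      if (g.cell[u]) ncell[c0] -= 1;
      kuc.clear();
      kuc[c0] = 0.0; // staying (or returning) is always a candidate
      for (size_t t = 0; t < g.adj[u].size(); ++t)
        kuc[comm[g.adj[u][t].first]] += g.adj[u][t].second;
      int best = c0;
      double best_gain = -1e300, gain0 = 0.0;
      for (std::map<int, double>::const_iterator it = kuc.begin();
           it != kuc.end(); ++it) {
        int c = it->first;
        if (g.cell[u] && c != c0 && ncell[c] > 0) continue;
        double gain = it->second / m - tot[c] * k[u] / (2.0 * m * m);
        if (c == c0) gain0 = gain;
        if (gain > best_gain + eps ||
            (gain > best_gain - eps && c < best)) {
          best_gain = gain;
          best = c;
        }
      }
      comm[u] = best;
      tot[best] += k[u];
      if (g.cell[u]) ncell[best] += 1;
      if (best != c0 && best_gain > gain0 + eps) {
        sweep_improved = true;
        any_improved = true;
      }
    }
  }
  return any_improved;
}

// Relabel communities to 0..nc-1 preserving numeric order of old ids.
static int compress(std::vector<int>& comm) {
  std::vector<int> ids(comm);
  std::sort(ids.begin(), ids.end());
  ids.erase(std::unique(ids.begin(), ids.end()), ids.end());
  for (size_t u = 0; u < comm.size(); ++u)
    comm[u] = (int)(std::lower_bound(ids.begin(), ids.end(), comm[u]) -
                    ids.begin());
  return (int)ids.size();
}

static LvGraph aggregate(const LvGraph& g, const std::vector<int>& comm,
                         int nc) {
  LvGraph h;
  h.n = nc;
  h.adj.assign(nc, std::vector<std::pair<int, double> >());
  h.loop.assign(nc, 0.0);
  h.cell.assign(nc, false);
  std::map<std::pair<int, int>, double> ew;
  for (int u = 0; u < g.n; ++u) {
    int cu = comm[u];
    h.loop[cu] += g.loop[u];
    if (g.cell[u]) h.cell[cu] = true;
    for (size_t t = 0; t < g.adj[u].size(); ++t) {
      int v = g.adj[u][t].first;
      if (v < u) continue;
      int cv = comm[v];
      double w = g.adj[u][t].second;
      if (cu == cv) h.loop[cu] += w;
      else ew[std::make_pair(std::min(cu, cv), std::max(cu, cv))] += w;
    }
  }
  for (std::map<std::pair<int, int>, double>::const_iterator it = ew.begin();
       it != ew.end(); ++it) {
    h.adj[it->first.first].push_back(
      std::make_pair(it->first.second, it->second));
    h.adj[it->first.second].push_back(
      std::make_pair(it->first.first, it->second));
  }
  return h;
}

// [[Rcpp::export]]
List louvain_constrained_cpp(int n, IntegerVector eu, IntegerVector ev,
                             NumericVector ew, LogicalVector is_cell,
                             int seed) {
  LvGraph g;
  g.n = n;
  g.adj.assign(n, std::vector<std::pair<int, double> >());
  g.loop.assign(n, 0.0);
  g.cell.assign(n, false);
  for (int i = 0; i < n; ++i) g.cell[i] = is_cell[i];
  for (int e = 0; e < eu.size(); ++e) {
    int u = eu[e], v = ev[e];
    double w = ew[e];
    if (u == v) { g.loop[u] += w; continue; }
    g.adj[u].push_back(std::make_pair(v, w));
    g.adj[v].push_back(std::make_pair(u, w));
  }
  std::vector<int> membership(n);
  for (int u = 0; u < n; ++u) membership[u] = u;
  double m = graph_m(g);
  std::vector<double> trace;
  if (m <= 0.0) {
    return List::create(Named("membership") = IntegerVector(membership.begin(),
                                                            membership.end()),
                        Named("Q") = 0.0,
                        Named("q_trace") = NumericVector(0));
  }
  std::mt19937 rng((unsigned)seed);
  double q = 0.0;
  // Outer cycle: restart node-level sweeps on the original graph from the
  // current membership, then aggregate; stop only when a full cycle makes
  // no strictly improving move, so the result is a local optimum with
  // respect to single-node moves on the original graph.
  while (true) {
    LvGraph cur = g;
    std::vector<int> o2c(n);              // original node -> current node
    std::vector<int> comm(membership);
    compress(comm);
    for (int u = 0; u < n; ++u) o2c[u] = u;
    bool any = false;
    while (true) {
      bool improved = local_phase(cur, comm, rng, m);
      int nc = compress(comm);
      for (int u = 0; u < n; ++u) membership[u] = comm[o2c[u]];
      q = partition_q(cur, comm, m);
      trace.push_back(q);
      if (!improved || nc == cur.n) break;
      any = true;
      cur = aggregate(cur, comm, nc);
      for (int u = 0; u < n; ++u) o2c[u] = membership[u];
      comm.resize(cur.n);
      for (int u = 0; u < cur.n; ++u) comm[u] = u;
    }
    if (!any) break;
  }
  return List::create(Named("membership") = IntegerVector(membership.begin(),
                                                          membership.end()),
                      Named("Q") = q,
                      Named("q_trace") = NumericVector(trace.begin(),
                                                       trace.end()));
}
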