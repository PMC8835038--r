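#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact uncapacitated min-cost flow by successive shortest paths with
// Dijkstra on reduced costs (Johnson potentials). Supplies are real-valued;
// every augmentation zeroes at least one surplus or deficit node, so the
// number of phases is bounded by the number of nodes with nonzero supply.

namespace {

struct Arc {
  int to;
  double cap;   // residual capacity
  double cost;  // arc cost (negative on residual arcs)
};

class MinCostFlow {
public:
  explicit MinCostFlow(int n) : n_(n), head_(n) {}

  void add_arc(int u, int v, double cost) {
    head_[u].push_back((int)arcs_.size());
    arcs_.push_back({v, std::numeric_limits<double>::infinity(), cost});
    head_[v].push_back((int)arcs_.size());
    arcs_.push_back({u, 0.0, -cost});
  }

  // b: supplies (positive) and demands (negative), must balance.
  double solve(std::vector<double> b, double tol) {
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<double> pot(n_, 0.0), dist(n_);
    std::vector<int> par_arc(n_);
    std::vector<char> done(n_);
    double total_cost = 0.0;
    int max_phase = 4 * n_ + 64;

    for (int phase = 0; ; ++phase) {
      double surplus = 0.0;
      for (int i = 0; i < n_; ++i)
        if (b[i] > 0) surplus += b[i];
      if (surplus <= tol) break;
      if (phase >= max_phase)
        stop("min-cost flow failed to terminate (numerically degenerate input)");

      std::fill(dist.begin(), dist.end(), INF);
      std::fill(done.begin(), done.end(), 0);
      std::fill(par_arc.begin(), par_arc.end(), -1);
      typedef std::pair<double, int> QE;
      std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
      for (int i = 0; i < n_; ++i)
        if (b[i] > tol) { dist[i] = 0.0; pq.push(QE(0.0, i)); }

      int sink = -1;
      while (!pq.empty()) {
        QE top = pq.top(); pq.pop();
        int u = top.second;
        if (done[u]) continue;
        done[u] = 1;
        if (sink < 0 && b[u] < -tol) sink = u;  // nearest deficit node
        for (size_t idx = 0; idx < head_[u].size(); ++idx) {
          int a = head_[u][idx];
          const Arc& arc = arcs_[a];
          if (arc.cap <= tol) continue;
          double rc = arc.cost + pot[u] - pot[arc.to];
          if (rc < 0) rc = 0;  // guard tiny negative round-off
          double nd = dist[u] + rc;
          if (nd < dist[arc.to] - 1e-15) {
            dist[arc.to] = nd;
            par_arc[arc.to] = a;
            pq.push(QE(nd, arc.to));
          }
        }
      }
      if (sink < 0)
        stop("transport problem infeasible: some mass cannot reach a deficit node");

      for (int i = 0; i < n_; ++i)
        if (dist[i] < INF) pot[i] += dist[i];

      // trace path back to the originating surplus node
      double push = -b[sink];
      int v = sink;
      while (par_arc[v] >= 0) {
        const Arc& arc = arcs_[par_arc[v]];
        if (arc.cap < push) push = arc.cap;
        v = arcs_[par_arc[v] ^ 1].to;
      }
      if (b[v] < push) push = b[v];

      v = sink;
      while (par_arc[v] >= 0) {
        int a = par_arc[v];
        arcs_[a].cap -= push;
        arcs_[a ^ 1].cap += push;
        total_cost += push * arcs_[a].cost;
        v = arcs_[a ^ 1].to;
      }
      b[v] -= push;
      b[sink] += push;
    }
    return total_cost;
  }

private:
  int n_;
  std::vector<Arc> arcs_;
  std::vector<std::vector<int> > head_;
};

}  // namespace

// W1 between two distributions on an undirected weighted graph; the ground
// metric is implicitly the shortest-path metric of the graph.
// edges: m x 2 matrix of 0-based node indices; w: edge weights (>0).
// [[Rcpp::export(name = ".emd_graph_cpp")]]
double emd_graph_cpp(IntegerMatrix edges, NumericVector w,
                     int n_nodes, NumericVector mu, NumericVector nu) {
  MinCostFlow mcf(n_nodes);
  for (int e = 0; e < edges.nrow(); ++e) {
    mcf.add_arc(edges(e, 0), edges(e, 1), w[e]);
    mcf.add_arc(edges(e, 1), edges(e, 0), w[e]);
  }
  std::vector<double> b(n_nodes);
  for (int i = 0; i < n_nodes; ++i) b[i] = mu[i] - nu[i];
  return mcf.solve(b, 1e-12);
}

// W1 for an arbitrary ground metric: bipartite transportation between the
// surplus and deficit parts of mu - nu.
// [[Rcpp::export(name = ".emd_dense_cpp")]]
double emd_dense_cpp(NumericMatrix cost, NumericVector mu, NumericVector nu) {
  int n = mu.size();
  std::vector<int> sup, def;
  for (int i = 0; i < n; ++i) {
    double d = mu[i] - nu[i];
    if (d > 1e-14) sup.push_back(i);
    else if (d < -1e-14) def.push_back(i);
  }
  if (sup.empty()) return 0.0;
  int ns = (int)sup.size(), nd = (int)def.size();
  MinCostFlow mcf(ns + nd);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < nd; ++j)
      mcf.add_arc(i, ns + j, cost(sup[i], def[j]));
  std::vector<double> b(ns + nd);
  for (int i = 0; i < ns; ++i) b[i] = mu[sup[i]] - nu[sup[i]];
  for (int j = 0; j < nd; ++j) b[ns + j] = mu[def[j]] - nu[def[j]];
  return mcf.solve(b, 1e-12);
}
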