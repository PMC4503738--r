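// In-repo Louvain modularity optimisation (greedy local moving + aggregation),
// seeded and restartable so results are reproducible. Self-loops in aggregated
// graphs are stored once with weight 2*internal so that weighted degrees come
// out right.
#include <Rcpp.h>
#include <vector>
#include <random>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

typedef std::mt19937_64 RNG;
typedef std::vector<std::vector<std::pair<int, double> > > AdjList;

static double node_wdeg(const AdjList& g, int i) {
  double s = 0.0;
  for (size_t t = 0; t < g[i].size(); ++t) s += g[i][t].second;
  return s;
}

// one local-moving phase; labels renumbered 0..K-1 on return
static std::vector<int> one_level(const AdjList& g, double m2, RNG& rng,
                                  bool& moved_any) {
  int n = (int)g.size();
  std::vector<int> comm(n);
  std::vector<double> wdeg(n), tot(n);
  for (int i = 0; i < n; ++i) {
    comm[i] = i;
    wdeg[i] = node_wdeg(g, i);
    tot[i] = wdeg[i];
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);

  std::vector<double> nb_w(n, 0.0);
  std::vector<int> nb_comm;
  moved_any = false;
  bool improved = true;
  while (improved) {
    improved = false;
    for (int t = 0; t < n; ++t) {
      int i = order[t];
      int ci = comm[i];
      // weights from i to neighbouring communities (self-loop excluded)
      nb_comm.clear();
      for (size_t u = 0; u < g[i].size(); ++u) {
        int j = g[i][u].first;
        if (j == i) continue;
        int cj = comm[j];
        if (nb_w[cj] == 0.0) nb_comm.push_back(cj);
        nb_w[cj] += g[i][u].second;
      }
      tot[ci] -= wdeg[i];
      double best_gain = 0.0;
      int best_c = ci;
      double base = nb_w[ci] - tot[ci] * wdeg[i] / m2;  // gain of staying
      for (size_t u = 0; u < nb_comm.size(); ++u) {
        int c = nb_comm[u];
        double gain = nb_w[c] - tot[c] * wdeg[i] / m2 - base;
        if (gain > best_gain + 1e-12) { best_gain = gain; best_c = c; }
      }
      tot[best_c] += wdeg[i];
      if (best_c != ci) { comm[i] = best_c; improved = true; moved_any = true; }
      for (size_t u = 0; u < nb_comm.size(); ++u) nb_w[nb_comm[u]] = 0.0;
      nb_w[ci] = 0.0;
    }
  }
  // renumber
  std::vector<int> remap(n, -1);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (remap[comm[i]] < 0) remap[comm[i]] = k++;
    comm[i] = remap[comm[i]];
  }
  return comm;
}

static double modularity_of(const AdjList& g, const std::vector<int>& comm,
                            double m2) {
  int k = 0;
  for (size_t i = 0; i < comm.size(); ++i) k = std::max(k, comm[i] + 1);
  std::vector<double> in(k, 0.0), tot(k, 0.0);
  for (size_t i = 0; i < g.size(); ++i) {
    double wd = node_wdeg(g, (int)i);
    tot[comm[i]] += wd;
    for (size_t t = 0; t < g[i].size(); ++t) {
      int j = g[i][t].first;
      if (j == (int)i) in[comm[i]] += g[i][t].second;       // stored as 2*w
      else if (comm[j] == comm[i]) in[comm[i]] += g[i][t].second;
    }
  }
  double q = 0.0;
  for (int c = 0; c < k; ++c)
    q += in[c] / m2 - (tot[c] / m2) * (tot[c] / m2);
  return q;
}

static AdjList aggregate(const AdjList& g, const std::vector<int>& comm) {
  int k = 0;
  for (size_t i = 0; i < comm.size(); ++i) k = std::max(k, comm[i] + 1);
  std::vector<double> buf(k, 0.0);
  AdjList h(k);
  std::vector<int> touched;
  // group nodes by community
  std::vector<std::vector<int> > members(k);
  for (size_t i = 0; i < g.size(); ++i) members[comm[i]].push_back((int)i);
  for (int c = 0; c < k; ++c) {
    touched.clear();
    for (size_t a = 0; a < members[c].size(); ++a) {
      int i = members[c][a];
      for (size_t t = 0; t < g[i].size(); ++t) {
        int j = g[i][t].first;
        int cj = (j == i) ? c : comm[j];
        if (buf[cj] == 0.0) touched.push_back(cj);
        buf[cj] += g[i][t].second;
      }
    }
    for (size_t u = 0; u < touched.size(); ++u) {
      int cj = touched[u];
      h[c].push_back(std::make_pair(cj, buf[cj]));  // self entry already 2*w
      buf[cj] = 0.0;
    }
  }
  return h;
}

// [[Rcpp::export]]
List cpp_louvain(int n, IntegerVector ei, IntegerVector ej, NumericVector ew,
                 int restarts, double seed) {
  AdjList g0(n);
  double m2 = 0.0;
  for (int t = 0; t < ei.size(); ++t) {
    int a = ei[t] - 1, b = ej[t] - 1;
    g0[a].push_back(std::make_pair(b, ew[t]));
    g0[b].push_back(std::make_pair(a, ew[t]));
    m2 += 2.0 * ew[t];
  }
  std::vector<int> best_final, best_first;
  double best_q = -2.0;
  for (int r = 0; r < restarts; ++r) {
    RNG rng((std::uint64_t)seed + (std::uint64_t)r * 1000003ULL);
    AdjList g = g0;
    std::vector<int> node2comm(n);
    for (int i = 0; i < n; ++i) node2comm[i] = i;
    std::vector<int> first_level;
    int pass = 0;
    while (true) {
      bool moved = false;
      std::vector<int> comm = one_level(g, m2, rng, moved);
      if (pass == 0) {
        first_level.resize(n);
        for (int i = 0; i < n; ++i) first_level[i] = comm[node2comm[i]];
      }
      if (!moved && pass > 0) break;
      for (int i = 0; i < n; ++i) node2comm[i] = comm[node2comm[i]];
      if (!moved) break;
      g = aggregate(g, comm);
      ++pass;
      if ((int)g.size() == 1) break;
    }
    double q = modularity_of(g0, node2comm, m2);
    if (q > best_q) {
      best_q = q;
      best_final = node2comm;
      best_first = first_level;
    }
  }
  return List::create(_["membership"] = wrap(best_final),
                      _["first_level"] = wrap(best_first),
                      _["modularity"] = best_q);
}
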