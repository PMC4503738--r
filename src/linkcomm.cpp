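// Link communities: similarity between edges sharing a node (Jaccard of
// inclusive neighbourhoods, or Tanimoto of inclusive weighted neighbour
// vectors), single-linkage agglomeration via union-find in decreasing
// similarity order, dendrogram cut at maximum partition density.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Pair { int e1, e2; double sim; };

static double comp_D(long m_c, long n_c) {
  if (n_c <= 2) return 0.0;
  return (double)m_c * (double)(m_c - (n_c - 1)) /
         ((double)(n_c - 2) * (double)(n_c - 1));
}

struct Forest {
  std::vector<int> parent;
  std::vector<long> m_c;
  std::vector<std::unordered_set<int> > nodes;
  double dsum;
  Forest(int M, const std::vector<int>& a, const std::vector<int>& b)
      : parent(M), m_c(M, 1), nodes(M), dsum(0.0) {
    for (int e = 0; e < M; ++e) {
      parent[e] = e;
      nodes[e].insert(a[e]);
      nodes[e].insert(b[e]);
    }
  }
  int find(int e) {
    while (parent[e] != e) { parent[e] = parent[parent[e]]; e = parent[e]; }
    return e;
  }
  void unite(int e1, int e2) {
    int r1 = find(e1), r2 = find(e2);
    if (r1 == r2) return;
    if (nodes[r1].size() < nodes[r2].size()) std::swap(r1, r2);
    dsum -= comp_D(m_c[r1], (long)nodes[r1].size());
    dsum -= comp_D(m_c[r2], (long)nodes[r2].size());
    for (std::unordered_set<int>::iterator it = nodes[r2].begin();
         it != nodes[r2].end(); ++it)
      nodes[r1].insert(*it);
    nodes[r2].clear();
    m_c[r1] += m_c[r2];
    parent[r2] = r1;
    dsum += comp_D(m_c[r1], (long)nodes[r1].size());
  }
};

// [[Rcpp::export]]
List cpp_link_communities(int n, IntegerVector ei, IntegerVector ej,
                          NumericVector ew, bool weighted) {
  int M = ei.size();
  std::vector<int> ea(M), eb(M);
  std::vector<std::unordered_map<int, double> > adj(n);
  std::vector<std::vector<std::pair<int, int> > > inc(n);  // (edge, other end)
  for (int e = 0; e < M; ++e) {
    int a = ei[e] - 1, b = ej[e] - 1;
    ea[e] = a; eb[e] = b;
    adj[a][b] = ew[e];
    adj[b][a] = ew[e];
    inc[a].push_back(std::make_pair(e, b));
    inc[b].push_back(std::make_pair(e, a));
  }
  std::vector<double> selfw(n, 0.0), norm2(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (std::unordered_map<int, double>::iterator it = adj[i].begin();
         it != adj[i].end(); ++it) {
      s += it->second;
      norm2[i] += it->second * it->second;
    }
    if (!adj[i].empty()) selfw[i] = s / adj[i].size();
    norm2[i] += selfw[i] * selfw[i];
  }

  std::vector<Pair> pairs;
  for (int k = 0; k < n; ++k) {
    int d = (int)inc[k].size();
    for (int u = 0; u < d; ++u)
      for (int v = u + 1; v < d; ++v) {
        int i = inc[k][u].second, j = inc[k][v].second;
        double sim;
        if (weighted) {
          double dot = 0.0;
          // support of a_i is N(i) U {i}
          for (std::unordered_map<int, double>::iterator it = adj[i].begin();
               it != adj[i].end(); ++it) {
            int t = it->first;
            double aj;
            if (t == j) aj = selfw[j];
            else {
              std::unordered_map<int, double>::iterator f = adj[j].find(t);
              aj = (f == adj[j].end()) ? 0.0 : f->second;
            }
            dot += it->second * aj;
          }
          std::unordered_map<int, double>::iterator f = adj[j].find(i);
          dot += selfw[i] * ((f == adj[j].end()) ? 0.0 : f->second);
          sim = dot / (norm2[i] + norm2[j] - dot);
        } else {
          int inter = 0;
          for (std::unordered_map<int, double>::iterator it = adj[i].begin();
               it != adj[i].end(); ++it) {
            int t = it->first;
            if (t == j || adj[j].count(t)) ++inter;
          }
          if (adj[j].count(i)) ++inter;  // i itself in N+(j)
          int uni = (int)adj[i].size() + 1 + (int)adj[j].size() + 1 - inter;
          sim = (double)inter / (double)uni;
        }
        Pair p; p.e1 = inc[k][u].first; p.e2 = inc[k][v].first; p.sim = sim;
        pairs.push_back(p);
      }
  }

  std::sort(pairs.begin(), pairs.end(),
            [](const Pair& x, const Pair& y) {
              if (x.sim != y.sim) return x.sim > y.sim;
              if (x.e1 != y.e1) return x.e1 < y.e1;
              return x.e2 < y.e2;
            });

  // scan merge levels (groups of equal similarity), tracking D
  Forest forest(M, ea, eb);
  std::vector<double> level_h, level_D;
  double best_D = 0.0, best_h = R_PosInf;
  int best_level = -1;
  size_t p = 0;
  int level = 0;
  while (p < pairs.size()) {
    double h = pairs[p].sim;
    while (p < pairs.size() && pairs[p].sim == h) {
      forest.unite(pairs[p].e1, pairs[p].e2);
      ++p;
    }
    double D = (M > 0) ? 2.0 * forest.dsum / M : 0.0;
    level_h.push_back(h);
    level_D.push_back(D);
    if (D >= best_D) { best_D = D; best_level = level; best_h = h; }
    ++level;
  }

  // rebuild partition at the best cut
  Forest cut(M, ea, eb);
  p = 0;
  for (int l = 0; l <= best_level && p < pairs.size(); ++l) {
    double h = pairs[p].sim;
    while (p < pairs.size() && pairs[p].sim == h) {
      cut.unite(pairs[p].e1, pairs[p].e2);
      ++p;
    }
  }
  std::vector<int> labels(M);
  std::unordered_map<int, int> remap;
  for (int e = 0; e < M; ++e) {
    int r = cut.find(e);
    std::unordered_map<int, int>::iterator f = remap.find(r);
    if (f == remap.end()) {
      int k = (int)remap.size() + 1;
      remap[r] = k;
      labels[e] = k;
    } else labels[e] = f->second;
  }
  int K = (int)remap.size();
  IntegerVector node_counts(K), edge_counts(K);
  for (std::unordered_map<int, int>::iterator it = remap.begin();
       it != remap.end(); ++it) {
    node_counts[it->second - 1] = (int)cut.nodes[it->first].size();
    edge_counts[it->second - 1] = (int)cut.m_c[it->first];
  }
  return List::create(
      _["labels"] = wrap(labels), _["node_counts"] = node_counts,
      _["edge_counts"] = edge_counts, _["D"] = best_D,
      _["height"] = (best_level < 0) ? NA_REAL : best_h,
      _["scan_height"] = wrap(level_h), _["scan_D"] = wrap(level_D));
}
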