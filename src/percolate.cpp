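// Link percolation by weight order: edges removed one by one (ties randomly
// permuted per shuffle); largest and second-largest component sizes tracked
// by union-find on the reversed insertion sequence.
#include <Rcpp.h>
#include <vector>
#include <set>
#include <random>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

typedef std::mt19937_64 RNG;

struct UF {
  std::vector<int> parent, size;
  UF(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
};

// [[Rcpp::export]]
List cpp_percolation_curve(int n, IntegerVector ei, IntegerVector ej,
                           NumericVector ew, bool descending, int n_shuffles,
                           double seed) {
  int m = ei.size();
  // index r = state after r removals (r = 0..m)
  NumericVector rlcc(m + 1, 0.0), s2(m + 1, 0.0);
  for (int sh = 0; sh < n_shuffles; ++sh) {
    RNG rng((std::uint64_t)seed + (std::uint64_t)sh * 7919ULL);
    std::vector<int> ord(m);
    for (int e = 0; e < m; ++e) ord[e] = e;
    std::shuffle(ord.begin(), ord.end(), rng);      // random tie-break
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return descending ? (ew[a] > ew[b]) : (ew[a] < ew[b]);
    });
    UF uf(n);
    std::multiset<int> sizes;
    for (int i = 0; i < n; ++i) sizes.insert(1);
    // insert edges in reverse removal order; after inserting edges
    // ord[t..m-1] the network state corresponds to r = t removals
    for (int r = m; r >= 0; --r) {
      if (r < m) {
        int e = ord[r];
        int ra = uf.find(ei[e] - 1), rb = uf.find(ej[e] - 1);
        if (ra != rb) {
          int sa = uf.size[ra], sb = uf.size[rb];
          if (sa < sb) std::swap(ra, rb);
          uf.size[ra] = sa + sb;
          uf.parent[rb] = ra;
          sizes.erase(sizes.find(sa));
          sizes.erase(sizes.find(sb));
          sizes.insert(sa + sb);
        }
      }
      std::multiset<int>::reverse_iterator it = sizes.rbegin();
      int l1 = *it;
      ++it;
      int l2 = (it == sizes.rend()) ? 0 : *it;
      rlcc[r] += (double)l1 / n;
      s2[r] += (double)l2 / n;
    }
  }
  for (int r = 0; r <= m; ++r) {
    rlcc[r] /= n_shuffles;
    s2[r] /= n_shuffles;
  }
  return List::create(_["rlcc"] = rlcc, _["s2"] = s2);
}
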