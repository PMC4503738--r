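// Simulation engine: weighted tie formation by local (cyclic-closure) and
// global (focal-closure) attachment with three termination mechanisms.
// Adjacency is stored as flat per-node vectors of (neighbour, weight) pairs;
// degrees stay small (~10) so linear scans beat hashing.
#include <Rcpp.h>
#include <vector>
#include <random>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

typedef std::mt19937_64 RNG;

// Adjacency lives in one contiguous slab with per-node (offset, length,
// capacity) and capacity doubling; degrees stay ~10 so linear scans over a
// node's contiguous block are cache-friendly. Freed blocks are not reused —
// total slack is bounded by the doubling series.
struct Net {
  int n;
  long m;
  std::vector<std::pair<int, double> > slab;
  std::vector<long> off;
  std::vector<int> len, cap;

  explicit Net(int n_) : n(n_), m(0) {
    const int cap0 = 16;
    slab.resize((size_t)n_ * cap0);
    off.resize(n_); len.assign(n_, 0); cap.assign(n_, cap0);
    for (int i = 0; i < n_; ++i) off[i] = (long)i * cap0;
  }
  int deg(int a) const { return len[a]; }
  std::pair<int, double>* nb(int a) { return &slab[off[a]]; }
  const std::pair<int, double>* nb(int a) const { return &slab[off[a]]; }

  int find(int a, int b) const {
    const std::pair<int, double>* v = nb(a);
    for (int t = 0; t < len[a]; ++t) if (v[t].first == b) return t;
    return -1;
  }
  bool has(int a, int b) const { return find(a, b) >= 0; }
  void push_nb(int a, int b, double w) {
    if (len[a] == cap[a]) {                   // relocate a's block, doubled
      int nc = cap[a] * 2;
      long no = (long)slab.size();
      slab.resize(slab.size() + nc);
      std::copy(slab.begin() + off[a], slab.begin() + off[a] + len[a],
                slab.begin() + no);
      off[a] = no;
      cap[a] = nc;
    }
    slab[off[a] + len[a]++] = std::make_pair(b, w);
  }
  void add_edge(int a, int b, double w) {
    push_nb(a, b, w);
    push_nb(b, a, w);
    ++m;
  }
  void drop_dir(int a, int b) {       // remove b from a's list (swap-pop)
    int t = find(a, b);
    slab[off[a] + t] = slab[off[a] + len[a] - 1];
    --len[a];
  }
  void remove_edge(int a, int b) { drop_dir(a, b); drop_dir(b, a); --m; }
  void bump(int a, int b, double d) {
    slab[off[a] + find(a, b)].second += d;
    slab[off[b] + find(b, a)].second += d;
  }
};

static Net net_from_r(int n, const IntegerVector& ei, const IntegerVector& ej,
                      const NumericVector& w) {
  Net net(n);
  for (int t = 0; t < ei.size(); ++t)
    net.add_edge(ei[t] - 1, ej[t] - 1, w[t]);
  return net;
}

static List net_to_r(const Net& net) {
  std::vector<int> ri, rj;
  std::vector<double> rw;
  ri.reserve(net.m); rj.reserve(net.m); rw.reserve(net.m);
  for (int a = 0; a < net.n; ++a) {
    const std::pair<int, double>* v = net.nb(a);
    for (int t = 0; t < net.deg(a); ++t)
      if (a < v[t].first) {
        ri.push_back(a + 1);
        rj.push_back(v[t].first + 1);
        rw.push_back(v[t].second);
      }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(rj), _["w"] = wrap(rw));
}

static double runif01(RNG& rng) {
  return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
}

// weighted pick among a's neighbours, optionally excluding `excl`;
// returns -1 when no admissible neighbour exists
static int weighted_pick(const Net& net, int a, int excl, RNG& rng) {
  const std::pair<int, double>* v = net.nb(a);
  const int d = net.deg(a);
  double tot = 0.0;
  for (int t = 0; t < d; ++t)
    if (v[t].first != excl) tot += v[t].second;
  if (tot <= 0.0) return -1;
  double u = runif01(rng) * tot, acc = 0.0;
  int last = -1;
  for (int t = 0; t < d; ++t) {
    if (v[t].first == excl) continue;
    acc += v[t].second;
    last = v[t].first;
    if (u <= acc) return last;
  }
  return last;  // guard against rounding at the top edge
}

// one local-attachment event initiated at node i
static void la_event(Net& net, int i, double p_delta, double w0, double delta,
                     RNG& rng) {
  if (net.deg(i) == 0) return;
  int j = weighted_pick(net, i, -1, rng);
  int k = weighted_pick(net, j, i, rng);
  if (k < 0) return;                       // truncated walk: no reinforcement
  bool existed = net.has(i, k);
  if (!existed && runif01(rng) < p_delta) net.add_edge(i, k, w0);
  net.bump(i, j, delta);
  net.bump(j, k, delta);
  if (existed) net.bump(i, k, delta);
}

static void la_sweep(Net& net, double p_delta, double w0, double delta,
                     RNG& rng) {
  std::vector<int> order(net.n);
  for (int a = 0; a < net.n; ++a) order[a] = a;
  std::shuffle(order.begin(), order.end(), rng);
  for (int t = 0; t < net.n; ++t)
    la_event(net, order[t], p_delta, w0, delta, rng);
}

static void ga_sweep(Net& net, double p_r, double w0, RNG& rng) {
  std::vector<int> order(net.n);
  for (int a = 0; a < net.n; ++a) order[a] = a;
  std::shuffle(order.begin(), order.end(), rng);
  std::uniform_int_distribution<int> pick(0, net.n - 1);
  for (int t = 0; t < net.n; ++t) {
    int i = order[t];
    int k = net.deg(i);
    if (k >= net.n - 1) continue;          // no non-neighbour available
    if (k > 0 && runif01(rng) >= p_r) continue;
    // uniform over non-neighbours via rejection; a non-neighbour exists
    int tgt;
    do { tgt = pick(rng); } while (tgt == i || net.has(i, tgt));
    net.add_edge(i, tgt, w0);
  }
}

static void nd_sweep(Net& net, double p_nd, RNG& rng) {
  for (int i = 0; i < net.n; ++i) {
    if (runif01(rng) >= p_nd) continue;
    while (net.deg(i) > 0)
      net.remove_edge(i, net.nb(i)[net.deg(i) - 1].first);
  }
}

static void ld_sweep(Net& net, double p_ld, RNG& rng) {
  std::vector<std::pair<int, int> > doomed;
  for (int a = 0; a < net.n; ++a) {
    const std::pair<int, double>* v = net.nb(a);
    for (int t = 0; t < net.deg(a); ++t)
      if (a < v[t].first && runif01(rng) < p_ld)
        doomed.push_back(std::make_pair(a, v[t].first));
  }
  for (size_t t = 0; t < doomed.size(); ++t)
    net.remove_edge(doomed[t].first, doomed[t].second);
}

static void aging_sweep(Net& net, double f, double w_th) {
  std::vector<std::pair<int, int> > doomed;
  for (int a = 0; a < net.n; ++a) {
    std::pair<int, double>* v = net.nb(a);
    for (int t = 0; t < net.deg(a); ++t) {
      v[t].second *= f;
      int b = v[t].first;
      if (a < b && v[t].second < w_th)
        doomed.push_back(std::make_pair(a, b));
    }
  }
  for (size_t t = 0; t < doomed.size(); ++t)
    net.remove_edge(doomed[t].first, doomed[t].second);
}

// mechanism codes: 0 = ND, 1 = LD, 2 = AGING
static void step(Net& net, double p_delta, double p_r, double w0, double delta,
                 int mech, double p_nd, double p_ld, double f, double w_th,
                 RNG& rng) {
  la_sweep(net, p_delta, w0, delta, rng);
  ga_sweep(net, p_r, w0, rng);
  if (mech == 0) nd_sweep(net, p_nd, rng);
  else if (mech == 1) ld_sweep(net, p_ld, rng);
  else aging_sweep(net, f, w_th);
}

// [[Rcpp::export]]
List cpp_evolve(int n, IntegerVector ei, IntegerVector ej, NumericVector ew,
                int steps, double p_delta, double p_r, double w0, double delta,
                int mech, double p_nd, double p_ld, double f, double w_th,
                double seed, bool record_ts, bool verbose) {
  Net net = net_from_r(n, ei, ej, ew);
  RNG rng((std::uint64_t)seed);
  NumericVector ts;
  if (record_ts) {
    ts = NumericVector(steps + 1);
    ts[0] = 2.0 * net.m / n;
  }
  for (int t = 1; t <= steps; ++t) {
    step(net, p_delta, p_r, w0, delta, mech, p_nd, p_ld, f, w_th, rng);
    if (record_ts) ts[t] = 2.0 * net.m / n;
    if (t % 1000 == 0) {
      if (verbose)
        Rcpp::Rcerr << "step " << t << "/" << steps
                    << "  <k> = " << 2.0 * net.m / n << std::endl;
      Rcpp::checkUserInterrupt();
    }
  }
  List out = net_to_r(net);
  if (record_ts) out["k_mean"] = ts;
  return out;
}

// [[Rcpp::export]]
List cpp_la_sweep(int n, IntegerVector ei, IntegerVector ej, NumericVector ew,
                  double p_delta, double w0, double delta, double seed) {
  Net net = net_from_r(n, ei, ej, ew);
  RNG rng((std::uint64_t)seed);
  la_sweep(net, p_delta, w0, delta, rng);
  return net_to_r(net);
}

// [[Rcpp::export]]
List cpp_la_event(int n, IntegerVector ei, IntegerVector ej, NumericVector ew,
                  int node, double p_delta, double w0, double delta,
                  double seed) {
  Net net = net_from_r(n, ei, ej, ew);
  RNG rng((std::uint64_t)seed);
  la_event(net, node - 1, p_delta, w0, delta, rng);
  return net_to_r(net);
}

// [[Rcpp::export]]
List cpp_ga_sweep(int n, IntegerVector ei, IntegerVector ej, NumericVector ew,
                  double p_r, double w0, double seed) {
  Net net = net_from_r(n, ei, ej, ew);
  RNG rng((std::uint64_t)seed);
  ga_sweep(net, p_r, w0, rng);
  return net_to_r(net);
}

// [[Rcpp::export]]
List cpp_nd_sweep(int n, IntegerVector ei, IntegerVector ej, NumericVector ew,
                  double p_nd, double seed) {
  Net net = net_from_r(n, ei, ej, ew);
  RNG rng((std::uint64_t)seed);
  nd_sweep(net, p_nd, rng);
  return net_to_r(net);
}

// [[Rcpp::export]]
List cpp_ld_sweep(int n, IntegerVector ei, IntegerVector ej, NumericVector ew,
                  double p_ld, double seed) {
  Net net = net_from_r(n, ei, ej, ew);
  RNG rng((std::uint64_t)seed);
  ld_sweep(net, p_ld, rng);
  return net_to_r(net);
}

// [[Rcpp::export]]
List cpp_aging_sweep(int n, IntegerVector ei, IntegerVector ej,
                     NumericVector ew, double f, double w_th) {
  Net net = net_from_r(n, ei, ej, ew);
  aging_sweep(net, f, w_th);
  return net_to_r(net);
}
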