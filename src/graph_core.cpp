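#include <Rcpp.h>
#include <vector>
#include <random>
#include <cstdint>
#include <limits>
#include <cmath>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// O(n^2) single-source Dijkstra on a dense length matrix; dense scan beats a
// heap at the graph sizes used here (<= a few hundred nodes).
static void dijkstra_dense(const std::vector<double>& L, int n, int src,
                           std::vector<double>& dist) {
  std::vector<char> done(n, 0);
  std::fill(dist.begin(), dist.end(), INF);
  dist[src] = 0.0;
  for (int it = 0; it < n; ++it) {
    int u = -1;
    double best = INF;
    for (int v = 0; v < n; ++v)
      if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
    if (u < 0) break;
    done[u] = 1;
    const double du = dist[u];
    const double* Lu = &L[(size_t)u * n];
    for (int v = 0; v < n; ++v) {
      double luv = Lu[v];
      if (luv < INF && !done[v] && du + luv < dist[v]) dist[v] = du + luv;
    }
  }
}

// All-pairs shortest path lengths from a dense length matrix.
// Entries <= 0 or non-finite are treated as absent edges.
// [[Rcpp::export]]
NumericMatrix cpp_apsp(NumericMatrix len) {
  int n = len.nrow();
  std::vector<double> L((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double x = len(i, j);
      L[(size_t)i * n + j] = (i != j && R_finite(x) && x > 0) ? x : INF;
    }
  NumericMatrix D(n, n);
  std::vector<double> dist(n);
  for (int s = 0; s < n; ++s) {
    dijkstra_dense(L, n, s, dist);
    for (int j = 0; j < n; ++j) D(s, j) = dist[j];
    D(s, s) = 0.0;
  }
  return D;
}

// Per-node local efficiency, Brain-Connectivity-Toolbox conventions.
// weighted = true: 2010 weighted formulation — shortest paths inside the
// neighbour subgraph on cube-rooted lengths (1/w)^(1/3), terms
// w_uj^(1/3) * w_uh^(1/3) / d_jh. Reduces exactly to the binary variant on
// unit weights.
// weighted = false: global efficiency of the binary neighbour subgraph.
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(NumericMatrix W, bool weighted) {
  int n = W.nrow();
  // contiguous copy; symmetric, so column-major == row-major layout
  std::vector<double> Wv((size_t)n * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) Wv[(size_t)i * n + j] = W(i, j);
  NumericVector eloc(n);
  std::vector<int> nb;
  for (int u = 0; u < n; ++u) {
    nb.clear();
    const double* Wu = &Wv[(size_t)u * n];
    for (int v = 0; v < n; ++v)
      if (v != u && Wu[v] > 0) nb.push_back(v);
    int k = (int)nb.size();
    if (k < 2) { eloc[u] = 0.0; continue; }
    // subgraph length matrix
    std::vector<double> L((size_t)k * k, INF);
    for (int a = 0; a < k; ++a) {
      const double* Wa = &Wv[(size_t)nb[a] * n];
      for (int b = 0; b < k; ++b) {
        if (a == b) continue;
        double w = Wa[nb[b]];
        if (w > 0) L[(size_t)a * k + b] = weighted ? std::cbrt(1.0 / w) : 1.0;
      }
    }
    std::vector<double> dist(k);
    double acc = 0.0;
    for (int a = 0; a < k; ++a) {
      dijkstra_dense(L, k, a, dist);
      for (int b = 0; b < k; ++b) {
        if (a == b || dist[b] == INF || dist[b] <= 0) continue;
        if (weighted) {
          acc += std::cbrt(Wu[nb[a]]) * std::cbrt(Wu[nb[b]]) / dist[b];
        } else {
          acc += 1.0 / dist[b];
        }
      }
    }
    eloc[u] = acc / ((double)k * (k - 1));
  }
  return eloc;
}

// ---- Louvain community detection -------------------------------------------

// Deterministic Fisher-Yates with mt19937 so results are identical across
// platforms for a given seed (std::shuffle is implementation-defined).
static void shuffle_order(std::vector<int>& ord, std::mt19937& rng) {
  for (int i = (int)ord.size() - 1; i > 0; --i) {
    std::uniform_int_distribution<int> d(0, i);
    std::swap(ord[i], ord[d(rng)]);
  }
}

struct Graph {
  int n;
  std::vector<double> W;   // dense symmetric, diagonal = self-loop weight
  std::vector<double> s;   // strengths incl. self-loop
  double two_m;            // sum of all entries
};

// One level of local moving; labels updated in place (0..n-1, not compacted).
// Returns true if any node moved.
static bool local_move(const Graph& g, std::vector<int>& lab,
                       std::mt19937& rng, double resolution) {
  int n = g.n;
  std::vector<double> Stot(n, 0.0);  // community total strength
  for (int i = 0; i < n; ++i) Stot[lab[i]] += g.s[i];
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::vector<double> wtoc(n, 0.0);
  std::vector<int> touched;
  bool any = false, improved = true;
  while (improved) {
    improved = false;
    shuffle_order(ord, rng);
    for (int oi = 0; oi < n; ++oi) {
      int i = ord[oi];
      int a = lab[i];
      // weights from i to each community (excluding self-loop)
      touched.clear();
      const double* Wi = &g.W[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        if (j == i || Wi[j] <= 0) continue;
        int c = lab[j];
        if (wtoc[c] == 0.0) touched.push_back(c);
        wtoc[c] += Wi[j];
      }
      Stot[a] -= g.s[i];
      double base = wtoc[a] - resolution * g.s[i] * Stot[a] / g.two_m;
      int best_c = a;
      double best_gain = 0.0;
      for (int t = 0; t < (int)touched.size(); ++t) {
        int c = touched[t];
        if (c == a) continue;
        double gain = (wtoc[c] - resolution * g.s[i] * Stot[c] / g.two_m) - base;
        if (gain > best_gain + 1e-12 ||
            (gain > best_gain - 1e-12 && gain > 0 && c < best_c)) {
          best_gain = gain; best_c = c;
        }
      }
      if (best_c != a && best_gain > 1e-12) {
        lab[i] = best_c;
        improved = true; any = true;
      }
      Stot[lab[i]] += g.s[i];
      for (int t = 0; t < (int)touched.size(); ++t) wtoc[touched[t]] = 0.0;
    }
  }
  return any;
}

static void compact_labels(std::vector<int>& lab, int& ncomm) {
  std::vector<int> map(lab.size(), -1);
  ncomm = 0;
  for (size_t i = 0; i < lab.size(); ++i) {
    if (map[lab[i]] < 0) map[lab[i]] = ncomm++;
    lab[i] = map[lab[i]];
  }
}

static Graph aggregate(const Graph& g, const std::vector<int>& lab, int ncomm) {
  Graph h;
  h.n = ncomm;
  h.W.assign((size_t)ncomm * ncomm, 0.0);
  for (int i = 0; i < g.n; ++i)
    for (int j = 0; j < g.n; ++j) {
      double w = g.W[(size_t)i * g.n + j];
      if (w > 0) h.W[(size_t)lab[i] * ncomm + lab[j]] += w;
    }
  h.s.assign(ncomm, 0.0);
  h.two_m = 0.0;
  for (int i = 0; i < ncomm; ++i)
    for (int j = 0; j < ncomm; ++j) {
      h.s[i] += h.W[(size_t)i * ncomm + j];
      h.two_m += h.W[(size_t)i * ncomm + j];
    }
  return h;
}

static double modularity_of(const Graph& g, const std::vector<int>& lab) {
  int ncomm = 0;
  for (size_t i = 0; i < lab.size(); ++i) ncomm = std::max(ncomm, lab[i] + 1);
  std::vector<double> ein(ncomm, 0.0), stot(ncomm, 0.0);
  for (int i = 0; i < g.n; ++i) {
    stot[lab[i]] += g.s[i];
    for (int j = 0; j < g.n; ++j)
      if (lab[j] == lab[i]) ein[lab[i]] += g.W[(size_t)i * g.n + j];
  }
  double q = 0.0;
  for (int c = 0; c < ncomm; ++c)
    q += ein[c] / g.two_m - (stot[c] / g.two_m) * (stot[c] / g.two_m);
  return q;
}

// Greedy two-phase Louvain on a dense nonnegative symmetric matrix with zero
// diagonal. Node visit order is shuffled from `seed`; fully deterministic for
// a given seed. Returns 1-based labels and the modularity of the partition.
// [[Rcpp::export]]
List cpp_louvain(NumericMatrix Wm, int seed, double resolution = 1.0) {
  int n = Wm.nrow();
  Graph g;
  g.n = n;
  g.W.assign((size_t)n * n, 0.0);
  g.s.assign(n, 0.0);
  g.two_m = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double w = Wm(i, j);
      if (i != j && w > 0) {
        g.W[(size_t)i * n + j] = w;
        g.s[i] += w;
        g.two_m += w;
      }
    }
  if (g.two_m <= 0) stop("graph has no positive weight; modularity undefined");

  std::mt19937 rng((uint32_t)seed);
  std::vector<int> final_lab(n);
  for (int i = 0; i < n; ++i) final_lab[i] = i;

  Graph cur = g;
  std::vector<int> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = i;
  bool moved = true;
  while (moved) {
    moved = local_move(cur, lab, rng, resolution);
    int ncomm;
    compact_labels(lab, ncomm);
    // map through to original nodes
    for (int i = 0; i < n; ++i) final_lab[i] = lab[final_lab[i]];
    if (!moved || ncomm == cur.n) break;
    cur = aggregate(cur, lab, ncomm);
    lab.assign(cur.n, 0);
    for (int i = 0; i < cur.n; ++i) lab[i] = i;
  }
  int ncomm;
  compact_labels(final_lab, ncomm);
  double q = modularity_of(g, final_lab);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = final_lab[i] + 1;
  return List::create(_["labels"] = out, _["q"] = q,
                      _["n_modules"] = ncomm);
}
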