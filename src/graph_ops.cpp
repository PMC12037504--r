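#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Binary undirected graph primitives used across the sparsity sweep and the
// degree-preserving null ensembles. Adjacency matrices are 0/1 integer,
// symmetric, zero diagonal; all checks on that contract live on the R side.
// Internally graphs are a flat char adjacency plus neighbor lists; the null
// ensemble loop reuses buffers to stay cheap (it runs ~10^5 times per
// cohort analysis).

struct Graph {
  int n;
  std::vector<char> adj;               // n*n, symmetric
  std::vector< std::vector<int> > nbr;

  void from_matrix(const IntegerMatrix &A) {
    n = A.nrow();
    adj.assign((size_t) n * n, 0);
    nbr.assign(n, std::vector<int>());
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        if (i != j && A(i, j) != 0) {
          adj[(size_t) i * n + j] = 1;
          nbr[i].push_back(j);
        }
  }
  void rebuild_nbr() {
    nbr.assign(n, std::vector<int>());
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (adj[(size_t) i * n + j]) nbr[i].push_back(j);
  }
  inline bool has(int i, int j) const { return adj[(size_t) i * n + j]; }
};

static void bfs_from(const Graph &g, int src, std::vector<int> &dist,
                     std::vector<int> &queue) {
  std::fill(dist.begin(), dist.end(), -1);
  queue.clear();
  queue.push_back(src);
  dist[src] = 0;
  for (size_t h = 0; h < queue.size(); ++h) {
    const int u = queue[h];
    const std::vector<int> &nb = g.nbr[u];
    for (size_t k = 0; k < nb.size(); ++k)
      if (dist[nb[k]] < 0) { dist[nb[k]] = dist[u] + 1; queue.push_back(nb[k]); }
  }
}

// mean clustering coefficient; nodes of degree < 2 contribute 0
static double clustering_mean(const Graph &g) {
  double acc = 0.0;
  for (int i = 0; i < g.n; ++i) {
    const std::vector<int> &nb = g.nbr[i];
    const int deg = (int) nb.size();
    if (deg < 2) continue;
    int links = 0;
    for (int a = 0; a < deg; ++a) {
      const char *row = &g.adj[(size_t) nb[a] * g.n];
      for (int b = a + 1; b < deg; ++b) links += row[nb[b]];
    }
    acc += 2.0 * links / ((double) deg * (deg - 1));
  }
  return acc / g.n;
}

struct PathStats {
  double lp;
  double eglob;
  int ncomp;
  bool has_pairs;
};

// single BFS sweep: components, characteristic path length and global
// efficiency. lp_mode: 0 = exclude disconnected pairs, 1 = largest
// component only.
static PathStats path_stats(const Graph &g, int lp_mode,
                            std::vector<int> &dist, std::vector<int> &queue,
                            std::vector<int> &comp) {
  const int n = g.n;
  comp.assign(n, -1);
  int ncomp = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    bfs_from(g, s, dist, queue);
    for (size_t h = 0; h < queue.size(); ++h) comp[queue[h]] = ncomp;
    ++ncomp;
  }
  std::vector<long> comp_size(ncomp, 0);
  for (int i = 0; i < n; ++i) ++comp_size[comp[i]];
  int big = 0;
  for (int c = 1; c < ncomp; ++c) if (comp_size[c] > comp_size[big]) big = c;

  double sum_d_all = 0.0, sum_d_big = 0.0, sum_inv = 0.0;
  long cnt_all = 0, cnt_big = 0;
  for (int s = 0; s < n; ++s) {
    bfs_from(g, s, dist, queue);
    const bool in_big = comp[s] == big;
    for (int t = 0; t < n; ++t) {
      const int d = dist[t];
      if (d <= 0) continue;
      sum_d_all += d;
      ++cnt_all;
      sum_inv += 1.0 / d;
      if (in_big) { sum_d_big += d; ++cnt_big; }
    }
  }
  PathStats out;
  out.ncomp = ncomp;
  out.eglob = (n > 1) ? sum_inv / ((double) n * (n - 1)) : 0.0;
  if (lp_mode == 1) {
    out.has_pairs = cnt_big > 0;
    out.lp = out.has_pairs ? sum_d_big / cnt_big : 0.0;
  } else {
    out.has_pairs = cnt_all > 0;
    out.lp = out.has_pairs ? sum_d_all / cnt_all : 0.0;
  }
  return out;
}

// global efficiency of the subgraph induced by each node's neighbors
static double local_efficiency(const Graph &g) {
  double acc = 0.0;
  std::vector< std::vector<int> > sub;
  std::vector<int> dist, queue;
  for (int i = 0; i < g.n; ++i) {
    const std::vector<int> &nb = g.nbr[i];
    const int k = (int) nb.size();
    if (k < 2) continue;
    sub.assign(k, std::vector<int>());
    for (int a = 0; a < k; ++a) {
      const char *row = &g.adj[(size_t) nb[a] * g.n];
      for (int b = 0; b < k; ++b)
        if (b != a && row[nb[b]]) sub[a].push_back(b);
    }
    dist.assign(k, -1);
    double sum_inv = 0.0;
    for (int s = 0; s < k; ++s) {
      // BFS within the neighborhood subgraph
      std::fill(dist.begin(), dist.end(), -1);
      queue.clear();
      queue.push_back(s);
      dist[s] = 0;
      for (size_t h = 0; h < queue.size(); ++h) {
        const int u = queue[h];
        for (size_t m = 0; m < sub[u].size(); ++m) {
          const int v = sub[u][m];
          if (dist[v] < 0) { dist[v] = dist[u] + 1; queue.push_back(v); }
        }
      }
      for (int t = 0; t < k; ++t)
        if (t != s && dist[t] > 0) sum_inv += 1.0 / dist[t];
    }
    acc += sum_inv / ((double) k * (k - 1));
  }
  return acc / g.n;
}

// [[Rcpp::export]]
IntegerMatrix cpp_distances(IntegerMatrix adj) {
  Graph g;
  g.from_matrix(adj);
  IntegerMatrix D(g.n, g.n);
  std::vector<int> dist(g.n), queue;
  queue.reserve(g.n);
  for (int s = 0; s < g.n; ++s) {
    bfs_from(g, s, dist, queue);
    for (int t = 0; t < g.n; ++t) D(s, t) = dist[t];  // -1 = unreachable
  }
  return D;
}

// [[Rcpp::export]]
List cpp_graph_metrics(IntegerMatrix adj, int lp_mode) {
  Graph g;
  g.from_matrix(adj);
  std::vector<int> dist(g.n), queue, comp;
  queue.reserve(g.n);
  const double cp = clustering_mean(g);
  PathStats ps = path_stats(g, lp_mode, dist, queue, comp);
  const double eloc = local_efficiency(g);
  return List::create(
    _["cp"] = cp,
    _["lp"] = ps.has_pairs ? ps.lp : NA_REAL,
    _["eloc"] = eloc,
    _["eglob"] = ps.eglob,
    _["n_components"] = ps.ncomp);
}

// Maslov-Sneppen double-edge swaps in place on a Graph's adjacency plus an
// explicit edge list; uses R's RNG so set.seed() on the R side makes
// ensembles reproducible.
static long do_rewire(Graph &g, std::vector<int> &ei, std::vector<int> &ej,
                      double swap_factor, int max_try_factor) {
  const long m = (long) ei.size();
  if (m < 2) return 0;
  const long target = (long) std::floor(swap_factor * m + 0.5);
  if (target <= 0) return 0;
  const long max_tries = (long) max_try_factor * target;
  const int n = g.n;
  long done = 0, tries = 0;
  while (done < target && tries < max_tries) {
    ++tries;
    const long e1 = (long) (unif_rand() * m);
    const long e2 = (long) (unif_rand() * m);
    if (e1 == e2) continue;
    int a = ei[e1], b = ej[e1];
    int c = ei[e2], d = ej[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // rewire (a,b),(c,d) -> (a,d),(b,c); degrees unchanged
    if (a == d || b == c) continue;                      // self-loops
    if (g.adj[(size_t) a * n + d] || g.adj[(size_t) b * n + c]) continue;
    g.adj[(size_t) a * n + b] = g.adj[(size_t) b * n + a] = 0;
    g.adj[(size_t) c * n + d] = g.adj[(size_t) d * n + c] = 0;
    g.adj[(size_t) a * n + d] = g.adj[(size_t) d * n + a] = 1;
    g.adj[(size_t) b * n + c] = g.adj[(size_t) c * n + b] = 1;
    ei[e1] = std::min(a, d); ej[e1] = std::max(a, d);
    ei[e2] = std::min(b, c); ej[e2] = std::max(b, c);
    ++done;
  }
  return done;
}

static void edge_list(const Graph &g, std::vector<int> &ei,
                      std::vector<int> &ej) {
  ei.clear(); ej.clear();
  for (int i = 0; i < g.n; ++i)
    for (int j = i + 1; j < g.n; ++j)
      if (g.has(i, j)) { ei.push_back(i); ej.push_back(j); }
}

static IntegerMatrix to_matrix(const Graph &g) {
  IntegerMatrix out(g.n, g.n);
  for (int j = 0; j < g.n; ++j)
    for (int i = 0; i < g.n; ++i)
      out(i, j) = g.adj[(size_t) i * g.n + j];
  return out;
}

// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix adj, double swap_factor, int max_try_factor) {
  Graph g;
  g.from_matrix(adj);
  std::vector<int> ei, ej;
  edge_list(g, ei, ej);
  const long target = (long) std::floor(swap_factor * (double) ei.size() + 0.5);
  const long done = do_rewire(g, ei, ej, swap_factor, max_try_factor);
  return List::create(
    _["adj"] = to_matrix(g),
    _["swaps"] = (double) done,
    _["target"] = (double) target);
}

// cp and lp over an ensemble of degree-preserving nulls (the hot path of
// the gamma/lambda/sigma normalization); one row per null graph.
// [[Rcpp::export]]
NumericMatrix cpp_null_cp_lp(IntegerMatrix adj, int n_null, double swap_factor,
                             int lp_mode, int max_try_factor) {
  Graph base;
  base.from_matrix(adj);
  std::vector<int> ei0, ej0;
  edge_list(base, ei0, ej0);
  NumericMatrix out(n_null, 2);
  Graph g;
  g.n = base.n;
  std::vector<int> ei, ej, dist(base.n), queue, comp;
  queue.reserve(base.n);
  for (int r = 0; r < n_null; ++r) {
    g.adj = base.adj;
    ei = ei0; ej = ej0;
    do_rewire(g, ei, ej, swap_factor, max_try_factor);
    g.rebuild_nbr();
    out(r, 0) = clustering_mean(g);
    PathStats ps = path_stats(g, lp_mode, dist, queue, comp);
    out(r, 1) = ps.has_pairs ? ps.lp : NA_REAL;
  }
  return out;
}

// Connected-component labels of the graph formed by an edge list
// (1-based endpoints); isolated nodes get their own label.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector ei, IntegerVector ej, int n) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  struct UF {
    std::vector<int> &p;
    UF(std::vector<int> &p_) : p(p_) {}
    int find(int x) {
      while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }  // path halving
      return x;
    }
  } uf(parent);
  const int m = ei.size();
  for (int k = 0; k < m; ++k) {
    int a = uf.find(ei[k] - 1), b = uf.find(ej[k] - 1);
    if (a != b) parent[a] = b;
  }
  IntegerVector lab(n);
  std::vector<int> remap(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (remap[r] < 0) remap[r] = next++;
    lab[i] = remap[r] + 1;
  }
  return lab;
}
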