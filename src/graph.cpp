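#include <Rcpp.h>
using namespace Rcpp;

// Adjacency convention throughout: adj(i, j) == 1 encodes an edge j -> i
// (information flow from column to row, matching the PDC index convention).
// Successors of node u are therefore the rows i with adj(i, u) != 0.

static void bfs_from(const int* adj, int d, int src, std::vector<int>& dist,
                     std::vector<int>& queue) {
  std::fill(dist.begin(), dist.end(), -1);
  queue.clear();
  dist[src] = 0;
  queue.push_back(src);
  for (size_t h = 0; h < queue.size(); ++h) {
    int u = queue[h];
    const int* col = adj + static_cast<size_t>(u) * d;
    for (int i = 0; i < d; ++i) {
      if (col[i] != 0 && dist[i] < 0) {
        dist[i] = dist[u] + 1;
        queue.push_back(i);
      }
    }
  }
}

// Directed geodesic distances; D(s, t) is the length of the shortest
// path s -> t, Inf when t is unreachable from s.
// [[Rcpp::export]]
NumericMatrix cpp_bfs_distances(IntegerMatrix adj) {
  const int d = adj.nrow();
  NumericMatrix D(d, d);
  std::vector<int> dist(d), queue;
  queue.reserve(d);
  for (int s = 0; s < d; ++s) {
    bfs_from(adj.begin(), d, s, dist, queue);
    for (int t = 0; t < d; ++t)
      D(s, t) = (dist[t] < 0) ? R_PosInf : static_cast<double>(dist[t]);
  }
  return D;
}

// Mean of 1/dist over ordered pairs (Latora-Marchiori), 1/Inf = 0.
static double global_eff(const std::vector<int>& sub, int m) {
  if (m < 2) return 0.0;
  double acc = 0.0;
  std::vector<int> dist(m), queue;
  queue.reserve(m);
  for (int s = 0; s < m; ++s) {
    bfs_from(sub.data(), m, s, dist, queue);
    for (int t = 0; t < m; ++t)
      if (t != s && dist[t] > 0) acc += 1.0 / dist[t];
  }
  return acc / (static_cast<double>(m) * (m - 1));
}

// [[Rcpp::export]]
double cpp_global_efficiency(IntegerMatrix adj) {
  const int d = adj.nrow();
  std::vector<int> sub(adj.begin(), adj.end());
  return global_eff(sub, d);
}

// Per-node local efficiency of a directed binary graph: efficiency of the
// subgraph induced on the union of in- and out-neighbours, node excluded;
// 0 when fewer than two neighbours.  Works on adjacency lists so the cost
// scales with edges actually present rather than d^2 per neighbourhood.
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(IntegerMatrix adj) {
  const int d = adj.nrow();
  const int* a = adj.begin();
  std::vector<std::vector<int> > outs(d), ins(d);
  for (int u = 0; u < d; ++u) {
    const int* col = a + static_cast<size_t>(u) * d;
    for (int i = 0; i < d; ++i) {
      if (col[i] != 0) {
        outs[u].push_back(i);   // edge u -> i
        ins[i].push_back(u);
      }
    }
  }
  NumericVector res(d);
  std::vector<int> pos(d, -1), nbr, dist, queue;
  std::vector<std::vector<int> > sub;
  for (int i = 0; i < d; ++i) {
    nbr.clear();
    for (int j : outs[i]) if (pos[j] == -1) { pos[j] = -2; nbr.push_back(j); }
    for (int j : ins[i])  if (pos[j] == -1) { pos[j] = -2; nbr.push_back(j); }
    const int m = static_cast<int>(nbr.size());
    if (m < 2) {
      for (int j : nbr) pos[j] = -1;
      res[i] = 0.0;
      continue;
    }
    for (int b = 0; b < m; ++b) pos[nbr[b]] = b;
    sub.assign(m, std::vector<int>());
    for (int b = 0; b < m; ++b)
      for (int j : outs[nbr[b]])
        if (j != i && pos[j] >= 0) sub[b].push_back(pos[j]);
    double acc = 0.0;
    dist.assign(m, -1);
    queue.resize(m);
    for (int s = 0; s < m; ++s) {
      std::fill(dist.begin(), dist.end(), -1);
      int head = 0, tail = 0;
      dist[s] = 0;
      queue[tail++] = s;
      while (head < tail) {
        const int u = queue[head++];
        for (int v : sub[u]) {
          if (dist[v] < 0) {
            dist[v] = dist[u] + 1;
            queue[tail++] = v;
          }
        }
      }
      for (int t = 0; t < m; ++t)
        if (t != s && dist[t] > 0) acc += 1.0 / dist[t];
    }
    res[i] = acc / (static_cast<double>(m) * (m - 1));
    for (int b = 0; b < m; ++b) pos[nbr[b]] = -1;
  }
  return res;
}

// adj: d x d x n_freq binary array, column-major.
// [[Rcpp::export]]
NumericMatrix cpp_local_efficiency_series(IntegerVector adj, IntegerVector dims) {
  const int d = dims[0], nf = dims[2];
  NumericMatrix out(d, nf);
  IntegerMatrix slice(d, d);
  const size_t dd = static_cast<size_t>(d) * d;
  for (int f = 0; f < nf; ++f) {
    std::copy(adj.begin() + f * dd, adj.begin() + (f + 1) * dd, slice.begin());
    NumericVector e = cpp_local_efficiency(slice);
    for (int i = 0; i < d; ++i) out(i, f) = e[i];
  }
  return out;
}
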