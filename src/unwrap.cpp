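// Reliability-sorted 2D phase unwrapping.
//
// Herraez-style algorithm: every pixel gets a reliability from wrapped
// second differences; edges between 4-neighbours are sorted by joint
// reliability and merged with a union-find whose per-node offsets count
// the integer number of 2*pi periods relative to the component root.
// The output therefore differs from the input by an exact integer
// multiple of 2*pi at every pixel.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

static inline double wrap_pi(double x) {
  const double TWO_PI = 2.0 * M_PI;
  return x - TWO_PI * std::floor((x + M_PI) / TWO_PI);
  // result lies in [-pi, pi)
}

static inline long long round_ll(double x) {
  return (long long)(x >= 0 ? x + 0.5 : x - 0.5);
}

struct UnionFind {
  std::vector<int> parent, rank_;
  std::vector<long long> off;  // periods relative to parent
  explicit UnionFind(int n) : parent(n), rank_(n, 0), off(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  // find root; path-compress while accumulating offsets
  int find(int a, long long &acc) {
    long long total = 0;
    int r = a;
    while (parent[r] != r) { total += off[r]; r = parent[r]; }
    // compress
    int cur = a;
    long long rem = total;
    while (parent[cur] != r) {
      int nxt = parent[cur];
      long long o = off[cur];
      parent[cur] = r;
      off[cur] = rem;
      rem -= o;
      cur = nxt;
    }
    acc = total;
    return r;
  }
  // enforce n(a) - n(b) = d
  void unite(int a, int b, long long d) {
    long long oa, ob;
    int ra = find(a, oa), rb = find(b, ob);
    if (ra == rb) return;  // inconsistency (residue) — keep first solution
    // n(a) = oa + N(ra); n(b) = ob + N(rb); want oa + N(ra) - ob - N(rb) = d
    if (rank_[ra] < rank_[rb]) {
      // attach ra under rb: off[ra] = N(ra) - N(rb) = d - oa + ob
      parent[ra] = rb;
      off[ra] = d - oa + ob;
    } else {
      parent[rb] = ra;
      off[rb] = -(d - oa + ob);
      if (rank_[ra] == rank_[rb]) rank_[ra]++;
    }
  }
};

// [[Rcpp::export(name = ".unwrap2d")]]
Rcpp::NumericMatrix unwrap2d(Rcpp::NumericMatrix phase) {
  const int nr = phase.nrow(), nc = phase.ncol(), n = nr * nc;
  const double TWO_PI = 2.0 * M_PI;
  std::vector<double> rel(n, 0.0);

  // pixel reliability = 1 / D, D from wrapped second differences
  const double BIG = 1e10;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int idx = i + j * nr;
      if (i == 0 || i == nr - 1 || j == 0 || j == nc - 1) {
        rel[idx] = 1.0 / BIG;
        continue;
      }
      double c = phase(i, j);
      double H = wrap_pi(phase(i, j - 1) - c) - wrap_pi(c - phase(i, j + 1));
      double V = wrap_pi(phase(i - 1, j) - c) - wrap_pi(c - phase(i + 1, j));
      double D1 =
          wrap_pi(phase(i - 1, j - 1) - c) - wrap_pi(c - phase(i + 1, j + 1));
      double D2 =
          wrap_pi(phase(i + 1, j - 1) - c) - wrap_pi(c - phase(i - 1, j + 1));
      double D = std::sqrt(H * H + V * V + D1 * D1 + D2 * D2);
      rel[idx] = 1.0 / (D > 1e-12 ? D : 1e-12);
    }
  }

  // edges between horizontal and vertical neighbours
  struct Edge { double r; int a, b; };
  std::vector<Edge> edges;
  edges.reserve(2 * (size_t)n);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i + 1 < nr; ++i) {
      int a = i + j * nr;
      edges.push_back({rel[a] + rel[a + 1], a, a + 1});
    }
  for (int j = 0; j + 1 < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int a = i + j * nr;
      edges.push_back({rel[a] + rel[a + nr], a, a + nr});
    }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge &x, const Edge &y) { return x.r > y.r; });

  UnionFind uf(n);
  const double *ph = phase.begin();
  for (const Edge &e : edges) {
    // want ph[a] + 2*pi*n(a) - ph[b] - 2*pi*n(b) wrapped to (-pi, pi]
    double d = (ph[e.b] - ph[e.a]) / TWO_PI;
    long long k = round_ll(d);
    uf.unite(e.a, e.b, k);
  }

  Rcpp::NumericMatrix out(nr, nc);
  for (int idx = 0; idx < n; ++idx) {
    long long o;
    uf.find(idx, o);
    out[idx] = ph[idx] + TWO_PI * (double)o;
  }
  return out;
}
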