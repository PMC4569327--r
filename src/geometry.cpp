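#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double d, double E) {
  double m = d - E * std::floor(d / E); // in [0, E)
  if (m > E / 2.0) m -= E;
  return m;
}

// Full matrix of minimal-image toroidal distances.
// [[Rcpp::export(name = ".torus_dist_cpp")]]
NumericMatrix torus_dist_cpp(NumericMatrix pos, double EW, double EH) {
  const int n = pos.nrow();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(pos(j, 0) - pos(i, 0), EW);
      double dy = min_image(pos(j, 1) - pos(i, 1), EH);
      double d = std::sqrt(dx * dx + dy * dy);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

struct UnionFind {
  std::vector<int> parent, size;
  UnionFind(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

// Size of the largest connected component of the toroidal proximity graph
// (edge iff distance <= r_vis).
// [[Rcpp::export(name = ".largest_cluster_cpp")]]
int largest_cluster_cpp(NumericMatrix pos, double r_vis, double EW, double EH) {
  const int n = pos.nrow();
  UnionFind uf(n);
  const double r2 = r_vis * r_vis;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(pos(j, 0) - pos(i, 0), EW);
      double dy = min_image(pos(j, 1) - pos(i, 1), EH);
      if (dx * dx + dy * dy <= r2) uf.unite(i, j);
    }
  }
  int best = 0;
  for (int i = 0; i < n; ++i)
    if (uf.find(i) == i && uf.size[i] > best) best = uf.size[i];
  return best;
}
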