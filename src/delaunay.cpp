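#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <set>
#include <utility>
using namespace Rcpp;

// Bowyer-Watson Delaunay triangulation.  Points that are exactly cocircular
// are treated as "not inside" the circumcircle (strict test with a relative
// tolerance), so degenerate lattices still yield a valid triangulation with
// an arbitrary but deterministic tie-break.

struct Tri {
  int a, b, c;      // vertex indices, -1..-3 are super-triangle vertices
  double cx, cy, r2; // circumcircle
  bool alive;
};

static bool circumcircle(double ax, double ay, double bx, double by,
                         double cx_, double cy_,
                         double &ox, double &oy, double &r2) {
  double d = 2.0 * (ax * (by - cy_) + bx * (cy_ - ay) + cx_ * (ay - by));
  if (std::fabs(d) < 1e-12) return false; // collinear
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
         c2 = cx_ * cx_ + cy_ * cy_;
  ox = (a2 * (by - cy_) + b2 * (cy_ - ay) + c2 * (ay - by)) / d;
  oy = (a2 * (cx_ - bx) + b2 * (ax - cx_) + c2 * (bx - ax)) / d;
  double dx = ax - ox, dy = ay - oy;
  r2 = dx * dx + dy * dy;
  return true;
}

// Triangulate points (px, py); returns triangles as triples of 0-based
// indices.  O(n^2) insertion, adequate for the ~10^3 points used here.
static std::vector<std::array<int, 3>>
bowyer_watson(const std::vector<double> &px, const std::vector<double> &py) {
  const int n = (int)px.size();
  std::vector<std::array<int, 3>> out;
  if (n < 3) return out;

  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) dmax = 1.0;
  double midx = (xmin + xmax) / 2.0, midy = (ymin + ymax) / 2.0;
  // super-triangle vertices, far outside the point cloud
  double sx[3] = {midx - 30.0 * dmax, midx, midx + 30.0 * dmax};
  double sy[3] = {midy - 10.0 * dmax, midy + 30.0 * dmax, midy - 10.0 * dmax};

  auto get_x = [&](int i) { return i >= 0 ? px[i] : sx[-i - 1]; };
  auto get_y = [&](int i) { return i >= 0 ? py[i] : sy[-i - 1]; };

  std::vector<Tri> tris;
  auto add_tri = [&](int a, int b, int c) {
    Tri t;
    t.a = a; t.b = b; t.c = c; t.alive = true;
    if (!circumcircle(get_x(a), get_y(a), get_x(b), get_y(b),
                      get_x(c), get_y(c), t.cx, t.cy, t.r2))
      t.alive = false; // degenerate (collinear) triangle: drop
    else
      tris.push_back(t);
  };
  add_tri(-1, -2, -3);

  typedef std::pair<int, int> Edge;
  std::vector<int> bad;
  std::vector<Edge> boundary;
  size_t dead = 0;
  for (int p = 0; p < n; ++p) {
    double pxx = px[p], pyy = py[p];
    bad.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = pxx - tris[t].cx, dy = pyy - tris[t].cy;
      double d2 = dx * dx + dy * dy;
      if (d2 < tris[t].r2 * (1.0 - 1e-12)) bad.push_back(t);
    }
    // boundary of the cavity: edges appearing in exactly one bad triangle
    boundary.clear();
    auto toggle = [&](int u, int v) {
      Edge e = u < v ? Edge(u, v) : Edge(v, u);
      for (size_t k = 0; k < boundary.size(); ++k)
        if (boundary[k] == e) {
          boundary[k] = boundary.back();
          boundary.pop_back();
          return;
        }
      boundary.push_back(e);
    };
    for (int t : bad) {
      toggle(tris[t].a, tris[t].b);
      toggle(tris[t].b, tris[t].c);
      toggle(tris[t].c, tris[t].a);
      tris[t].alive = false;
    }
    dead += bad.size();
    for (const Edge &e : boundary) add_tri(e.first, e.second, p);
    if (dead > tris.size() / 2) { // compact the triangle list
      size_t w = 0;
      for (size_t r = 0; r < tris.size(); ++r)
        if (tris[r].alive) tris[w++] = tris[r];
      tris.resize(w);
      dead = 0;
    }
  }

  for (const Tri &t : tris) {
    if (!t.alive) continue;
    if (t.a < 0 || t.b < 0 || t.c < 0) continue; // touches super-triangle
    out.push_back({t.a, t.b, t.c});
  }
  return out;
}

// Planar Delaunay triangulation: m x 3 matrix of 1-based vertex indices.
// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  auto tris = bowyer_watson(px, py);
  IntegerMatrix out(tris.size(), 3);
  for (int i = 0; i < (int)tris.size(); ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = tris[i][j] + 1;
  return out;
}

// Voronoi (Delaunay-dual) adjacency on the torus: triangulate the 3x3
// tiling, keep edges with at least one endpoint in the central tile, map
// copies back to original indices.  Returns a list of sorted 1-based
// neighbour vectors.  Empty list element(s) signal degeneracy the caller
// should handle (fallback).
// [[Rcpp::export(name = ".torus_voronoi_cpp")]]
List torus_voronoi_cpp(NumericMatrix pos, double EW, double EH) {
  const int n = pos.nrow();
  std::vector<double> px, py;
  px.reserve(9 * n); py.reserve(9 * n);
  const double offs[3] = {-1.0, 0.0, 1.0};
  // tile order: (dx,dy) row-major; central tile (0,0) is block index 4
  for (int oy = 0; oy < 3; ++oy)
    for (int ox = 0; ox < 3; ++ox)
      for (int i = 0; i < n; ++i) {
        px.push_back(pos(i, 0) + offs[ox] * EW);
        py.push_back(pos(i, 1) + offs[oy] * EH);
      }
  auto tris = bowyer_watson(px, py);
  std::vector<std::set<int>> adj(n);
  const int lo = 4 * n, hi = 5 * n; // central tile indices [lo, hi)
  auto add_edge = [&](int u, int v) {
    bool cu = (u >= lo && u < hi), cv = (v >= lo && v < hi);
    if (!cu && !cv) return;
    int iu = u % n, iv = v % n;
    if (iu == iv) return; // a point and its own periodic image
    adj[iu].insert(iv);
    adj[iv].insert(iu);
  };
  for (const auto &t : tris) {
    add_edge(t[0], t[1]);
    add_edge(t[1], t[2]);
    add_edge(t[2], t[0]);
  }
  List out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v(adj[i].size());
    int k = 0;
    for (int j : adj[i]) v[k++] = j + 1;
    out[i] = v;
  }
  return out;
}
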