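// Deterministic Bowyer-Watson Delaunay triangulation and small geometric
// helpers for unstructured mesh generation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <array>

using namespace Rcpp;

struct Tri {
  int a, b, c;       // vertex indices
  double cx, cy, r2; // circumcircle
  bool alive;
};

static inline void circum(const std::vector<double>& px,
                          const std::vector<double>& py, Tri& t) {
  double ax = px[t.a], ay = py[t.a];
  double bx = px[t.b], by = py[t.b];
  double cx = px[t.c], cy = py[t.c];
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) { t.cx = t.cy = 0; t.r2 = 1e300; return; }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  t.cx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  t.cy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - t.cx, dy = ay - t.cy;
  t.r2 = dx * dx + dy * dy;
}

// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(n + 3), py(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1);
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) dmax = 1.0;
  double xc = 0.5 * (xmin + xmax), yc = 0.5 * (ymin + ymax);
  // super triangle
  px[n] = xc - 20.0 * dmax; py[n] = yc - 10.0 * dmax;
  px[n + 1] = xc + 20.0 * dmax; py[n + 1] = yc - 10.0 * dmax;
  px[n + 2] = xc; py[n + 2] = yc + 20.0 * dmax;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  Tri super { n, n + 1, n + 2, 0, 0, 0, true };
  circum(px, py, super);
  tris.push_back(super);

  std::vector<int> bad;
  size_t ndead = 0;
  // edge list of cavity boundary: pairs (u,v) with count
  for (int ip = 0; ip < n; ++ip) {
    if (ndead > tris.size() / 2 && tris.size() > 64) {
      std::vector<Tri> keep;
      keep.reserve(tris.size() - ndead);
      for (auto& t : tris) if (t.alive) keep.push_back(t);
      tris.swap(keep);
      ndead = 0;
    }
    double x = px[ip], y = py[ip];
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = x - tris[t].cx, dy = y - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 * (1.0 + 1e-12)) bad.push_back((int)t);
    }
    // collect boundary edges (edges appearing once among bad triangles)
    std::vector<std::array<int,2>> edges;
    edges.reserve(bad.size() * 3);
    for (int bt : bad) {
      const Tri& T = tris[bt];
      int vs[3] = { T.a, T.b, T.c };
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        bool dup = false;
        for (size_t k = 0; k < edges.size(); ++k) {
          if (edges[k][0] == v && edges[k][1] == u) {
            edges.erase(edges.begin() + k); dup = true; break;
          }
        }
        if (!dup) edges.push_back({u, v});
      }
    }
    for (int bt : bad) tris[bt].alive = false;
    ndead += bad.size();
    for (auto& e : edges) {
      Tri nt { e[0], e[1], ip, 0, 0, 0, true };
      circum(px, py, nt);
      tris.push_back(nt);
    }
  }
  // collect triangles not touching the super vertices
  std::vector<std::array<int,3>> out;
  for (auto& t : tris) {
    if (!t.alive) continue;
    if (t.a >= n || t.b >= n || t.c >= n) continue;
    // orient counterclockwise
    double ax = px[t.a], ay = py[t.a], bx = px[t.b], by = py[t.b],
           cx2 = px[t.c], cy2 = py[t.c];
    double cr = (bx - ax) * (cy2 - ay) - (by - ay) * (cx2 - ax);
    if (cr >= 0) out.push_back({t.a, t.b, t.c});
    else out.push_back({t.a, t.c, t.b});
  }
  IntegerMatrix res(out.size(), 3);
  for (size_t i = 0; i < out.size(); ++i) {
    res(i, 0) = out[i][0]; res(i, 1) = out[i][1]; res(i, 2) = out[i][2];
  }
  return res;
}

// ray-casting point in polygon (open vertex list, implicit closure)
static bool pip(double x, double y, const NumericMatrix& poly) {
  int n = poly.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = poly(i, 0), yi = poly(i, 1);
    double xj = poly(j, 0), yj = poly(j, 1);
    if (((yi > y) != (yj > y)) &&
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector points_in_polygon_cpp(NumericMatrix pts, NumericMatrix poly) {
  int n = pts.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pip(pts(i, 0), pts(i, 1), poly);
  return out;
}

// minimum distance from each point to a closed polyline (polygon boundary)
// [[Rcpp::export]]
NumericVector dist_to_polyline_cpp(NumericMatrix pts, NumericMatrix poly,
                                   bool closed = true) {
  int n = pts.nrow(), m = poly.nrow();
  NumericVector out(n);
  int mseg = closed ? m : (m - 1);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1);
    double best = R_PosInf;
    for (int j = 0; j < mseg; ++j) {
      int k = (j + 1) % m;
      double ax = poly(j, 0), ay = poly(j, 1);
      double bx = poly(k, 0), by = poly(k, 1);
      double dx = bx - ax, dy = by - ay;
      double L2 = dx * dx + dy * dy;
      double t = L2 > 0 ? ((x - ax) * dx + (y - ay) * dy) / L2 : 0.0;
      t = std::max(0.0, std::min(1.0, t));
      double qx = ax + t * dx - x, qy = ay + t * dy - y;
      double d2 = qx * qx + qy * qy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// locate containing triangle for each query point (brute force, used for
// remesh field transfer and endpoint probing); returns 0-based cell index or
// -1, with nearest-centroid fallback if `nearest` is true.
// [[Rcpp::export]]
IntegerVector locate_cells_cpp(NumericMatrix query, NumericMatrix nodes,
                               IntegerMatrix tris1, bool nearest = true) {
  int nq = query.nrow(), nt = tris1.nrow();
  IntegerMatrix tris(nt, 3);              // accept 1-based triangles from R
  for (int t = 0; t < nt; ++t)
    for (int j = 0; j < 3; ++j) tris(t, j) = tris1(t, j) - 1;
  IntegerVector out(nq);
  std::vector<double> cx(nt), cy(nt);
  for (int t = 0; t < nt; ++t) {
    cx[t] = (nodes(tris(t,0),0) + nodes(tris(t,1),0) + nodes(tris(t,2),0)) / 3.0;
    cy[t] = (nodes(tris(t,0),1) + nodes(tris(t,1),1) + nodes(tris(t,2),1)) / 3.0;
  }
  for (int i = 0; i < nq; ++i) {
    double x = query(i, 0), y = query(i, 1);
    int found = -1;
    for (int t = 0; t < nt; ++t) {
      double ax = nodes(tris(t,0),0), ay = nodes(tris(t,0),1);
      double bx = nodes(tris(t,1),0), by = nodes(tris(t,1),1);
      double cx2 = nodes(tris(t,2),0), cy2 = nodes(tris(t,2),1);
      double d1 = (bx-ax)*(y-ay) - (by-ay)*(x-ax);
      double d2 = (cx2-bx)*(y-by) - (cy2-by)*(x-bx);
      double d3 = (ax-cx2)*(y-cy2) - (ay-cy2)*(x-cx2);
      double eps = -1e-12;
      if (d1 >= eps && d2 >= eps && d3 >= eps) { found = t; break; }
    }
    if (found < 0 && nearest) {
      double best = R_PosInf;
      for (int t = 0; t < nt; ++t) {
        double dx = cx[t] - x, dy = cy[t] - y;
        double d2 = dx * dx + dy * dy;
        if (d2 < best) { best = d2; found = t; }
      }
    }
    out[i] = found;
  }
  return out;
}
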