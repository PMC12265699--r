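#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <utility>

// Incremental 3D convex hull. Points are added one at a time; faces
// visible from the new point are removed and the horizon is re-capped.
// Returns the triangular facets (1-based vertex indices) oriented with
// outward normals. Robustness: signed-volume predicate with a tolerance
// scaled to the point cloud extent.

struct Face {
  int a, b, c;
  double nx, ny, nz, off; // outward normal and plane offset (n . x = off)
  bool alive;
};

static inline void face_plane(const std::vector<double>& X,
                              const std::vector<double>& Y,
                              const std::vector<double>& Z,
                              Face& f) {
  double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
  double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * X[f.a] + f.ny * Y[f.a] + f.nz * Z[f.a];
}

// [[Rcpp::export]]
Rcpp::List hull3d_cpp(Rcpp::NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) Rcpp::stop("need at least 4 points for a 3D hull");
  std::vector<double> X(n), Y(n), Z(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
    double v[3] = {X[i], Y[i], Z[i]};
    for (int k = 0; k < 3; ++k) {
      if (v[k] < lo[k]) lo[k] = v[k];
      if (v[k] > hi[k]) hi[k] = v[k];
    }
  }
  double scale = 0.0;
  for (int k = 0; k < 3; ++k) scale = std::max(scale, hi[k] - lo[k]);
  if (scale <= 0.0) Rcpp::stop("degenerate geometry: all points coincide");
  const double eps = 1e-10 * scale * scale;       // area-scaled tolerance
  const double veps = 1e-12 * scale * scale * scale;

  // initial simplex: two extreme points in x, then farthest from the
  // line, then farthest from the plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (X[i] < X[i0]) i0 = i;
    if (X[i] > X[i1]) i1 = i;
  }
  if (i0 == i1) { i0 = 0; i1 = 1; }
  double best = -1.0; int i2 = -1;
  double ax = X[i1] - X[i0], ay = Y[i1] - Y[i0], az = Z[i1] - Z[i0];
  for (int i = 0; i < n; ++i) {
    double bx = X[i] - X[i0], by = Y[i] - Y[i0], bz = Z[i] - Z[i0];
    double cx = ay * bz - az * by, cy = az * bx - ax * bz, cz = ax * by - ay * bx;
    double d2 = cx * cx + cy * cy + cz * cz;
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (i2 < 0 || best <= eps * eps) Rcpp::stop("degenerate geometry: points are collinear");
  best = -1.0; int i3 = -1;
  Face f0{i0, i1, i2, 0, 0, 0, 0, true};
  std::vector<Face> faces;
  face_plane(X, Y, Z, f0);
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(f0.nx * X[i] + f0.ny * Y[i] + f0.nz * Z[i] - f0.off);
    if (d > best) { best = d; i3 = i; }
  }
  {
    double d = f0.nx * X[i3] + f0.ny * Y[i3] + f0.nz * Z[i3] - f0.off;
    if (std::fabs(d) <= veps) Rcpp::stop("degenerate geometry: points are coplanar");
    // orient the four initial faces outward w.r.t. the simplex centroid
    double cx = (X[i0] + X[i1] + X[i2] + X[i3]) / 4.0;
    double cy = (Y[i0] + Y[i1] + Y[i2] + Y[i3]) / 4.0;
    double cz = (Z[i0] + Z[i1] + Z[i2] + Z[i3]) / 4.0;
    int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
    for (int t = 0; t < 4; ++t) {
      Face f{tet[t][0], tet[t][1], tet[t][2], 0, 0, 0, 0, true};
      face_plane(X, Y, Z, f);
      if (f.nx * cx + f.ny * cy + f.nz * cz - f.off > 0) {
        std::swap(f.b, f.c);
        face_plane(X, Y, Z, f);
      }
      faces.push_back(f);
    }
  }

  std::vector<char> done(n, 0);
  done[i0] = done[i1] = done[i2] = done[i3] = 1;

  std::vector<int> visible;
  for (int p = 0; p < n; ++p) {
    if (done[p]) continue;
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double d = faces[f].nx * X[p] + faces[f].ny * Y[p] + faces[f].nz * Z[p]
                 - faces[f].off;
      if (d > eps) visible.push_back((int)f);
    }
    if (visible.empty()) continue; // interior point
    // horizon: directed edges of visible faces whose reverse is not visible
    std::map<std::pair<int, int>, int> edge;
    for (int fi : visible) {
      const Face& f = faces[fi];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int k = 0; k < 3; ++k)
        edge[std::make_pair(e[k][0], e[k][1])] = 1;
    }
    std::vector<std::pair<int, int> > horizon;
    for (std::map<std::pair<int, int>, int>::iterator it = edge.begin();
         it != edge.end(); ++it) {
      std::pair<int, int> rev(it->first.second, it->first.first);
      if (edge.find(rev) == edge.end()) horizon.push_back(it->first);
    }
    for (int fi : visible) faces[fi].alive = false;
    for (size_t h = 0; h < horizon.size(); ++h) {
      Face f{horizon[h].first, horizon[h].second, p, 0, 0, 0, 0, true};
      face_plane(X, Y, Z, f);
      faces.push_back(f);
    }
  }

  std::vector<int> keep;
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].alive) keep.push_back((int)f);
  Rcpp::IntegerMatrix tri(keep.size(), 3);
  for (size_t k = 0; k < keep.size(); ++k) {
    tri(k, 0) = faces[keep[k]].a + 1;
    tri(k, 1) = faces[keep[k]].b + 1;
    tri(k, 2) = faces[keep[k]].c + 1;
  }
  std::vector<char> isv(n, 0);
  for (size_t k = 0; k < keep.size(); ++k) {
    isv[faces[keep[k]].a] = 1; isv[faces[keep[k]].b] = 1; isv[faces[keep[k]].c] = 1;
  }
  std::vector<int> verts;
  for (int i = 0; i < n; ++i) if (isv[i]) verts.push_back(i + 1);
  return Rcpp::List::create(Rcpp::Named("faces") = tri,
                            Rcpp::Named("vertices") = Rcpp::wrap(verts));
}
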