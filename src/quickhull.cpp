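// 3D convex hull (quickhull) used for intracranial-volume extraction and for
// triangulating quasi-uniform point sets on the sphere.  Visibility is tested
// by a full face scan rather than an adjacency walk: simpler, and fast enough
// for the point counts this package meets (<= a few 10^4).
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Face {
  int a, b, c;                 // vertex indices, outward CCW
  double nx, ny, nz, off;      // unnormalized outward normal, plane offset
  std::vector<int> outside;    // candidate points strictly outside
  bool alive;
};

inline void plane(const std::vector<double>& X, const std::vector<double>& Y,
                  const std::vector<double>& Z, Face& f) {
  double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
  double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * X[f.a] + f.ny * Y[f.a] + f.nz * Z[f.a];
}

inline double sdist(const Face& f, double x, double y, double z) {
  double nn = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
  if (nn == 0.0) return 0.0;
  return (f.nx * x + f.ny * y + f.nz * z - f.off) / nn;
}

} // namespace

// [[Rcpp::export(name = ".quickhull_cpp")]]
List quickhull_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<double> X(n), Y(n), Z(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
    double p[3] = {X[i], Y[i], Z[i]};
    for (int k = 0; k < 3; ++k) {
      if (p[k] < lo[k]) lo[k] = p[k];
      if (p[k] > hi[k]) hi[k] = p[k];
    }
  }
  double diag = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) + (hi[1]-lo[1])*(hi[1]-lo[1]) +
                          (hi[2]-lo[2])*(hi[2]-lo[2]));
  if (!R_finite(diag) || diag <= 0.0) stop("degenerate point set: zero extent");
  const double eps = 1e-10 * diag;

  // Initial simplex: two extreme points, farthest from the segment, farthest
  // from the plane.
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (X[i] < X[i0] || (X[i] == X[i0] && Y[i] < Y[i0])) i0 = i;
    if (X[i] > X[i1] || (X[i] == X[i1] && Y[i] > Y[i1])) i1 = i;
  }
  if (i0 == i1) i1 = (i0 + 1) % n;
  double dx = X[i1]-X[i0], dy = Y[i1]-Y[i0], dz = Z[i1]-Z[i0];
  double dlen2 = dx*dx + dy*dy + dz*dz;
  if (dlen2 <= eps * eps) stop("degenerate point set: all points coincide");
  int i2 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    double px = X[i]-X[i0], py = Y[i]-Y[i0], pz = Z[i]-Z[i0];
    double cx = dy*pz - dz*py, cy = dz*px - dx*pz, cz = dx*py - dy*px;
    double d = std::sqrt((cx*cx + cy*cy + cz*cz) / dlen2);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point set: all points collinear");
  Face f0; f0.a = i0; f0.b = i1; f0.c = i2; f0.alive = true;
  plane(X, Y, Z, f0);
  int i3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(sdist(f0, X[i], Y[i], Z[i]));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point set: all points coplanar");

  // interior reference point
  double ox = (X[i0]+X[i1]+X[i2]+X[i3]) / 4.0;
  double oy = (Y[i0]+Y[i1]+Y[i2]+Y[i3]) / 4.0;
  double oz = (Z[i0]+Z[i1]+Z[i2]+Z[i3]) / 4.0;

  std::vector<Face> faces;
  faces.reserve(8 * (size_t)std::sqrt((double)n) + 64);
  int tet[4][3] = {{i0,i1,i2},{i0,i1,i3},{i0,i2,i3},{i1,i2,i3}};
  for (int t = 0; t < 4; ++t) {
    Face f; f.a = tet[t][0]; f.b = tet[t][1]; f.c = tet[t][2]; f.alive = true;
    plane(X, Y, Z, f);
    if (sdist(f, ox, oy, oz) > 0) { std::swap(f.b, f.c); plane(X, Y, Z, f); }
    faces.push_back(f);
  }
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (size_t t = 0; t < faces.size(); ++t) {
      if (sdist(faces[t], X[i], Y[i], Z[i]) > eps) { faces[t].outside.push_back(i); break; }
    }
  }

  // Main loop
  for (;;) {
    int fi = -1;
    for (size_t t = 0; t < faces.size(); ++t)
      if (faces[t].alive && !faces[t].outside.empty()) { fi = (int)t; break; }
    if (fi < 0) break;
    // farthest outside point of this face
    int p = -1; double bd = -1.0;
    for (int idx : faces[fi].outside) {
      double d = sdist(faces[fi], X[idx], Y[idx], Z[idx]);
      if (d > bd) { bd = d; p = idx; }
    }
    // visible faces (full scan)
    std::vector<int> visible;
    for (size_t t = 0; t < faces.size(); ++t) {
      if (!faces[t].alive) continue;
      if (sdist(faces[t], X[p], Y[p], Z[p]) > eps) visible.push_back((int)t);
    }
    // horizon: undirected edges appearing exactly once among visible faces,
    // kept with the directed orientation of their visible face
    std::unordered_map<int64_t, std::pair<int,int> > once;
    std::unordered_map<int64_t, int> cnt;
    for (int t : visible) {
      const Face& f = faces[t];
      int uu[3] = {f.a, f.b, f.c};
      int vv[3] = {f.b, f.c, f.a};
      for (int e = 0; e < 3; ++e) {
        int u = uu[e], v = vv[e];
        int64_t key = ((int64_t)std::min(u, v) << 32) | (int64_t)std::max(u, v);
        cnt[key] += 1;
        once[key] = std::make_pair(u, v);
      }
    }
    std::vector<std::pair<int,int> > horizon;
    for (std::unordered_map<int64_t, int>::iterator it = cnt.begin(); it != cnt.end(); ++it)
      if (it->second == 1) horizon.push_back(once[it->first]);
    // collect candidate points of visible faces, kill them
    std::vector<int> orphans;
    for (int t : visible) {
      Face& f = faces[t];
      for (int idx : f.outside) if (idx != p) orphans.push_back(idx);
      f.outside.clear();
      f.alive = false;
    }
    // cone of new faces over the horizon
    std::vector<int> fresh;
    for (size_t e = 0; e < horizon.size(); ++e) {
      Face f; f.a = horizon[e].first; f.b = horizon[e].second; f.c = p; f.alive = true;
      plane(X, Y, Z, f);
      faces.push_back(f);
      fresh.push_back((int)faces.size() - 1);
    }
    for (int idx : orphans) {
      for (int t : fresh) {
        if (sdist(faces[t], X[idx], Y[idx], Z[idx]) > eps) { faces[t].outside.push_back(idx); break; }
      }
    }
    // compact dead faces occasionally to keep scans cheap
    if (faces.size() > 64 && visible.size() * 4 > faces.size()) {
      std::vector<Face> keep;
      keep.reserve(faces.size());
      for (size_t t = 0; t < faces.size(); ++t) if (faces[t].alive) keep.push_back(faces[t]);
      faces.swap(keep);
    }
  }

  // volume (signed tetra sum about interior point) + faces out
  double vol6 = 0.0;
  int nf = 0;
  for (size_t t = 0; t < faces.size(); ++t) if (faces[t].alive) ++nf;
  IntegerMatrix Fout(nf, 3);
  std::vector<bool> used(n, false);
  int r = 0;
  for (size_t t = 0; t < faces.size(); ++t) {
    const Face& f = faces[t];
    if (!f.alive) continue;
    double ax = X[f.a]-ox, ay = Y[f.a]-oy, az = Z[f.a]-oz;
    double bx = X[f.b]-ox, by = Y[f.b]-oy, bz = Z[f.b]-oz;
    double cx = X[f.c]-ox, cy = Y[f.c]-oy, cz = Z[f.c]-oz;
    vol6 += ax*(by*cz - bz*cy) - ay*(bx*cz - bz*cx) + az*(bx*cy - by*cx);
    Fout(r, 0) = f.a + 1; Fout(r, 1) = f.b + 1; Fout(r, 2) = f.c + 1;
    used[f.a] = used[f.b] = used[f.c] = true;
    ++r;
  }
  int nhv = 0;
  for (int i = 0; i < n; ++i) if (used[i]) ++nhv;
  return List::create(_["volume"] = vol6 / 6.0,
                      _["faces"] = Fout,
                      _["n_hull_vertices"] = nhv);
}
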