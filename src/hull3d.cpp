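#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull, volume only. Points are processed one at a
// time against the current facet list; visible facets are replaced by a fan
// from the horizon to the new point. Facet count for realistic clouds stays
// small (O(log^2 n) for uniform samples), so the O(n * facets) scan is fast.

struct Facet {
  int a, b, c;          // vertex indices, outward-oriented
  double nx, ny, nz, d; // plane: n . x = d, n outward
  bool alive;
};

static inline void plane(const double* px, const double* py, const double* pz,
                         int a, int b, int c, double& nx, double& ny,
                         double& nz, double& d) {
  double ux = px[b] - px[a], uy = py[b] - py[a], uz = pz[b] - pz[a];
  double vx = px[c] - px[a], vy = py[c] - py[a], vz = pz[c] - pz[a];
  nx = uy * vz - uz * vy;
  ny = uz * vx - ux * vz;
  nz = ux * vy - uy * vx;
  d = nx * px[a] + ny * py[a] + nz * pz[a];
}

// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2); }
  const double* px = x.data();
  const double* py = y.data();
  const double* pz = z.data();

  // scale-aware tolerance
  double lo[3] = {x[0], y[0], z[0]}, hi[3] = {x[0], y[0], z[0]};
  for (int i = 1; i < n; ++i) {
    if (x[i] < lo[0]) lo[0] = x[i]; if (x[i] > hi[0]) hi[0] = x[i];
    if (y[i] < lo[1]) lo[1] = y[i]; if (y[i] > hi[1]) hi[1] = y[i];
    if (z[i] < lo[2]) lo[2] = z[i]; if (z[i] > hi[2]) hi[2] = z[i];
  }
  double diag = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) + (hi[1]-lo[1])*(hi[1]-lo[1]) +
                          (hi[2]-lo[2])*(hi[2]-lo[2]));
  if (diag <= 0) return 0.0;
  double eps = 1e-12 * diag * diag * diag + 1e-300;

  // initial tetrahedron: extreme point pair, then farthest from line, then from plane
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double dx = x[i]-x[0], dy = y[i]-y[0], dz = z[i]-z[0];
    double dd = dx*dx + dy*dy + dz*dz;
    if (dd > best) { best = dd; i1 = i; }
  }
  if (best <= 1e-24 * diag * diag) return 0.0;
  best = -1.0;
  double ax = x[i1]-x[i0], ay = y[i1]-y[i0], az = z[i1]-z[i0];
  for (int i = 0; i < n; ++i) {
    double bx = x[i]-x[i0], by = y[i]-y[i0], bz = z[i]-z[i0];
    double cx = ay*bz-az*by, cy = az*bx-ax*bz, cz = ax*by-ay*bx;
    double dd = cx*cx + cy*cy + cz*cz;
    if (dd > best) { best = dd; i2 = i; }
  }
  if (i2 < 0 || best <= eps * eps) return 0.0; // collinear
  double nx, ny, nz, d0;
  plane(px, py, pz, i0, i1, i2, nx, ny, nz, d0);
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    double dd = std::fabs(nx*x[i] + ny*y[i] + nz*z[i] - d0);
    if (dd > best) { best = dd; i3 = i; }
  }
  if (i3 < 0 || best <= eps) return 0.0; // coplanar

  // interior reference point
  double ox = (x[i0]+x[i1]+x[i2]+x[i3]) / 4.0;
  double oy = (y[i0]+y[i1]+y[i2]+y[i3]) / 4.0;
  double oz = (z[i0]+z[i1]+z[i2]+z[i3]) / 4.0;

  std::vector<Facet> facets;
  facets.reserve(256);
  int tet[4][3] = {{i0,i1,i2},{i0,i1,i3},{i0,i2,i3},{i1,i2,i3}};
  for (int f = 0; f < 4; ++f) {
    Facet fc; fc.a = tet[f][0]; fc.b = tet[f][1]; fc.c = tet[f][2]; fc.alive = true;
    plane(px, py, pz, fc.a, fc.b, fc.c, fc.nx, fc.ny, fc.nz, fc.d);
    if (fc.nx*ox + fc.ny*oy + fc.nz*oz > fc.d) { // flip outward
      std::swap(fc.b, fc.c);
      plane(px, py, pz, fc.a, fc.b, fc.c, fc.nx, fc.ny, fc.nz, fc.d);
    }
    facets.push_back(fc);
  }

  std::vector<int> visible;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    visible.clear();
    for (size_t f = 0; f < facets.size(); ++f) {
      if (!facets[f].alive) continue;
      if (facets[f].nx*x[i] + facets[f].ny*y[i] + facets[f].nz*z[i] - facets[f].d > eps)
        visible.push_back((int)f);
    }
    if (visible.empty()) continue; // inside (or on) the current hull

    // horizon = directed edges of visible facets whose reverse is not visible
    std::map<std::pair<int,int>, int> edges;
    for (size_t v = 0; v < visible.size(); ++v) {
      const Facet& fc = facets[visible[v]];
      int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (int k = 0; k < 3; ++k) edges[std::make_pair(e[k][0], e[k][1])] = 1;
    }
    for (size_t v = 0; v < visible.size(); ++v) facets[visible[v]].alive = false;
    for (std::map<std::pair<int,int>, int>::iterator it = edges.begin();
         it != edges.end(); ++it) {
      int u = it->first.first, w = it->first.second;
      if (edges.count(std::make_pair(w, u))) continue; // interior edge
      Facet fc; fc.a = u; fc.b = w; fc.c = i; fc.alive = true;
      plane(px, py, pz, fc.a, fc.b, fc.c, fc.nx, fc.ny, fc.nz, fc.d);
      if (fc.nx*ox + fc.ny*oy + fc.nz*oz > fc.d) {
        std::swap(fc.b, fc.c);
        plane(px, py, pz, fc.a, fc.b, fc.c, fc.nx, fc.ny, fc.nz, fc.d);
      }
      facets.push_back(fc);
    }
    // periodic compaction keeps the scan short
    if (facets.size() > 4096) {
      std::vector<Facet> keep;
      keep.reserve(facets.size());
      for (size_t f = 0; f < facets.size(); ++f)
        if (facets[f].alive) keep.push_back(facets[f]);
      facets.swap(keep);
    }
  }

  double vol = 0.0;
  for (size_t f = 0; f < facets.size(); ++f) {
    if (!facets[f].alive) continue;
    const Facet& fc = facets[f];
    double ux = x[fc.a]-ox, uy = y[fc.a]-oy, uz = z[fc.a]-oz;
    double vx = x[fc.b]-ox, vy = y[fc.b]-oy, vz = z[fc.b]-oz;
    double wx = x[fc.c]-ox, wy = y[fc.c]-oy, wz = z[fc.c]-oz;
    vol += ux*(vy*wz - vz*wy) - uy*(vx*wz - vz*wx) + uz*(vx*wy - vy*wx);
  }
  return vol / 6.0;
}
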