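// Low-level mesh geometry kernels: 3D convex hull, point-to-mesh distance,
// generalized winding number. Coordinates are in mm throughout.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <utility>

using namespace Rcpp;

namespace {

struct Facet {
  int a, b, c;
  double nx, ny, nz, off; // outward unit normal, plane offset (n . x = off)
  bool alive;
};

inline void facet_plane(const NumericMatrix &V, Facet &f,
                        double ix, double iy, double iz) {
  double ax = V(f.a, 0), ay = V(f.a, 1), az = V(f.a, 2);
  double ux = V(f.b, 0) - ax, uy = V(f.b, 1) - ay, uz = V(f.b, 2) - az;
  double vx = V(f.c, 0) - ax, vy = V(f.c, 1) - ay, vz = V(f.c, 2) - az;
  double nx = uy * vz - uz * vy;
  double ny = uz * vx - ux * vz;
  double nz = ux * vy - uy * vx;
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (nn > 0) { nx /= nn; ny /= nn; nz /= nn; }
  double off = nx * ax + ny * ay + nz * az;
  // orient away from the interior reference point
  if (nx * ix + ny * iy + nz * iz > off) {
    std::swap(f.b, f.c);
    nx = -nx; ny = -ny; nz = -nz; off = -off;
  }
  f.nx = nx; f.ny = ny; f.nz = nz; f.off = off;
}

inline double pdist(const NumericMatrix &V, const Facet &f, int p) {
  return f.nx * V(p, 0) + f.ny * V(p, 1) + f.nz * V(p, 2) - f.off;
}

} // namespace

// [[Rcpp::export(name = ".cpp_convex_hull")]]
List cpp_convex_hull(NumericMatrix V) {
  const int n = V.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");

  // scale-aware tolerance
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = V(0, d); hi[d] = V(0, d); }
  for (int i = 1; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (V(i, d) < lo[d]) lo[d] = V(i, d);
      if (V(i, d) > hi[d]) hi[d] = V(i, d);
    }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diag <= 0) stop("degenerate point set (zero extent)");
  const double eps = 1e-9 * diag;

  // initial simplex: two extreme points, farthest from line, farthest from plane
  int i0 = 0, i1 = 0;
  {
    double best = -1;
    for (int d = 0; d < 3; ++d) {
      int amin = 0, amax = 0;
      for (int i = 1; i < n; ++i) {
        if (V(i, d) < V(amin, d)) amin = i;
        if (V(i, d) > V(amax, d)) amax = i;
      }
      double ext = V(amax, d) - V(amin, d);
      if (ext > best) { best = ext; i0 = amin; i1 = amax; }
    }
  }
  double ex = V(i1, 0) - V(i0, 0), ey = V(i1, 1) - V(i0, 1), ez = V(i1, 2) - V(i0, 2);
  double el = std::sqrt(ex * ex + ey * ey + ez * ez);
  if (el < eps) stop("degenerate point set (all points coincide)");
  int i2 = -1;
  {
    double best = -1;
    for (int i = 0; i < n; ++i) {
      double wx = V(i, 0) - V(i0, 0), wy = V(i, 1) - V(i0, 1), wz = V(i, 2) - V(i0, 2);
      double cx = wy * ez - wz * ey, cy = wz * ex - wx * ez, cz = wx * ey - wy * ex;
      double d2 = cx * cx + cy * cy + cz * cz;
      if (d2 > best) { best = d2; i2 = i; }
    }
    if (std::sqrt(best) / el < eps) stop("degenerate point set (collinear)");
  }
  // plane through i0,i1,i2
  double ux = V(i2, 0) - V(i0, 0), uy = V(i2, 1) - V(i0, 1), uz = V(i2, 2) - V(i0, 2);
  double nx = ey * uz - ez * uy, ny = ez * ux - ex * uz, nz = ex * uy - ey * ux;
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  nx /= nn; ny /= nn; nz /= nn;
  double off0 = nx * V(i0, 0) + ny * V(i0, 1) + nz * V(i0, 2);
  int i3 = -1;
  {
    double best = -1;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(nx * V(i, 0) + ny * V(i, 1) + nz * V(i, 2) - off0);
      if (d > best) { best = d; i3 = i; }
    }
    if (best < eps) stop("degenerate point set (coplanar)");
  }

  double ix = (V(i0, 0) + V(i1, 0) + V(i2, 0) + V(i3, 0)) / 4.0;
  double iy = (V(i0, 1) + V(i1, 1) + V(i2, 1) + V(i3, 1)) / 4.0;
  double iz = (V(i0, 2) + V(i1, 2) + V(i2, 2) + V(i3, 2)) / 4.0;

  std::vector<Facet> facets;
  facets.reserve(512);
  int tri[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int k = 0; k < 4; ++k) {
    Facet f; f.a = tri[k][0]; f.b = tri[k][1]; f.c = tri[k][2]; f.alive = true;
    facet_plane(V, f, ix, iy, iz);
    facets.push_back(f);
  }

  std::vector<int> alive_idx;
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // visible facets
    std::vector<int> vis;
    for (size_t k = 0; k < facets.size(); ++k)
      if (facets[k].alive && pdist(V, facets[k], p) > eps) vis.push_back((int)k);
    if (vis.empty()) continue;
    // horizon edges: directed edges of visible facets whose reverse is not visible
    std::map<std::pair<int, int>, int> edge_count;
    for (int k : vis) {
      const Facet &f = facets[k];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j) {
        int u = e[j][0], v = e[j][1];
        std::pair<int, int> key = u < v ? std::make_pair(u, v) : std::make_pair(v, u);
        edge_count[key] += 1;
      }
    }
    for (int k : vis) facets[k].alive = false;
    for (std::map<std::pair<int, int>, int>::iterator it = edge_count.begin();
         it != edge_count.end(); ++it) {
      if (it->second != 1) continue; // interior edge of the visible patch
      Facet f; f.a = it->first.first; f.b = it->first.second; f.c = p; f.alive = true;
      facet_plane(V, f, ix, iy, iz);
      facets.push_back(f);
    }
  }

  int m = 0;
  for (size_t k = 0; k < facets.size(); ++k) if (facets[k].alive) ++m;
  IntegerMatrix F(m, 3);
  NumericMatrix N(m, 3);
  int r = 0;
  for (size_t k = 0; k < facets.size(); ++k) {
    if (!facets[k].alive) continue;
    F(r, 0) = facets[k].a + 1; F(r, 1) = facets[k].b + 1; F(r, 2) = facets[k].c + 1;
    N(r, 0) = facets[k].nx; N(r, 1) = facets[k].ny; N(r, 2) = facets[k].nz;
    ++r;
  }
  return List::create(_["faces"] = F, _["normals"] = N);
}

// closest point on triangle (Ericson, Real-Time Collision Detection)
static inline double tri_dist2(double px, double py, double pz,
                               double ax, double ay, double az,
                               double bx, double by, double bz,
                               double cx, double cy, double cz) {
  double abx = bx - ax, aby = by - ay, abz = bz - az;
  double acx = cx - ax, acy = cy - ay, acz = cz - az;
  double apx = px - ax, apy = py - ay, apz = pz - az;
  double d1 = abx * apx + aby * apy + abz * apz;
  double d2 = acx * apx + acy * apy + acz * apz;
  double qx, qy, qz;
  if (d1 <= 0 && d2 <= 0) { qx = ax; qy = ay; qz = az; goto done; }
  {
    double bpx = px - bx, bpy = py - by, bpz = pz - bz;
    double d3 = abx * bpx + aby * bpy + abz * bpz;
    double d4 = acx * bpx + acy * bpy + acz * bpz;
    if (d3 >= 0 && d4 <= d3) { qx = bx; qy = by; qz = bz; goto done; }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double v = d1 / (d1 - d3);
      qx = ax + v * abx; qy = ay + v * aby; qz = az + v * abz; goto done;
    }
    double cpx = px - cx, cpy = py - cy, cpz = pz - cz;
    double d5 = abx * cpx + aby * cpy + abz * cpz;
    double d6 = acx * cpx + acy * cpy + acz * cpz;
    if (d6 >= 0 && d5 <= d6) { qx = cx; qy = cy; qz = cz; goto done; }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double w = d2 / (d2 - d6);
      qx = ax + w * acx; qy = ay + w * acy; qz = az + w * acz; goto done;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      qx = bx + w * (cx - bx); qy = by + w * (cy - by); qz = bz + w * (cz - bz);
      goto done;
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    qx = ax + abx * v + acx * w;
    qy = ay + aby * v + acy * w;
    qz = az + abz * v + acz * w;
  }
done:
  double dx = px - qx, dy = py - qy, dz = pz - qz;
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export(name = ".cpp_point_mesh_distance")]]
NumericVector cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V,
                                      IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    double best = R_PosInf;
    for (int k = 0; k < nf; ++k) {
      int a = F(k, 0) - 1, b = F(k, 1) - 1, c = F(k, 2) - 1;
      double d2 = tri_dist2(px, py, pz,
                            V(a, 0), V(a, 1), V(a, 2),
                            V(b, 0), V(b, 1), V(b, 2),
                            V(c, 0), V(c, 1), V(c, 2));
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// generalized winding number (van Oosterom & Strackee solid angles)
// [[Rcpp::export(name = ".cpp_winding_number")]]
NumericVector cpp_winding_number(NumericMatrix P, NumericMatrix V,
                                 IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    double total = 0.0;
    for (int k = 0; k < nf; ++k) {
      int ia = F(k, 0) - 1, ib = F(k, 1) - 1, ic = F(k, 2) - 1;
      double ax = V(ia, 0) - px, ay = V(ia, 1) - py, az = V(ia, 2) - pz;
      double bx = V(ib, 0) - px, by = V(ib, 1) - py, bz = V(ib, 2) - pz;
      double cx = V(ic, 0) - px, cy = V(ic, 1) - py, cz = V(ic, 2) - pz;
      double la = std::sqrt(ax * ax + ay * ay + az * az);
      double lb = std::sqrt(bx * bx + by * by + bz * bz);
      double lc = std::sqrt(cx * cx + cy * cy + cz * cz);
      double num = ax * (by * cz - bz * cy) + ay * (bz * cx - bx * cz) +
                   az * (bx * cy - by * cx);
      double den = la * lb * lc + (ax * bx + ay * by + az * bz) * lc +
                   (bx * cx + by * cy + bz * cz) * la +
                   (cx * ax + cy * ay + cz * az) * lb;
      total += 2.0 * std::atan2(num, den);
    }
    out[i] = total / (4.0 * M_PI);
  }
  return out;
}
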