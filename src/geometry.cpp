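// Voxel/SDF kernels for lattice scaffold construction and measurement.
// All lengths in mm. Signed distance fields are exact for the cylinder
// primitives away from union creases, which is sufficient for the
// co-area (smoothed indicator) V/S estimators used by measure_geometry().
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

namespace {

struct Vec3 { double x, y, z; };

inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// distance from p to segment ab
inline double seg_dist(const Vec3& p, const Vec3& a, const Vec3& b) {
  double abx = b.x - a.x, aby = b.y - a.y, abz = b.z - a.z;
  double apx = p.x - a.x, apy = p.y - a.y, apz = p.z - a.z;
  double t = (apx * abx + apy * aby + apz * abz) /
             (abx * abx + aby * aby + abz * abz);
  t = clampd(t, 0.0, 1.0);
  double dx = apx - t * abx, dy = apy - t * aby, dz = apz - t * abz;
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Truncated octahedron edge set for a cell of width `pitch` across its
// square faces, centred at the origin.  Vertices are the permutations of
// (0, +/-1, +/-2) * pitch/4; the 36 edges have length pitch/(2 sqrt 2).
struct ToEdges {
  std::vector<Vec3> a, b;
  explicit ToEdges(double pitch) {
    double s = pitch / 4.0;
    std::vector<Vec3> v;
    int perm[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
    for (int pi = 0; pi < 6; ++pi)
      for (int s1 = -1; s1 <= 1; s1 += 2)
        for (int s2 = -1; s2 <= 1; s2 += 2) {
          double c[3]; double vals[3] = {0.0, s1 * 1.0, s2 * 2.0};
          for (int k = 0; k < 3; ++k) c[perm[pi][k]] = vals[k] * s;
          bool dup = false;
          for (auto& u : v)
            if (std::fabs(u.x - c[0]) + std::fabs(u.y - c[1]) +
                std::fabs(u.z - c[2]) < 1e-12 * pitch) { dup = true; break; }
          if (!dup) v.push_back({c[0], c[1], c[2]});
        }
    double elen = std::sqrt(2.0) * s, tol = 1e-9 * pitch;
    for (size_t i = 0; i < v.size(); ++i)
      for (size_t j = i + 1; j < v.size(); ++j) {
        double dx = v[i].x - v[j].x, dy = v[i].y - v[j].y, dz = v[i].z - v[j].z;
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (std::fabs(d - elen) < tol) { a.push_back(v[i]); b.push_back(v[j]); }
      }
  }
};

// SDF of the periodic cubic cross-link lattice: three orthogonal families
// of infinite cylinders of radius r with axes on a square grid of the given
// pitch, axes passing through coordinate `off` (same on all axes).
inline double sdf_cubic(double x, double y, double z,
                        double pitch, double r, double off, double offz) {
  double wx = x - off - pitch * std::floor((x - off) / pitch + 0.5);
  double wy = y - off - pitch * std::floor((y - off) / pitch + 0.5);
  double wz = z - offz - pitch * std::floor((z - offz) / pitch + 0.5);
  double dz = std::sqrt(wx * wx + wy * wy) - r; // axes along z
  double dx = std::sqrt(wy * wy + wz * wz) - r; // axes along x
  double dy = std::sqrt(wx * wx + wz * wz) - r; // axes along y
  return std::min(dz, std::min(dx, dy));
}

// SDF of the TO edge-strut honeycomb (bitruncated cubic): cell centres on a
// BCC lattice of cubic period `pitch`, struts of radius r along each cell's
// 36 edges (edges shared between neighbouring cells coincide).  `cx,cy,cz`
// is the lattice origin.  Only the two nearest candidate centres (corner
// sublattice and body-centre sublattice) matter near the surface.
inline double sdf_to(double x, double y, double z, const ToEdges& E,
                     double pitch, double r,
                     double cx, double cy, double cz) {
  double qx = x - cx, qy = y - cy, qz = z - cz;
  double best = 1e30;
  for (int s = 0; s < 2; ++s) {
    double sh = s ? 0.5 : 0.0;
    Vec3 p = {qx - pitch * (std::floor(qx / pitch - sh + 0.5) + sh),
              qy - pitch * (std::floor(qy / pitch - sh + 0.5) + sh),
              qz - pitch * (std::floor(qz / pitch - sh + 0.5) + sh)};
    for (size_t e = 0; e < E.a.size(); ++e) {
      double d = seg_dist(p, E.a[e], E.b[e]);
      if (d < best) best = d;
    }
  }
  return best - r;
}

// Finite capped cylinder along z, centred at (cx, cy, z0 + h/2).
inline double sdf_cylinder(double x, double y, double z,
                           double cx, double cy, double z0,
                           double r, double h) {
  double dr = std::sqrt((x - cx) * (x - cx) + (y - cy) * (y - cy)) - r;
  double dzl = std::fabs(z - (z0 + 0.5 * h)) - 0.5 * h;
  double outside = std::sqrt(std::pow(std::max(dr, 0.0), 2) +
                             std::pow(std::max(dzl, 0.0), 2));
  return outside + std::min(std::max(dr, dzl), 0.0);
}

struct SdfSpec {
  int design; // 0 cubic lattice, 1 TO strut lattice, 2 lone cylinder, 3 solid box
  double pitch, r, off, offz, cx, cy, cz, cylz0, cylh;
  double bx, by, bz; // bounding box extents (origin at 0)
  ToEdges* edges;
};

inline double sdf_lattice(const SdfSpec& S, double x, double y, double z) {
  switch (S.design) {
    case 0: return sdf_cubic(x, y, z, S.pitch, S.r, S.off, S.offz);
    case 1: return sdf_to(x, y, z, *S.edges, S.pitch, S.r, S.cx, S.cy, S.cz);
    case 2: return sdf_cylinder(x, y, z, S.cx, S.cy, S.cylz0, S.r, S.cylh);
    default: return -1.0; // solid box: clip supplies the boundary
  }
}

inline double sdf_box(const SdfSpec& S, double x, double y, double z) {
  double d = -x;
  d = std::max(d, x - S.bx);
  d = std::max(d, -y); d = std::max(d, y - S.by);
  d = std::max(d, -z); d = std::max(d, z - S.bz);
  return d;
}

SdfSpec parse_spec(const List& spec, ToEdges*& edges_out) {
  SdfSpec S;
  S.design = as<int>(spec["design_code"]);
  S.pitch  = spec.containsElementNamed("pitch") ? as<double>(spec["pitch"]) : 1.0;
  S.r      = spec.containsElementNamed("radius") ? as<double>(spec["radius"]) : 0.25;
  S.off    = spec.containsElementNamed("offset") ? as<double>(spec["offset"]) : 0.0;
  S.offz   = spec.containsElementNamed("offset_z") ? as<double>(spec["offset_z"]) : S.off;
  NumericVector bb = spec["bbox"];
  S.bx = bb[0]; S.by = bb[1]; S.bz = bb[2];
  S.cx = S.bx / 2.0; S.cy = S.by / 2.0; S.cz = S.bz / 2.0;
  if (spec.containsElementNamed("center")) {
    NumericVector cc = spec["center"];
    S.cx = cc[0]; S.cy = cc[1]; S.cz = cc[2];
  }
  S.cylz0 = spec.containsElementNamed("cyl_z0") ? as<double>(spec["cyl_z0"]) : 0.0;
  S.cylh  = spec.containsElementNamed("cyl_h") ? as<double>(spec["cyl_h"]) : S.bz;
  edges_out = (S.design == 1) ? new ToEdges(S.pitch) : nullptr;
  S.edges = edges_out;
  return S;
}

} // namespace

// Evaluate the clipped lattice SDF at arbitrary points (mm).
// [[Rcpp::export(name = ".cpp_sdf_eval")]]
NumericVector cpp_sdf_eval(List spec, NumericMatrix pts) {
  ToEdges* edges = nullptr;
  SdfSpec S = parse_spec(spec, edges);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    out[i] = std::max(sdf_lattice(S, x, y, z), sdf_box(S, x, y, z));
  }
  delete edges;
  return out;
}

// Voxelise the clipped lattice and measure V (smoothed Heaviside sum) and
// S (co-area / shell-volume estimator) in one slab-wise pass.
// include_clip: whether the flat faces created by the bounding-box cut
// count toward the surface area.
// [[Rcpp::export(name = ".cpp_voxelize_metrics")]]
List cpp_voxelize_metrics(List spec, double voxel, bool include_clip,
                          bool want_occupancy) {
  ToEdges* edges = nullptr;
  SdfSpec S = parse_spec(spec, edges);
  int nx = (int)std::lround(S.bx / voxel);
  int ny = (int)std::lround(S.by / voxel);
  int nz = (int)std::lround(S.bz / voxel);
  if (nx < 1 || ny < 1 || nz < 1) stop("voxel size larger than bounding box");
  double h = voxel, eps = voxel; // half-width of the smoothing band
  size_t plane = (size_t)nx * ny;
  // Accumulate over a 2-cell halo outside the box so that smoothing bands
  // of surfaces lying exactly on the bounding-box faces (clip faces, strut
  // cut ends) are integrated in full, not halved.
  const int HB = 2;
  int hx = nx + 2 * HB + 2, hy = ny + 2 * HB + 2; // +1 halo for differences
  std::vector<double> sl[3];
  for (int k = 0; k < 3; ++k) sl[k].assign((size_t)hx * hy, 0.0);
  RawVector occ(want_occupancy ? plane * (size_t)nz : 0);
  double V = 0.0, Ssurf = 0.0;
  size_t nsolid = 0;
  const int i0 = -HB - 1, i1 = nx + HB; // slice index range (inclusive)

  auto fill_slice = [&](std::vector<double>& buf, int kz) {
    double z = (kz + 0.5) * h;
    for (int j = i0; j <= ny + HB; ++j) {
      double y = (j + 0.5) * h;
      for (int i = i0; i <= nx + HB; ++i) {
        double x = (i + 0.5) * h;
        double d = sdf_lattice(S, x, y, z);
        if (include_clip) d = std::max(d, sdf_box(S, x, y, z));
        buf[(size_t)(j - i0) * hx + (i - i0)] = d;
      }
    }
  };

  fill_slice(sl[0], -HB - 1);
  fill_slice(sl[1], -HB);
  for (int k = -HB; k < nz + HB; ++k) {
    fill_slice(sl[2], k + 1);
    const std::vector<double>& zm = sl[0];
    const std::vector<double>& zc = sl[1];
    const std::vector<double>& zp = sl[2];
    for (int j = -HB; j < ny + HB; ++j) {
      for (int i = -HB; i < nx + HB; ++i) {
        size_t c = (size_t)(j - i0) * hx + (i - i0);
        double phi = zc[c];
        bool count = true;
        if (!include_clip) {
          double x = (i + 0.5) * h, y = (j + 0.5) * h, z = (k + 0.5) * h;
          count = sdf_box(S, x, y, z) <= 0.0;
        }
        if (count) {
          V += clampd(0.5 - phi / (2.0 * eps), 0.0, 1.0);
          // triangular mollified delta, support |phi| < 2*eps, unit integral
          double aphi = std::fabs(phi);
          if (aphi < 2.0 * eps) {
            double gx = (zc[c + 1] - zc[c - 1]) / (2.0 * h);
            double gy = (zc[c + hx] - zc[c - hx]) / (2.0 * h);
            double gz = (zp[c] - zm[c]) / (2.0 * h);
            double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
            Ssurf += gn * (1.0 - aphi / (2.0 * eps)) / (2.0 * eps);
          }
        }
        if (want_occupancy && i >= 0 && j >= 0 && k >= 0 &&
            i < nx && j < ny && k < nz) {
          bool solid = (phi < 0.0);
          occ[(size_t)k * plane + (size_t)j * nx + i] = solid ? 1 : 0;
          if (solid) ++nsolid;
        }
      }
    }
    sl[0].swap(sl[1]); sl[1].swap(sl[2]);
  }
  delete edges;
  double h3 = h * h * h;
  List out = List::create(
    _["V"] = V * h3, _["S"] = Ssurf * h3,
    _["dims"] = IntegerVector::create(nx, ny, nz),
    _["voxel"] = voxel, _["n_solid"] = (double)nsolid);
  if (want_occupancy) out["occupancy"] = occ;
  return out;
}

// Exact boundary mesh of a voxel occupancy grid: two triangles per exposed
// face, vertices deduplicated, outward orientation.  Returns 1-based faces.
// [[Rcpp::export(name = ".cpp_voxel_mesh")]]
List cpp_voxel_mesh(RawVector occ, IntegerVector dims, double voxel,
                    NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t plane = (size_t)nx * ny;
  auto solid = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return occ[(size_t)k * plane + (size_t)j * nx + i] != 0;
  };
  std::unordered_map<long long, int> vid;
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;
  auto vert = [&](int i, int j, int k) -> int {
    long long key = ((long long)k * (ny + 1) + j) * (nx + 1) + i;
    auto it = vid.find(key);
    if (it != vid.end()) return it->second;
    int id = (int)vx.size();
    vid[key] = id;
    vx.push_back(origin[0] + i * voxel);
    vy.push_back(origin[1] + j * voxel);
    vz.push_back(origin[2] + k * voxel);
    return id;
  };
  auto quad = [&](int a, int b, int c, int d) {
    f1.push_back(a + 1); f2.push_back(b + 1); f3.push_back(c + 1);
    f1.push_back(a + 1); f2.push_back(c + 1); f3.push_back(d + 1);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!solid(i, j, k)) continue;
        if (!solid(i - 1, j, k)) // -x face, outward normal -x
          quad(vert(i, j, k), vert(i, j, k + 1), vert(i, j + 1, k + 1),
               vert(i, j + 1, k));
        if (!solid(i + 1, j, k)) // +x
          quad(vert(i + 1, j, k), vert(i + 1, j + 1, k),
               vert(i + 1, j + 1, k + 1), vert(i + 1, j, k + 1));
        if (!solid(i, j - 1, k)) // -y
          quad(vert(i, j, k), vert(i + 1, j, k), vert(i + 1, j, k + 1),
               vert(i, j, k + 1));
        if (!solid(i, j + 1, k)) // +y
          quad(vert(i, j + 1, k), vert(i, j + 1, k + 1),
               vert(i + 1, j + 1, k + 1), vert(i + 1, j + 1, k));
        if (!solid(i, j, k - 1)) // -z
          quad(vert(i, j, k), vert(i, j + 1, k), vert(i + 1, j + 1, k),
               vert(i + 1, j, k));
        if (!solid(i, j, k + 1)) // +z
          quad(vert(i, j, k + 1), vert(i + 1, j, k + 1),
               vert(i + 1, j + 1, k + 1), vert(i, j + 1, k + 1));
      }
  int nv = (int)vx.size(), nf = (int)f1.size();
  NumericMatrix Vm(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nv; ++i) { Vm(i,0)=vx[i]; Vm(i,1)=vy[i]; Vm(i,2)=vz[i]; }
  for (int i = 0; i < nf; ++i) { Fm(i,0)=f1[i]; Fm(i,1)=f2[i]; Fm(i,2)=f3[i]; }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// Signed volume (tetrahedron sum) and total area of a triangle mesh.
// [[Rcpp::export(name = ".cpp_mesh_measure")]]
List cpp_mesh_measure(NumericMatrix V, IntegerMatrix F) {
  double vol = 0.0, area = 0.0;
  for (int t = 0; t < F.nrow(); ++t) {
    int a = F(t,0) - 1, b = F(t,1) - 1, c = F(t,2) - 1;
    double ax=V(a,0), ay=V(a,1), az=V(a,2);
    double bx=V(b,0), by=V(b,1), bz=V(b,2);
    double cx=V(c,0), cy=V(c,1), cz=V(c,2);
    vol += (ax*(by*cz - bz*cy) - ay*(bx*cz - bz*cx) + az*(bx*cy - by*cx)) / 6.0;
    double ux=bx-ax, uy=by-ay, uz=bz-az, wx=cx-ax, wy=cy-ay, wz=cz-az;
    double nxv=uy*wz-uz*wy, nyv=uz*wx-ux*wz, nzv=ux*wy-uy*wx;
    area += 0.5 * std::sqrt(nxv*nxv + nyv*nyv + nzv*nzv);
  }
  return List::create(_["volume"] = vol, _["area"] = area);
}

// Watertightness: every directed edge must be matched by exactly one
// opposite directed edge (closed, consistently oriented 2-manifold).
// [[Rcpp::export(name = ".cpp_mesh_watertight")]]
bool cpp_mesh_watertight(IntegerMatrix F, int nvert) {
  std::unordered_map<long long, long> cnt;
  auto key = [&](int a, int b) {
    return (long long)a * (nvert + 1) + b;
  };
  for (int t = 0; t < F.nrow(); ++t) {
    int v[3] = {F(t,0), F(t,1), F(t,2)};
    for (int e = 0; e < 3; ++e) {
      cnt[key(v[e], v[(e+1)%3])] += 1;
    }
  }
  for (auto& kv : cnt) {
    long long k = kv.first;
    int a = (int)(k / (nvert + 1)), b = (int)(k % (nvert + 1));
    if (kv.second != 1) return false;
    auto it = cnt.find(key(b, a));
    if (it == cnt.end() || it->second != 1) return false;
  }
  return true;
}
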