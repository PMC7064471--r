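// Lagrangian cell tracking with wall impingement.
// Each suspended particle is relaxed toward the sampled fluid velocity with
// an exact exponential integrator for the linear drag term (stable for
// dt >> tau_r), then advected along its velocity with continuous collision
// detection: ray-voxel (DDA) traversal against the fine scaffold occupancy
// grid and analytic reflection at the well cylinder/bottom/top.
// Scaffold hits are classified by the impact-energy regime model
// (stick / rebound / spread / splash) with a per-surface-voxel wall film.
// SI units.  Status codes: 0 suspended, 1 attached (stick), 2 attached
// (spread), 3 dead attached, 4 fragment (moving).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

typedef std::unordered_map<long long, double> FilmMap;

namespace {

inline double trilin(const double* q, int qnx, int qny, int qnz,
                     double hx, double hy, double hz,
                     double ox, double oy, double oz,
                     double x, double y, double z) {
  double fi = (x - ox) / hx, fj = (y - oy) / hy, fk = (z - oz) / hz;
  int i = (int)std::floor(fi), j = (int)std::floor(fj), k = (int)std::floor(fk);
  double tx = fi - i, ty = fj - j, tz = fk - k;
  if (i < 0) { i = 0; tx = 0; } if (i > qnx - 2) { i = qnx - 2; tx = 1; }
  if (j < 0) { j = 0; ty = 0; } if (j > qny - 2) { j = qny - 2; ty = 1; }
  if (k < 0) { k = 0; tz = 0; } if (k > qnz - 2) { k = qnz - 2; tz = 1; }
  auto at = [&](int a, int b, int c) {
    return q[(size_t)a + (size_t)qnx * (b + (size_t)qny * c)];
  };
  double c00 = at(i,j,k)*(1-tx) + at(i+1,j,k)*tx;
  double c10 = at(i,j+1,k)*(1-tx) + at(i+1,j+1,k)*tx;
  double c01 = at(i,j,k+1)*(1-tx) + at(i+1,j,k+1)*tx;
  double c11 = at(i,j+1,k+1)*(1-tx) + at(i+1,j+1,k+1)*tx;
  double c0 = c00*(1-ty) + c10*ty, c1 = c01*(1-ty) + c11*ty;
  return c0*(1-tz) + c1*tz;
}

// Morsi & Alexander smooth-sphere drag bands (a1, a2, a3) with the Stokes
// band (0, 24, 0) below Re = 0.1.
inline void drag_bands(double Re, double& a1, double& a2, double& a3) {
  if (Re < 0.1)        { a1 = 0.0;    a2 = 24.0;    a3 = 0.0; }
  else if (Re < 1.0)   { a1 = 3.690;  a2 = 22.73;   a3 = 0.0903; }
  else if (Re < 10.0)  { a1 = 1.222;  a2 = 29.1667; a3 = -3.8889; }
  else if (Re < 100.0) { a1 = 0.6167; a2 = 46.50;   a3 = -116.67; }
  else if (Re < 1000.0){ a1 = 0.3644; a2 = 98.33;   a3 = -2778.0; }
  else                 { a1 = 0.357;  a2 = 148.62;  a3 = -47500.0; }
}

struct OccGrid {
  const unsigned char* occ;
  int nx, ny, nz;
  double vox, ox, oy, oz;
  inline bool solid(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return occ[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] != 0;
  }
  inline long long lin(int i, int j, int k) const {
    return (long long)i + (long long)nx * (j + (long long)ny * k);
  }
};

// First crossing of segment p -> p + v*tmax into a solid voxel.
// Returns time of hit (in [0, tmax]) or -1; fills voxel ijk and the axis/sign
// of the crossed face (normal points out of the solid, against travel).
double dda_hit(const OccGrid& G, const double p[3], const double v[3],
               double tmax, int out_ijk[3], int& axis, int& sgn) {
  // clip segment to grid bounding box
  double t0 = 0.0, t1 = tmax;
  double lo[3] = {G.ox, G.oy, G.oz};
  double hi[3] = {G.ox + G.nx * G.vox, G.oy + G.ny * G.vox,
                  G.oz + G.nz * G.vox};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(v[a]) < 1e-300) {
      if (p[a] <= lo[a] || p[a] >= hi[a]) return -1.0;
    } else {
      double ta = (lo[a] - p[a]) / v[a], tb = (hi[a] - p[a]) / v[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    }
  }
  if (t0 >= t1) return -1.0;
  double eps = 1e-12 * G.vox;
  double start[3] = {p[0] + v[0] * (t0 + eps), p[1] + v[1] * (t0 + eps),
                     p[2] + v[2] * (t0 + eps)};
  int ijk[3];
  ijk[0] = (int)std::floor((start[0] - G.ox) / G.vox);
  ijk[1] = (int)std::floor((start[1] - G.oy) / G.vox);
  ijk[2] = (int)std::floor((start[2] - G.oz) / G.vox);
  for (int a = 0; a < 3; ++a) {
    if (ijk[a] < 0) ijk[a] = 0;
    if (a == 0 && ijk[a] >= G.nx) ijk[a] = G.nx - 1;
    if (a == 1 && ijk[a] >= G.ny) ijk[a] = G.ny - 1;
    if (a == 2 && ijk[a] >= G.nz) ijk[a] = G.nz - 1;
  }
  if (G.solid(ijk[0], ijk[1], ijk[2])) {
    // segment starts inside solid (numerical slip-through): immediate hit
    out_ijk[0] = ijk[0]; out_ijk[1] = ijk[1]; out_ijk[2] = ijk[2];
    axis = 0; sgn = v[0] >= 0 ? 1 : -1;
    return t0;
  }
  int step[3]; double tMax[3], tDelta[3];
  double orig[3] = {G.ox, G.oy, G.oz};
  for (int a = 0; a < 3; ++a) {
    if (v[a] > 0) {
      step[a] = 1;
      double bnd = orig[a] + (ijk[a] + 1) * G.vox;
      tMax[a] = (bnd - p[a]) / v[a];
      tDelta[a] = G.vox / v[a];
    } else if (v[a] < 0) {
      step[a] = -1;
      double bnd = orig[a] + ijk[a] * G.vox;
      tMax[a] = (bnd - p[a]) / v[a];
      tDelta[a] = -G.vox / v[a];
    } else {
      step[a] = 0; tMax[a] = 1e300; tDelta[a] = 1e300;
    }
  }
  while (true) {
    int a = 0;
    if (tMax[1] < tMax[a]) a = 1;
    if (tMax[2] < tMax[a]) a = 2;
    double tc = tMax[a];
    if (tc > t1) return -1.0;
    ijk[a] += step[a];
    if (ijk[0] < 0 || ijk[1] < 0 || ijk[2] < 0 ||
        ijk[0] >= G.nx || ijk[1] >= G.ny || ijk[2] >= G.nz) return -1.0;
    if (G.solid(ijk[0], ijk[1], ijk[2])) {
      out_ijk[0] = ijk[0]; out_ijk[1] = ijk[1]; out_ijk[2] = ijk[2];
      axis = a; sgn = step[a];
      return tc;
    }
    tMax[a] += tDelta[a];
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_film_new")]]
SEXP cpp_film_new() {
  XPtr<FilmMap> p(new FilmMap(), true);
  return p;
}

// [[Rcpp::export(name = ".cpp_film_lookup")]]
NumericVector cpp_film_lookup(SEXP filmp, NumericVector elems) {
  XPtr<FilmMap> fm(filmp);
  NumericVector out(elems.size());
  for (int i = 0; i < elems.size(); ++i) {
    auto it = fm->find((long long)elems[i]);
    out[i] = it == fm->end() ? 0.0 : it->second;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_film_total")]]
double cpp_film_total(SEXP filmp) {
  XPtr<FilmMap> fm(filmp);
  double s = 0.0;
  for (auto& kv : *fm) s += kv.second;
  return s;
}

// [[Rcpp::export(name = ".cpp_particles_step")]]
List cpp_particles_step(NumericVector x, NumericVector y, NumericVector z,
                        NumericVector vx, NumericVector vy, NumericVector vz,
                        IntegerVector status, NumericVector diam,
                        NumericVector ux, NumericVector uy, NumericVector uz,
                        NumericVector uplife,
                        NumericVector fu, NumericVector fv, NumericVector fw,
                        NumericVector falpha,
                        IntegerVector fdims, NumericVector fspacing,
                        RawVector occ, IntegerVector odims, double ovoxel,
                        NumericVector oorigin,
                        SEXP filmp, List params, double tnow, double dt) {
  int n = x.size();
  int nxf = fdims[0], nyf = fdims[1], nzf = fdims[2];
  double hx = fspacing[0], hy = fspacing[1], hz = fspacing[2];
  OccGrid G;
  G.occ = RAW(occ);
  G.nx = odims[0]; G.ny = odims[1]; G.nz = odims[2];
  G.vox = ovoxel; G.ox = oorigin[0]; G.oy = oorigin[1]; G.oz = oorigin[2];
  XPtr<FilmMap> film(filmp);

  const double rho_f = params["rho_fluid"], mu_f = params["mu"];
  const double rho_c = params["rho_cell"], sigma = params["sigma"];
  const double grav = params["g"];
  const double e_stick = params["e_stick"], e_splash = params["e_splash"];
  const double Twall = params["T_wall"], Tc = params["T_c"];
  const double en = params["restitution_n"], et = params["restitution_t"];
  const int nfrag = params["n_splash_fragments"];
  const double drw_rms = params["drw_rms"], drw_life = params["drw_life"];
  const double prewet = params["prewet_h"];
  const double Rw = params["well_radius"], wcx = params["well_cx"],
               wcy = params["well_cy"], wH = params["well_depth"];
  const bool eq9_literal = as<bool>(params["eq9_literal"]);
  const double frag_speed = params["frag_speed_factor"];

  std::vector<double> ev_t, ev_E, ev_vpn;
  std::vector<int> ev_id, ev_regime; std::vector<double> ev_elem;
  std::vector<double> fx_, fy_, fz_, fvx_, fvy_, fvz_, fd_;

  const double* FU = REAL(fu); const double* FV = REAL(fv);
  const double* FW = REAL(fw); const double* FA = REAL(falpha);

  auto sample_u = [&](double px, double py, double pz, double out[3]) {
    out[0] = trilin(FU, nxf+1, nyf, nzf, hx, hy, hz, 0.0, 0.5*hy, 0.5*hz, px, py, pz);
    out[1] = trilin(FV, nxf, nyf+1, nzf, hx, hy, hz, 0.5*hx, 0.0, 0.5*hz, px, py, pz);
    out[2] = trilin(FW, nxf, nyf, nzf+1, hx, hy, hz, 0.5*hx, 0.5*hy, 0.0, px, py, pz);
  };
  auto alpha_at = [&](double px, double py, double pz) {
    return trilin(FA, nxf, nyf, nzf, hx, hy, hz, 0.5*hx, 0.5*hy, 0.5*hz,
                  px, py, pz);
  };

  for (int m = 0; m < n; ++m) {
    if (status[m] != 0 && status[m] != 4) continue;
    double d = diam[m];
    double uf[3];
    sample_u(x[m], y[m], z[m], uf);
    // slip Reynolds number and relaxation time
    double sl[3] = {vx[m]-uf[0], vy[m]-uf[1], vz[m]-uf[2]};
    double slip = std::sqrt(sl[0]*sl[0] + sl[1]*sl[1] + sl[2]*sl[2]);
    double Re = rho_f * slip * d / mu_f;
    double tau;
    if (Re < 0.1) tau = rho_c * d * d / (18.0 * mu_f);
    else {
      double a1, a2, a3; drag_bands(Re, a1, a2, a3);
      double CD = a1 + a2 / Re + a3 / (Re * Re);
      tau = 4.0 * rho_c * d * d / (3.0 * mu_f * CD * Re);
    }
    double ef = std::exp(-dt / tau);
    double gfac = grav * (rho_c - rho_f) / rho_c; // settles if denser
    double gterm = -gfac * tau * (1.0 - ef);      // z is up
    double nvx = uf[0] + sl[0] * ef;
    double nvy = uf[1] + sl[1] * ef;
    double nvz = uf[2] + sl[2] * ef + gterm;
    // discrete random walk eddy kick
    if (drw_rms > 0.0) {
      if (uplife[m] <= 0.0) {
        ux[m] = drw_rms * R::norm_rand();
        uy[m] = drw_rms * R::norm_rand();
        uz[m] = drw_rms * R::norm_rand();
        uplife[m] = drw_life;
      }
      uplife[m] -= dt;
      nvx += ux[m]; nvy += uy[m]; nvz += uz[m];
    }
    vx[m] = nvx; vy[m] = nvy; vz[m] = nvz;

    double remaining = dt;
    double pp[3] = {x[m], y[m], z[m]};
    double vv[3] = {nvx, nvy, nvz};
    for (int bounce = 0; bounce < 16 && remaining > 0; ++bounce) {
      double speed = std::sqrt(vv[0]*vv[0] + vv[1]*vv[1] + vv[2]*vv[2]);
      if (speed * remaining < 1e-15) break;
      // earliest event among scaffold hit, cylinder wall, bottom, top
      int hijk[3], haxis = 0, hsgn = 1;
      double t_scaf = dda_hit(G, pp, vv, remaining, hijk, haxis, hsgn);
      double t_wall = 1e300; int wall_kind = -1; // 0 cyl, 1 bottom, 2 top
      // cylinder |p_xy + t v_xy - c| = Rw
      {
        double rx = pp[0]-wcx, ry = pp[1]-wcy;
        double a = vv[0]*vv[0] + vv[1]*vv[1];
        if (a > 0) {
          double b = 2.0*(rx*vv[0] + ry*vv[1]);
          double cq = rx*rx + ry*ry - Rw*Rw;
          double disc = b*b - 4*a*cq;
          if (disc >= 0) {
            double tq = (-b + std::sqrt(disc)) / (2*a); // outward root
            if (tq > 1e-14 && tq < t_wall) { t_wall = tq; wall_kind = 0; }
          }
        }
        if (vv[2] < 0) {
          double tq = (0.0 - pp[2]) / vv[2];
          if (tq > 1e-14 && tq < t_wall) { t_wall = tq; wall_kind = 1; }
        } else if (vv[2] > 0) {
          double tq = (wH - pp[2]) / vv[2];
          if (tq > 1e-14 && tq < t_wall) { t_wall = tq; wall_kind = 2; }
        }
      }
      bool scaf_first = (t_scaf >= 0) &&
                        (t_scaf <= remaining) &&
                        (t_scaf < t_wall);
      if (scaf_first) {
        // impingement on scaffold surface
        double tc = t_scaf;
        double hit[3] = {pp[0]+vv[0]*tc, pp[1]+vv[1]*tc, pp[2]+vv[2]*tc};
        double nrm[3] = {0,0,0};
        nrm[haxis] = -(double)hsgn; // outward from solid, against travel
        double vpn = -(vv[0]*nrm[0] + vv[1]*nrm[1] + vv[2]*nrm[2]);
        if (vpn < 0) vpn = 0;
        long long elem = G.lin(hijk[0], hijk[1], hijk[2]);
        double h_o = 0.0;
        if (alpha_at(hit[0], hit[1], hit[2]) > 0.5) h_o = prewet;
        auto it = film->find(elem);
        if (it != film->end()) h_o += it->second;
        double E = 0.0;
        if (vpn > 0) {
          double Rei = rho_f * vpn * d / mu_f;
          double dbl = d / std::sqrt(Rei);
          double base = rho_f * vpn * vpn * d / sigma;
          double hmin = std::min(h_o / d, 1.0);
          double E2;
          if (eq9_literal) {
            double inv = hmin > 1e-12 ? 1.0 / hmin : 1e12;
            E2 = base * (inv + dbl / d);
          } else {
            double br = hmin + dbl / d;
            E2 = br > 0 ? base / br : 0.0;
          }
          E = std::sqrt(std::max(E2, 0.0));
        }
        int regime; // 0 stick, 1 rebound, 2 spread, 3 splash
        if (Twall > Tc && E < e_splash) regime = 1;
        else if (E < e_stick) regime = 0;
        else if (E <= e_splash) regime = 2;
        else regime = 3;
        ev_t.push_back(tnow + (dt - remaining) + tc);
        ev_id.push_back(m + 1);
        ev_E.push_back(E);
        ev_vpn.push_back(vpn);
        ev_regime.push_back(regime);
        ev_elem.push_back((double)elem);
        double off = 1e-3 * G.vox;
        double rest[3] = {hit[0]+nrm[0]*off, hit[1]+nrm[1]*off,
                          hit[2]+nrm[2]*off};
        if (status[m] == 4) {
          // fragments deposit as dead matter on first scaffold contact
          status[m] = 3;
          pp[0]=rest[0]; pp[1]=rest[1]; pp[2]=rest[2];
          vv[0]=vv[1]=vv[2]=0; remaining = 0;
        } else if (regime == 0) {
          status[m] = 1;
          pp[0]=rest[0]; pp[1]=rest[1]; pp[2]=rest[2];
          vv[0]=vv[1]=vv[2]=0; remaining = 0;
        } else if (regime == 2) {
          status[m] = 2;
          (*film)[elem] += (M_PI / 6.0) * d * d * d / (G.vox * G.vox);
          pp[0]=rest[0]; pp[1]=rest[1]; pp[2]=rest[2];
          vv[0]=vv[1]=vv[2]=0; remaining = 0;
        } else if (regime == 1) {
          // rebound: decompose and reflect
          double vn = vv[0]*nrm[0] + vv[1]*nrm[1] + vv[2]*nrm[2];
          double vt[3] = {vv[0]-vn*nrm[0], vv[1]-vn*nrm[1], vv[2]-vn*nrm[2]};
          vv[0] = et*vt[0] - en*vn*nrm[0];
          vv[1] = et*vt[1] - en*vn*nrm[1];
          vv[2] = et*vt[2] - en*vn*nrm[2];
          pp[0]=rest[0]; pp[1]=rest[1]; pp[2]=rest[2];
          remaining -= tc;
        } else {
          // splash: the cell breaks into nfrag equal drops; one stays on
          // the wall as dead matter (the parent record, diameter reduced),
          // the other nfrag-1 fly off as fragments.  Mass is conserved.
          status[m] = 3;
          double df = d / std::cbrt((double)nfrag);
          diam[m] = df;
          for (int f = 0; f < nfrag - 1; ++f) {
            double th = std::acos(std::sqrt(R::unif_rand())); // cos-weighted
            double ph = 2.0 * M_PI * R::unif_rand();
            // hemisphere around outward normal
            double t1[3], t2[3];
            if (std::fabs(nrm[0]) < 0.9) { t1[0]=0; t1[1]=-nrm[2]; t1[2]=nrm[1]; }
            else { t1[0]=-nrm[1]; t1[1]=nrm[0]; t1[2]=0; }
            double tn = std::sqrt(t1[0]*t1[0]+t1[1]*t1[1]+t1[2]*t1[2]);
            t1[0]/=tn; t1[1]/=tn; t1[2]/=tn;
            t2[0] = nrm[1]*t1[2]-nrm[2]*t1[1];
            t2[1] = nrm[2]*t1[0]-nrm[0]*t1[2];
            t2[2] = nrm[0]*t1[1]-nrm[1]*t1[0];
            double dir[3];
            for (int a = 0; a < 3; ++a)
              dir[a] = std::cos(th)*nrm[a] +
                       std::sin(th)*(std::cos(ph)*t1[a] + std::sin(ph)*t2[a]);
            fx_.push_back(rest[0]); fy_.push_back(rest[1]); fz_.push_back(rest[2]);
            fvx_.push_back(frag_speed*speed*dir[0]);
            fvy_.push_back(frag_speed*speed*dir[1]);
            fvz_.push_back(frag_speed*speed*dir[2]);
            fd_.push_back(df);
          }
          pp[0]=rest[0]; pp[1]=rest[1]; pp[2]=rest[2];
          vv[0]=vv[1]=vv[2]=0; remaining = 0;
        }
      } else if (wall_kind >= 0 && t_wall <= remaining) {
        // specular reflection at well boundary (restitution 1, no trapping)
        double tc = t_wall;
        pp[0]+=vv[0]*tc; pp[1]+=vv[1]*tc; pp[2]+=vv[2]*tc;
        remaining -= tc;
        if (wall_kind == 0) {
          double nxr = (pp[0]-wcx), nyr = (pp[1]-wcy);
          double nn = std::sqrt(nxr*nxr + nyr*nyr);
          nxr /= nn; nyr /= nn; // outward radial
          double vn = vv[0]*nxr + vv[1]*nyr;
          vv[0] -= 2.0*vn*nxr; vv[1] -= 2.0*vn*nyr;
          // nudge inward to avoid re-detection
          pp[0] -= 1e-9*nxr; pp[1] -= 1e-9*nyr;
        } else if (wall_kind == 1) {
          vv[2] = -vv[2]; pp[2] = 1e-9;
        } else {
          vv[2] = -vv[2]; pp[2] = wH - 1e-9;
        }
      } else {
        pp[0]+=vv[0]*remaining; pp[1]+=vv[1]*remaining; pp[2]+=vv[2]*remaining;
        remaining = 0;
      }
    }
    x[m]=pp[0]; y[m]=pp[1]; z[m]=pp[2];
    vx[m]=vv[0]; vy[m]=vv[1]; vz[m]=vv[2];
  }
  return List::create(
    _["event_t"] = wrap(ev_t), _["event_id"] = wrap(ev_id),
    _["event_E"] = wrap(ev_E), _["event_vpn"] = wrap(ev_vpn),
    _["event_regime"] = wrap(ev_regime), _["event_elem"] = wrap(ev_elem),
    _["frag_x"] = wrap(fx_), _["frag_y"] = wrap(fy_), _["frag_z"] = wrap(fz_),
    _["frag_vx"] = wrap(fvx_), _["frag_vy"] = wrap(fvy_),
    _["frag_vz"] = wrap(fvz_), _["frag_d"] = wrap(fd_));
}

// Parity-count voxelization of a triangle mesh (x-ray casting per row).
// Used by import_mesh() to rebuild an occupancy grid.  Lengths in mm.
// [[Rcpp::export(name = ".cpp_voxelize_mesh")]]
RawVector cpp_voxelize_mesh(NumericMatrix V, IntegerMatrix F,
                            NumericVector bbox, double voxel) {
  int nx = (int)std::lround(bbox[0] / voxel);
  int ny = (int)std::lround(bbox[1] / voxel);
  int nz = (int)std::lround(bbox[2] / voxel);
  RawVector occ((size_t)nx * ny * nz);
  int nf = F.nrow();
  // tiny jitter avoids rays hitting triangle edges of axis-aligned meshes
  const double jy = 0.254e-3 * voxel, jz = 0.731e-3 * voxel;
  std::vector<double> xs;
  for (int k = 0; k < nz; ++k) {
    double zr = (k + 0.5) * voxel + jz;
    for (int j = 0; j < ny; ++j) {
      double yr = (j + 0.5) * voxel + jy;
      xs.clear();
      for (int t = 0; t < nf; ++t) {
        int a = F(t,0)-1, b = F(t,1)-1, c = F(t,2)-1;
        double y0=V(a,1), y1=V(b,1), y2=V(c,1);
        double z0=V(a,2), z1=V(b,2), z2=V(c,2);
        // 2D point-in-triangle in (y,z)
        double d00y = y1-y0, d00z = z1-z0, d01y = y2-y0, d01z = z2-z0;
        double det = d00y*d01z - d00z*d01y;
        if (std::fabs(det) < 1e-300) continue;
        double py = yr-y0, pz = zr-z0;
        double l1 = (py*d01z - pz*d01y) / det;
        double l2 = (d00y*pz - d00z*py) / det;
        if (l1 < 0 || l2 < 0 || l1 + l2 > 1) continue;
        double xhit = V(a,0) + l1*(V(b,0)-V(a,0)) + l2*(V(c,0)-V(a,0));
        xs.push_back(xhit);
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      for (size_t m = 0; m + 1 < xs.size(); m += 2) {
        int i0 = (int)std::ceil(xs[m] / voxel - 0.5);
        int i1 = (int)std::floor(xs[m+1] / voxel - 0.5);
        for (int i = std::max(0, i0); i <= std::min(nx-1, i1); ++i)
          occ[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = 1;
      }
    }
  }
  return occ;
}
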