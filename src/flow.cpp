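// Staggered-grid (MAC) incompressible flow kernel with a liquid
// volume-fraction field, used as the desk-scale filling solver.
// SI units (m, s, kg).  Arrays are R arrays modified in place:
//   u (nx+1, ny, nz), v (nx, ny+1, nz), w (nx, ny, nz+1),
//   p, alpha, drag (nx, ny, nz), flag (int; 0 fluid, 1 solid).
// Scheme: first-order upwind advection with automatic CFL sub-stepping,
// explicit viscosity, gravity weighted by the liquid fraction, implicit
// isotropic Darcy drag, then a pressure projection (matrix-free CG with a
// geometric multigrid preconditioner) enforcing the divergence constraint.
// The top boundary (k = nz-1 upper faces) is open at reference pressure 0
// so displaced air can leave the well while liquid is injected.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  double hx, hy, hz;
  inline size_t idc(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  }
  inline size_t idu(int i, int j, int k) const {
    return (size_t)i + (size_t)(nx + 1) * (j + (size_t)ny * k);
  }
  inline size_t idv(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * (j + (size_t)(ny + 1) * k);
  }
  // w faces use idw = i + nx*(j + ny*k) with k in 0..nz (same plane stride)
};

inline bool fluid_at(const int* flag, const Grid& g, int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= g.nx || j >= g.ny || k >= g.nz)
    return false;
  return flag[g.idc(i, j, k)] == 0;
}

// ---- geometric multigrid for the variable-coefficient Poisson problem ----
// Per level: face openness fractions (0..1) on the +x/+y/+z faces of each
// cell, an extra diagonal term for the Dirichlet ghost above top-layer
// cells, and a fluid mask.  Operator:
//   (A x)_c = diag_c x_c - sum_faces coef_f x_nb,
// with coef_f = openness / h_axis^2 and diag the sum of face coefs plus
// the top Dirichlet term.  Smoother: red-black Gauss-Seidel (symmetric
// ordering), restriction: 8-child average, prolongation: injection.
struct MgLevel {
  int nx, ny, nz;
  double hx, hy, hz;
  std::vector<double> ox, oy, oz;   // face openness (cell -> +axis nbr)
  std::vector<double> dtop;         // top Dirichlet openness
  std::vector<char> fluid;
  std::vector<double> diag, x, b, r;
  inline size_t id(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  }
  void finalize_diag() {
    double ix2 = 1.0/(hx*hx), iy2 = 1.0/(hy*hy), iz2 = 1.0/(hz*hz);
    diag.assign(ox.size(), 1.0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t c = id(i,j,k);
          if (!fluid[c]) { diag[c] = 1.0; continue; }
          double d = dtop[c]*iz2;
          d += ox[c]*ix2; if (i > 0) d += ox[c-1]*ix2;
          d += oy[c]*iy2; if (j > 0) d += oy[c-nx]*iy2;
          d += oz[c]*iz2; if (k > 0) d += oz[c-(size_t)nx*ny]*iz2;
          diag[c] = d > 0 ? d : 1.0;
        }
    x.assign(ox.size(), 0.0); b.assign(ox.size(), 0.0);
    r.assign(ox.size(), 0.0);
  }
  void apply(const std::vector<double>& v, std::vector<double>& out) const {
    double ix2 = 1.0/(hx*hx), iy2 = 1.0/(hy*hy), iz2 = 1.0/(hz*hz);
    size_t sz = (size_t)nx*ny;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t c = id(i,j,k);
          if (!fluid[c]) { out[c] = v[c]; continue; }
          double acc = diag[c]*v[c];
          if (i < nx-1) acc -= ox[c]*ix2*v[c+1];
          if (i > 0)    acc -= ox[c-1]*ix2*v[c-1];
          if (j < ny-1) acc -= oy[c]*iy2*v[c+nx];
          if (j > 0)    acc -= oy[c-nx]*iy2*v[c-nx];
          if (k < nz-1) acc -= oz[c]*iz2*v[c+sz];
          if (k > 0)    acc -= oz[c-sz]*iz2*v[c-sz];
          out[c] = acc;
        }
  }
  void smooth(int color) { // red-black Gauss-Seidel half sweep
    double ix2 = 1.0/(hx*hx), iy2 = 1.0/(hy*hy), iz2 = 1.0/(hz*hz);
    size_t sz = (size_t)nx*ny;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        int i0 = (color + j + k) & 1;
        for (int i = i0; i < nx; i += 2) {
          size_t c = id(i,j,k);
          if (!fluid[c]) continue;
          double acc = b[c];
          if (i < nx-1) acc += ox[c]*ix2*x[c+1];
          if (i > 0)    acc += ox[c-1]*ix2*x[c-1];
          if (j < ny-1) acc += oy[c]*iy2*x[c+nx];
          if (j > 0)    acc += oy[c-nx]*iy2*x[c-nx];
          if (k < nz-1) acc += oz[c]*iz2*x[c+sz];
          if (k > 0)    acc += oz[c-sz]*iz2*x[c-sz];
          x[c] = acc / diag[c];
        }
      }
  }
};

struct Multigrid {
  std::vector<MgLevel> lev;
  void build_coarse() {
    while (true) {
      MgLevel& f = lev.back();
      if (f.nx % 2 || f.ny % 2 || f.nz % 2) break;
      if (f.nx <= 4 || f.ny <= 4 || f.nz <= 4) break;
      MgLevel c;
      c.nx = f.nx/2; c.ny = f.ny/2; c.nz = f.nz/2;
      c.hx = 2*f.hx; c.hy = 2*f.hy; c.hz = 2*f.hz;
      size_t n = (size_t)c.nx*c.ny*c.nz;
      c.ox.assign(n, 0.0); c.oy.assign(n, 0.0); c.oz.assign(n, 0.0);
      c.dtop.assign(n, 0.0); c.fluid.assign(n, 0);
      for (int K = 0; K < c.nz; ++K)
        for (int J = 0; J < c.ny; ++J)
          for (int I = 0; I < c.nx; ++I) {
            size_t cc = c.id(I,J,K);
            bool anyf = false;
            for (int dk = 0; dk < 2; ++dk)
              for (int dj = 0; dj < 2; ++dj)
                for (int di = 0; di < 2; ++di)
                  if (f.fluid[f.id(2*I+di, 2*J+dj, 2*K+dk)]) anyf = true;
            c.fluid[cc] = anyf;
            if (!anyf) continue;
            // +x interface: fine faces at child i=1
            double s = 0;
            for (int dk = 0; dk < 2; ++dk)
              for (int dj = 0; dj < 2; ++dj)
                s += f.ox[f.id(2*I+1, 2*J+dj, 2*K+dk)];
            c.ox[cc] = s / 4.0;
            s = 0;
            for (int dk = 0; dk < 2; ++dk)
              for (int di = 0; di < 2; ++di)
                s += f.oy[f.id(2*I+di, 2*J+1, 2*K+dk)];
            c.oy[cc] = s / 4.0;
            s = 0;
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                s += f.oz[f.id(2*I+di, 2*J+dj, 2*K+1)];
            c.oz[cc] = s / 4.0;
            if (K == c.nz - 1) {
              s = 0;
              for (int dj = 0; dj < 2; ++dj)
                for (int di = 0; di < 2; ++di)
                  s += f.dtop[f.id(2*I+di, 2*J+dj, 2*K+1)];
              c.dtop[cc] = s / 4.0;
            }
          }
      c.finalize_diag();
      lev.push_back(std::move(c));
    }
    for (auto& l : lev) l.finalize_diag();
  }
  void vcycle(size_t l) {
    MgLevel& L = lev[l];
    if (l == lev.size() - 1) {
      for (int s = 0; s < 40; ++s) { L.smooth(0); L.smooth(1); }
      return;
    }
    L.smooth(0); L.smooth(1);
    L.apply(L.x, L.r);
    for (size_t c = 0; c < L.r.size(); ++c)
      L.r[c] = L.fluid[c] ? L.b[c] - L.r[c] : 0.0;
    MgLevel& C = lev[l+1];
    std::fill(C.x.begin(), C.x.end(), 0.0);
    for (int K = 0; K < C.nz; ++K)
      for (int J = 0; J < C.ny; ++J)
        for (int I = 0; I < C.nx; ++I) {
          double s = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                s += L.r[L.id(2*I+di, 2*J+dj, 2*K+dk)];
          // Galerkin-consistent scaling for piecewise-constant transfer in
          // 3D: P^T A_f P = 16 A_c, so the coarse rhs is P^T r / 16.
          C.b[C.id(I,J,K)] = C.fluid[C.id(I,J,K)] ? s / 16.0 : 0.0;
        }
    vcycle(l+1);
    for (int K = 0; K < C.nz; ++K)
      for (int J = 0; J < C.ny; ++J)
        for (int I = 0; I < C.nx; ++I) {
          double xc = C.x[C.id(I,J,K)];
          if (xc == 0.0) continue;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                size_t cf = L.id(2*I+di, 2*J+dj, 2*K+dk);
                if (L.fluid[cf]) L.x[cf] += xc;
              }
        }
    L.smooth(1); L.smooth(0);
  }
  // preconditioner: z = M^-1 r (one V-cycle from zero initial guess)
  void precondition(const std::vector<double>& rin, std::vector<double>& z) {
    MgLevel& L = lev[0];
    std::fill(L.x.begin(), L.x.end(), 0.0);
    L.b = rin;
    vcycle(0);
    z = L.x;
  }
};

} // namespace

// One macro time step.  inlet_u is a vector of u-face linear indices (0-based,
// into the u array) carrying prescribed velocity u_in while `inlet_on`.
// Returns diagnostics.
// [[Rcpp::export(name = ".cpp_flow_step")]]
List cpp_flow_step(NumericVector u, NumericVector v, NumericVector w,
                   NumericVector p, NumericVector alpha,
                   IntegerVector flag, NumericVector drag,
                   IntegerVector inlet_u, double u_in, bool inlet_on,
                   IntegerVector dims, NumericVector spacing,
                   double dt, double rho, double mu, double grav,
                   double cg_tol, int cg_maxiter) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.hx = spacing[0]; g.hy = spacing[1]; g.hz = spacing[2];
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const size_t nu = (size_t)(nx + 1) * ny * nz;
  const size_t nv = (size_t)nx * (ny + 1) * nz;
  const size_t nw = (size_t)nx * ny * (nz + 1);
  const size_t nc = (size_t)nx * ny * nz;
  double* U = REAL(u); double* V = REAL(v); double* W = REAL(w);
  double* P = REAL(p); double* A = REAL(alpha); double* D = REAL(drag);
  const int* F = INTEGER(flag);
  std::vector<char> is_inlet(nu, 0);
  for (int m = 0; m < inlet_u.size(); ++m) is_inlet[inlet_u[m]] = 1;

  auto enforce_bc = [&]() {
    // u faces
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i <= nx; ++i) {
          size_t id = g.idu(i, j, k);
          if (is_inlet[id]) { U[id] = inlet_on ? u_in : 0.0; continue; }
          bool fl = fluid_at(F, g, i - 1, j, k), fr = fluid_at(F, g, i, j, k);
          if (!fl || !fr) U[id] = 0.0;
        }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j <= ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = g.idv(i, j, k);
          bool fl = fluid_at(F, g, i, j - 1, k), fr = fluid_at(F, g, i, j, k);
          if (!fl || !fr) V[id] = 0.0;
        }
    // w faces (vertical): open at top (k == nz) above fluid cells
    for (int k = 0; k <= nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
          bool fb = fluid_at(F, g, i, j, k - 1), ft = fluid_at(F, g, i, j, k);
          if (k == nz) { if (!fb) W[id] = 0.0; continue; } // open top
          if (!fb || !ft) W[id] = 0.0;
        }
  };
  auto widx = [&](int i, int j, int k) -> size_t {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };

  enforce_bc();

  // ---- advection with CFL sub-stepping (upwind) --------------------------
  double vmax = 0.0;
  for (size_t m = 0; m < nu; ++m) vmax = std::max(vmax, std::fabs(U[m]));
  for (size_t m = 0; m < nv; ++m) vmax = std::max(vmax, std::fabs(V[m]));
  for (size_t m = 0; m < nw; ++m) vmax = std::max(vmax, std::fabs(W[m]));
  double hmin = std::min(g.hx, std::min(g.hy, g.hz));
  int nsub = std::max(1, (int)std::ceil(dt * vmax / (0.8 * hmin)));
  if (nsub > 4000) stop("flow solver CFL sub-stepping exploded (vmax=%f)", vmax);
  double dts = dt / nsub;
  std::vector<double> u0(nu), v0(nv), w0(nw), a0(nc);
  double injected = 0.0;
  // active (fluid-fluid, non-inlet) interior faces, precomputed once
  std::vector<char> au(nu, 0), av(nv, 0), aw(nw, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 1; i < nx; ++i) {
        size_t id = g.idu(i, j, k);
        au[id] = !is_inlet[id] && fluid_at(F, g, i-1, j, k) &&
                 fluid_at(F, g, i, j, k);
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        av[g.idv(i,j,k)] = fluid_at(F, g, i, j-1, k) &&
                           fluid_at(F, g, i, j, k);
  for (int k = 1; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        aw[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] =
          fluid_at(F, g, i, j, k-1) && fluid_at(F, g, i, j, k);

  for (int s = 0; s < nsub; ++s) {
    std::copy(U, U + nu, u0.begin());
    std::copy(V, V + nv, v0.begin());
    std::copy(W, W + nw, w0.begin());
    std::copy(A, A + nc, a0.begin());
    // u component
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 1; i < nx; ++i) {
          size_t id = g.idu(i, j, k);
          if (!au[id]) continue;
          double uc = u0[id];
          double vc = 0.25 * (v0[g.idv(i-1,j,k)] + v0[g.idv(i,j,k)] +
                              v0[g.idv(i-1,j+1,k)] + v0[g.idv(i,j+1,k)]);
          double wc = 0.25 * (w0[widx(i-1,j,k)] + w0[widx(i,j,k)] +
                              w0[widx(i-1,j,k+1)] + w0[widx(i,j,k+1)]);
          double dudx = uc >= 0 ? (uc - u0[g.idu(i-1,j,k)]) / g.hx
                                : (u0[g.idu(i+1,j,k)] - uc) / g.hx;
          double dudy = vc >= 0
            ? (uc - (j > 0 ? u0[g.idu(i,j-1,k)] : uc)) / g.hy
            : ((j < ny-1 ? u0[g.idu(i,j+1,k)] : uc) - uc) / g.hy;
          double dudz = wc >= 0
            ? (uc - (k > 0 ? u0[g.idu(i,j,k-1)] : uc)) / g.hz
            : ((k < nz-1 ? u0[g.idu(i,j,k+1)] : uc) - uc) / g.hz;
          U[id] = uc - dts * (uc * dudx + vc * dudy + wc * dudz);
        }
    // v component
    for (int k = 0; k < nz; ++k)
      for (int j = 1; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = g.idv(i, j, k);
          if (!av[id]) continue;
          double vc = v0[id];
          double uc = 0.25 * (u0[g.idu(i,j-1,k)] + u0[g.idu(i+1,j-1,k)] +
                              u0[g.idu(i,j,k)] + u0[g.idu(i+1,j,k)]);
          double wc = 0.25 * (w0[widx(i,j-1,k)] + w0[widx(i,j,k)] +
                              w0[widx(i,j-1,k+1)] + w0[widx(i,j,k+1)]);
          double dvdx = uc >= 0
            ? (vc - (i > 0 ? v0[g.idv(i-1,j,k)] : vc)) / g.hx
            : ((i < nx-1 ? v0[g.idv(i+1,j,k)] : vc) - vc) / g.hx;
          double dvdy = vc >= 0 ? (vc - v0[g.idv(i,j-1,k)]) / g.hy
                                : (v0[g.idv(i,j+1,k)] - vc) / g.hy;
          double dvdz = wc >= 0
            ? (vc - (k > 0 ? v0[g.idv(i,j,k-1)] : vc)) / g.hz
            : ((k < nz-1 ? v0[g.idv(i,j,k+1)] : vc) - vc) / g.hz;
          V[id] = vc - dts * (uc * dvdx + vc * dvdy + wc * dvdz);
        }
    // w component
    for (int k = 1; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = widx(i, j, k);
          if (!aw[id]) continue;
          double wc = w0[id];
          double uc = 0.25 * (u0[g.idu(i,j,k-1)] + u0[g.idu(i+1,j,k-1)] +
                              u0[g.idu(i,j,k)] + u0[g.idu(i+1,j,k)]);
          double vc = 0.25 * (v0[g.idv(i,j,k-1)] + v0[g.idv(i,j+1,k-1)] +
                              v0[g.idv(i,j,k)] + v0[g.idv(i,j+1,k)]);
          double dwdx = uc >= 0
            ? (wc - (i > 0 ? w0[widx(i-1,j,k)] : wc)) / g.hx
            : ((i < nx-1 ? w0[widx(i+1,j,k)] : wc) - wc) / g.hx;
          double dwdy = vc >= 0
            ? (wc - (j > 0 ? w0[widx(i,j-1,k)] : wc)) / g.hy
            : ((j < ny-1 ? w0[widx(i,j+1,k)] : wc) - wc) / g.hy;
          double dwdz = wc >= 0 ? (wc - w0[widx(i,j,k-1)]) / g.hz
                                : (w0[widx(i,j,k+1)] - wc) / g.hz;
          W[id] = wc - dts * (uc * dwdx + vc * dwdy + wc * dwdz);
        }
    // alpha: conservative upwind fluxes on start-of-substep field
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t c = g.idc(i, j, k);
          if (F[c] != 0) continue;
          double fx_w, fx_e, fy_s, fy_n, fz_b, fz_t;
          size_t iw = g.idu(i, j, k), ie = g.idu(i + 1, j, k);
          double uw = u0[iw], ue = u0[ie];
          double aw = is_inlet[iw] ? 1.0
                      : (uw >= 0 ? (i > 0 ? a0[g.idc(i-1,j,k)] : 0.0) : a0[c]);
          double ae = is_inlet[ie] ? 1.0
                      : (ue >= 0 ? a0[c] : (i < nx-1 ? a0[g.idc(i+1,j,k)] : 0.0));
          fx_w = uw * aw; fx_e = ue * ae;
          double vs = v0[g.idv(i, j, k)], vn = v0[g.idv(i, j + 1, k)];
          double as = vs >= 0 ? (j > 0 ? a0[g.idc(i,j-1,k)] : 0.0) : a0[c];
          double an = vn >= 0 ? a0[c] : (j < ny-1 ? a0[g.idc(i,j+1,k)] : 0.0);
          fy_s = vs * as; fy_n = vn * an;
          double wb = w0[widx(i, j, k)], wt = w0[widx(i, j, k + 1)];
          double ab = wb >= 0 ? (k > 0 ? a0[g.idc(i,j,k-1)] : 0.0) : a0[c];
          double at = wt >= 0 ? a0[c] : (k < nz-1 ? a0[g.idc(i,j,k+1)] : 0.0);
          fz_b = wb * ab; fz_t = wt * at;
          A[c] = a0[c] - dts * ((fx_e - fx_w) / g.hx +
                                (fy_n - fy_s) / g.hy +
                                (fz_t - fz_b) / g.hz);
          if (A[c] < 0.0) A[c] = 0.0;
          if (A[c] > 1.0) A[c] = 1.0;
        }
    if (inlet_on) {
      for (int m = 0; m < inlet_u.size(); ++m)
        injected += u_in * g.hy * g.hz * dts;
    }
  }

  // ---- viscosity (explicit), gravity, Darcy drag -------------------------
  double nu_visc = mu / rho;
  std::copy(U, U + nu, u0.begin());
  std::copy(V, V + nv, v0.begin());
  std::copy(W, W + nw, w0.begin());
  auto lap = [&](const std::vector<double>& q, size_t id,
                 size_t sx, size_t sy, size_t sz,
                 bool okxm, bool okxp, bool okym, bool okyp,
                 bool okzm, bool okzp) {
    double qc = q[id];
    double qxm = okxm ? q[id - sx] : 0.0, qxp = okxp ? q[id + sx] : 0.0;
    double qym = okym ? q[id - sy] : 0.0, qyp = okyp ? q[id + sy] : 0.0;
    double qzm = okzm ? q[id - sz] : 0.0, qzp = okzp ? q[id + sz] : 0.0;
    return (qxm - 2*qc + qxp) / (g.hx*g.hx) +
           (qym - 2*qc + qyp) / (g.hy*g.hy) +
           (qzm - 2*qc + qzp) / (g.hz*g.hz);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 1; i < nx; ++i) {
        size_t id = g.idu(i, j, k);
        if (is_inlet[id]) continue;
        if (!fluid_at(F, g, i-1, j, k) || !fluid_at(F, g, i, j, k)) continue;
        U[id] += dt * nu_visc * lap(u0, id, 1, nx + 1, (size_t)(nx+1)*ny,
                                    i > 0, i < nx, j > 0, j < ny-1,
                                    k > 0, k < nz-1);
        double Df = 0.5 * (D[g.idc(i-1,j,k)] + D[g.idc(i,j,k)]);
        if (Df > 0) U[id] /= (1.0 + dt * Df / rho);
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!fluid_at(F, g, i, j-1, k) || !fluid_at(F, g, i, j, k)) continue;
        size_t id = g.idv(i, j, k);
        V[id] += dt * nu_visc * lap(v0, id, 1, nx, (size_t)nx*(ny+1),
                                    i > 0, i < nx-1, j > 0, j < ny,
                                    k > 0, k < nz-1);
        double Df = 0.5 * (D[g.idc(i,j-1,k)] + D[g.idc(i,j,k)]);
        if (Df > 0) V[id] /= (1.0 + dt * Df / rho);
      }
  for (int k = 1; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!fluid_at(F, g, i, j, k-1) || !fluid_at(F, g, i, j, k)) continue;
        size_t id = widx(i, j, k);
        W[id] += dt * nu_visc * lap(w0, id, 1, nx, (size_t)nx*ny,
                                    i > 0, i < nx-1, j > 0, j < ny-1,
                                    k > 0, k < nz);
        // gravity acts on the liquid fraction (weighted body force)
        double af = 0.5 * (A[g.idc(i,j,k-1)] + A[g.idc(i,j,k)]);
        W[id] -= dt * grav * af;
        double Df = 0.5 * (D[g.idc(i,j,k-1)] + D[g.idc(i,j,k)]);
        if (Df > 0) W[id] /= (1.0 + dt * Df / rho);
      }
  enforce_bc();

  // ---- pressure projection ----------------------------------------------
  // Solve  A p = -(rho/dt) div(u*)  with A the (SPD) face-open Laplacian
  // and a Dirichlet p = 0 ghost above the top layer (open well mouth),
  // by conjugate gradients preconditioned with one geometric multigrid
  // V-cycle (red-black Gauss-Seidel smoothing).
  Multigrid mg;
  mg.lev.reserve(16); // avoid reallocation: L0 stays valid after coarsening
  mg.lev.resize(1);
  MgLevel& L0 = mg.lev[0];
  L0.nx = nx; L0.ny = ny; L0.nz = nz;
  L0.hx = g.hx; L0.hy = g.hy; L0.hz = g.hz;
  L0.ox.assign(nc, 0.0); L0.oy.assign(nc, 0.0); L0.oz.assign(nc, 0.0);
  L0.dtop.assign(nc, 0.0); L0.fluid.assign(nc, 0);
  std::vector<double> b(nc, 0.0);
  double divmax0 = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t c = g.idc(i, j, k);
        if (F[c] != 0) continue;
        L0.fluid[c] = 1;
        double div =
          (U[g.idu(i+1,j,k)] - U[g.idu(i,j,k)]) / g.hx +
          (V[g.idv(i,j+1,k)] - V[g.idv(i,j,k)]) / g.hy +
          (W[widx(i,j,k+1)] - W[widx(i,j,k)]) / g.hz;
        b[c] = -(rho / dt) * div;
        divmax0 = std::max(divmax0, std::fabs(div));
        if (i < nx-1 && fluid_at(F, g, i+1, j, k) &&
            !is_inlet[g.idu(i+1,j,k)]) L0.ox[c] = 1.0;
        if (j < ny-1 && fluid_at(F, g, i, j+1, k)) L0.oy[c] = 1.0;
        if (k < nz-1 && fluid_at(F, g, i, j, k+1)) L0.oz[c] = 1.0;
        if (k == nz-1) L0.dtop[c] = 1.0;
      }
  mg.build_coarse();
  std::vector<double> x(nc), r(nc), z(nc), d(nc), q(nc);
  for (size_t c = 0; c < nc; ++c) x[c] = L0.fluid[c] ? P[c] : 0.0;
  double bnorm = 0.0;
  for (size_t c = 0; c < nc; ++c) bnorm += b[c] * b[c];
  bnorm = std::sqrt(bnorm);
  int iters = 0;
  double relres = 0.0;
  if (bnorm > 0.0) {
    L0.apply(x, q);
    for (size_t c = 0; c < nc; ++c)
      r[c] = L0.fluid[c] ? b[c] - q[c] : 0.0;
    mg.precondition(r, z);
    d = z;
    double rz = 0.0;
    for (size_t c = 0; c < nc; ++c) rz += r[c] * z[c];
    for (iters = 0; iters < cg_maxiter; ++iters) {
      double rn = 0.0;
      for (size_t c = 0; c < nc; ++c) rn += r[c] * r[c];
      relres = std::sqrt(rn) / bnorm;
      if (relres < cg_tol) break;
      L0.apply(d, q);
      double dq = 0.0;
      for (size_t c = 0; c < nc; ++c) dq += d[c] * q[c];
      if (dq <= 0.0) break;
      double alpha_cg = rz / dq;
      for (size_t c = 0; c < nc; ++c) {
        x[c] += alpha_cg * d[c];
        r[c] -= alpha_cg * q[c];
      }
      mg.precondition(r, z);
      double rz_new = 0.0;
      for (size_t c = 0; c < nc; ++c) rz_new += r[c] * z[c];
      double beta = rz_new / rz;
      rz = rz_new;
      for (size_t c = 0; c < nc; ++c) d[c] = z[c] + beta * d[c];
    }
    if (relres >= cg_tol && iters >= cg_maxiter)
      stop("pressure solver did not converge (relative residual %g)", relres);
    for (size_t c = 0; c < nc; ++c) P[c] = L0.fluid[c] ? x[c] : 0.0;
    // velocity correction on open faces
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t c = g.idc(i, j, k);
          if (!L0.fluid[c]) continue;
          size_t sz = (size_t)nx * ny;
          if (L0.ox[c] > 0)
            U[g.idu(i+1,j,k)] -= dt / rho * (P[c+1] - P[c]) / g.hx;
          if (L0.oy[c] > 0)
            V[g.idv(i,j+1,k)] -= dt / rho * (P[c+nx] - P[c]) / g.hy;
          if (L0.oz[c] > 0)
            W[widx(i,j,k+1)] -= dt / rho * (P[c+sz] - P[c]) / g.hz;
          if (L0.dtop[c] > 0)
            W[widx(i,j,nz)] -= dt / rho * (0.0 - P[c]) / g.hz;
        }
  }
  double divmax = 0.0, liquid = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t c = g.idc(i, j, k);
        if (F[c] != 0) continue;
        double div =
          (U[g.idu(i+1,j,k)] - U[g.idu(i,j,k)]) / g.hx +
          (V[g.idv(i,j+1,k)] - V[g.idv(i,j,k)]) / g.hy +
          (W[widx(i,j,k+1)] - W[widx(i,j,k)]) / g.hz;
        divmax = std::max(divmax, std::fabs(div));
        liquid += A[c];
      }
  liquid *= g.hx * g.hy * g.hz;
  return List::create(_["nsub"] = nsub, _["cg_iters"] = iters,
                      _["relres"] = relres, _["div_before"] = divmax0,
                      _["div_after"] = divmax, _["liquid_volume"] = liquid,
                      _["injected_volume"] = injected, _["vmax"] = vmax);
}

// Trilinear MAC velocity sampling at arbitrary points (m).
// [[Rcpp::export(name = ".cpp_sample_velocity")]]
NumericMatrix cpp_sample_velocity(NumericVector u, NumericVector v,
                                  NumericVector w, IntegerVector dims,
                                  NumericVector spacing, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double* U = REAL(u); const double* V = REAL(v); const double* W = REAL(w);
  NumericMatrix out(pts.nrow(), 3);
  auto interp = [&](const double* q, double x, double y, double z,
                    int qnx, int qny, int qnz,
                    double ox, double oy, double oz) {
    // component grid node (i,j,k) at (i*hx+ox, j*hy+oy, k*hz+oz)
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
  };
  for (int m = 0; m < pts.nrow(); ++m) {
    double x = pts(m,0), y = pts(m,1), z = pts(m,2);
    out(m,0) = interp(U, x, y, z, nx+1, ny, nz, 0.0, 0.5*hy, 0.5*hz);
    out(m,1) = interp(V, x, y, z, nx, ny+1, nz, 0.5*hx, 0.0, 0.5*hz);
    out(m,2) = interp(W, x, y, z, nx, ny, nz+1, 0.5*hx, 0.5*hy, 0.0);
  }
  return out;
}
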