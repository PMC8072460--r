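// Core numerical kernels: signed-distance geometry of a vessel tree,
// Cartesian voxel classification, a staggered-grid (MAC) pseudo-transient
// projection solver for steady incompressible flow with Carreau viscosity and
// a sharp-interface (subcell ghost) immersed-boundary wall treatment, and
// wall-anchored quadratic probes for wall shear stress.
//
// All quantities here are SI (m, s, Pa); the R layer converts from mm.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <functional>
#include <limits>

using namespace Rcpp;

namespace {

struct Vessel {
  std::vector<double> px, py, pz;   // centerline polyline
  double r;
  bool cap0, cap1;                  // flat port cut at start / end
  double c0[3], n0[3];              // start port plane (outward normal)
  double c1[3], n1[3];              // end port plane
  double blo[3], bhi[3];            // bounding box of centerline
};

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// distance from p to segment ab
inline double seg_dist(const double* p, double ax, double ay, double az,
                       double bx, double by, double bz) {
  double dx = bx - ax, dy = by - ay, dz = bz - az;
  double wx = p[0] - ax, wy = p[1] - ay, wz = p[2] - az;
  double L2 = dx * dx + dy * dy + dz * dz;
  double t = (L2 > 0.0) ? (wx * dx + wy * dy + wz * dz) / L2 : 0.0;
  t = std::min(1.0, std::max(0.0, t));
  double qx = wx - t * dx, qy = wy - t * dy, qz = wz - t * dz;
  return std::sqrt(qx * qx + qy * qy + qz * qz);
}

double vessel_sdf(const Vessel& v, const double* p) {
  double d = std::numeric_limits<double>::max();
  const size_t n = v.px.size();
  for (size_t s = 0; s + 1 < n; ++s) {
    double ds = seg_dist(p, v.px[s], v.py[s], v.pz[s],
                         v.px[s + 1], v.py[s + 1], v.pz[s + 1]);
    if (ds < d) d = ds;
  }
  d -= v.r;
  if (v.cap0) {
    double q[3] = { p[0] - v.c0[0], p[1] - v.c0[1], p[2] - v.c0[2] };
    d = std::max(d, dot3(q, v.n0));
  }
  if (v.cap1) {
    double q[3] = { p[0] - v.c1[0], p[1] - v.c1[1], p[2] - v.c1[2] };
    d = std::max(d, dot3(q, v.n1));
  }
  return d;
}

// lower bound on vessel_sdf via the centerline bounding box
inline double vessel_lb(const Vessel& v, const double* p) {
  double d = 0.0;
  for (int a = 0; a < 3; ++a) {
    double lo = v.blo[a], hi = v.bhi[a];
    double e = (p[a] < lo) ? (lo - p[a]) : ((p[a] > hi) ? (p[a] - hi) : 0.0);
    d += e * e;
  }
  return std::sqrt(d) - v.r;
}

std::vector<Vessel> parse_geom(const List& geom) {
  std::vector<Vessel> vs;
  vs.reserve(geom.size());
  for (int i = 0; i < geom.size(); ++i) {
    List g = geom[i];
    NumericMatrix pts = g["pts"];
    Vessel v;
    v.r = as<double>(g["r"]);
    v.cap0 = as<bool>(g["cap0"]);
    v.cap1 = as<bool>(g["cap1"]);
    int n = pts.nrow();
    v.px.resize(n); v.py.resize(n); v.pz.resize(n);
    for (int k = 0; k < n; ++k) {
      v.px[k] = pts(k, 0); v.py[k] = pts(k, 1); v.pz[k] = pts(k, 2);
    }
    for (int a = 0; a < 3; ++a) {
      v.blo[a] = std::numeric_limits<double>::max();
      v.bhi[a] = -std::numeric_limits<double>::max();
    }
    for (int k = 0; k < n; ++k) {
      v.blo[0] = std::min(v.blo[0], v.px[k]); v.bhi[0] = std::max(v.bhi[0], v.px[k]);
      v.blo[1] = std::min(v.blo[1], v.py[k]); v.bhi[1] = std::max(v.bhi[1], v.py[k]);
      v.blo[2] = std::min(v.blo[2], v.pz[k]); v.bhi[2] = std::max(v.bhi[2], v.pz[k]);
    }
    NumericVector n0 = g["n0"], n1 = g["n1"];
    v.c0[0] = v.px[0]; v.c0[1] = v.py[0]; v.c0[2] = v.pz[0];
    v.c1[0] = v.px[n - 1]; v.c1[1] = v.py[n - 1]; v.c1[2] = v.pz[n - 1];
    for (int a = 0; a < 3; ++a) { v.n0[a] = n0[a]; v.n1[a] = n1[a]; }
    vs.push_back(std::move(v));
  }
  return vs;
}

double tree_sdf(const std::vector<Vessel>& vs, const double* p) {
  double d = std::numeric_limits<double>::max();
  for (const Vessel& v : vs) {
    if (vessel_lb(v, p) >= d) continue;
    d = std::min(d, vessel_sdf(v, p));
  }
  return d;
}

struct Carreau {
  double mu0, muInf, lambda, nexp;
  inline double mu(double g) const {
    double x = lambda * g;
    return muInf + (mu0 - muInf) * std::pow(1.0 + x * x, 0.5 * (nexp - 1.0));
  }
};

// trilinear sample of a lattice with given fractional offsets; outside -> 0
inline double sample_lat(const double* a, int nx, int ny, int nz,
                         double fx, double fy, double fz) {
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
  double tx = fx - i0, ty = fy - j0, tz = fz - k0;
  double out = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
        double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) * (dk ? tz : 1 - tz);
        out += w * a[i + (size_t)nx * (j + (size_t)ny * k)];
      }
  return out;
}

struct Grid {
  int nx, ny, nz;
  double x0, y0, z0, h;
  inline size_t cidx(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  }
};

// velocity probe at arbitrary point from MAC arrays
inline void sample_vel(const Grid& G, const double* u, const double* v,
                       const double* w, const double* p, double* out) {
  double fx = (p[0] - G.x0) / G.h, fy = (p[1] - G.y0) / G.h, fz = (p[2] - G.z0) / G.h;
  out[0] = sample_lat(u, G.nx + 1, G.ny, G.nz, fx, fy - 0.5, fz - 0.5);
  out[1] = sample_lat(v, G.nx, G.ny + 1, G.nz, fx - 0.5, fy, fz - 0.5);
  out[2] = sample_lat(w, G.nx, G.ny, G.nz + 1, fx - 0.5, fy - 0.5, fz);
}

// WSS probes shared by the solver monitor and the exported extractor.
// For each face: sample tangential velocity at d1 and d2 along the inward
// normal, fit u_t(s) = a s + b s^2 through u_t(0) = 0, wall shear rate = |a|.
void wss_probes(const Grid& G, const double* u, const double* v, const double* w,
                const double* muCell, const int* cclass,
                const NumericMatrix& cen, const NumericMatrix& nrm,
                double d1, double d2, const Carreau& C,
                std::vector<double>& gammaW, std::vector<double>& tau,
                std::vector<double>& muNW) {
  int nt = cen.nrow();
  gammaW.resize(nt); tau.resize(nt); muNW.resize(nt);
  for (int t = 0; t < nt; ++t) {
    double c[3] = { cen(t, 0), cen(t, 1), cen(t, 2) };
    double n[3] = { nrm(t, 0), nrm(t, 1), nrm(t, 2) };
    double p1[3] = { c[0] + d1 * n[0], c[1] + d1 * n[1], c[2] + d1 * n[2] };
    double p2[3] = { c[0] + d2 * n[0], c[1] + d2 * n[1], c[2] + d2 * n[2] };
    double u1[3], u2[3];
    sample_vel(G, u, v, w, p1, u1);
    sample_vel(G, u, v, w, p2, u2);
    // tangential components
    double un1 = dot3(u1, n), un2 = dot3(u2, n);
    double a2 = 0.0;
    double den = d1 * d2 * (d2 - d1);
    double av[3];
    for (int a = 0; a < 3; ++a) {
      double t1 = u1[a] - un1 * n[a];
      double t2 = u2[a] - un2 * n[a];
      av[a] = (d2 * d2 * t1 - d1 * d1 * t2) / den;
      a2 += av[a] * av[a];
    }
    double g = std::sqrt(a2);
    gammaW[t] = g;
    tau[t] = C.mu(g) * g;
    // near-wall viscosity: fluid-weighted trilinear sample of cell viscosity
    double fx = (p1[0] - G.x0) / G.h - 0.5, fy = (p1[1] - G.y0) / G.h - 0.5,
           fz = (p1[2] - G.z0) / G.h - 0.5;
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
    double tx = fx - i0, ty = fy - j0, tz = fz - k0, wsum = 0.0, msum = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          int i = i0 + di, j = j0 + dj, k = k0 + dk;
          if (i < 0 || j < 0 || k < 0 || i >= G.nx || j >= G.ny || k >= G.nz) continue;
          size_t cc = G.cidx(i, j, k);
          if (cclass[cc] == 0) continue;
          double wgt = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) * (dk ? tz : 1 - tz);
          wsum += wgt; msum += wgt * muCell[cc];
        }
    muNW[t] = (wsum > 1e-12) ? msum / wsum : C.mu(g);
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_sdf(List geom, NumericMatrix pts) {
  std::vector<Vessel> vs = parse_geom(geom);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    out[i] = tree_sdf(vs, p);
  }
  return out;
}

// Cell classification: 0 solid, 1 interior fluid, 2 outlet buffer,
// 10+k inlet plug of port k (0-based order of `ports` entries with kind 1).
// [[Rcpp::export]]
IntegerVector cpp_voxelize(List geom, NumericVector origin, double h,
                           IntegerVector dims, List ports) {
  std::vector<Vessel> vs = parse_geom(geom);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector cls((size_t)nx * ny * nz);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double p[3] = { origin[0] + (i + 0.5) * h, origin[1] + (j + 0.5) * h,
                        origin[2] + (k + 0.5) * h };
        if (tree_sdf(vs, p) >= 0.0) { cls[idx] = 0; continue; }
        int c = 1;
        int inlet_no = 0;
        for (int q = 0; q < ports.size(); ++q) {
          List pq = ports[q];
          int kind = as<int>(pq["kind"]);  // 1 inlet plug, 2 outlet buffer
          int vi = as<int>(pq["vessel"]);  // 0-based vessel index
          NumericVector ce = pq["center"], no = pq["normal"];
          double depth = as<double>(pq["depth"]);
          double s = (ce[0] - p[0]) * no[0] + (ce[1] - p[1]) * no[1] +
                     (ce[2] - p[2]) * no[2];
          if (s >= -1e-12 && s <= depth && vessel_sdf(vs[vi], p) < 0.0) {
            c = (kind == 2) ? 2 : (10 + inlet_no);
            break;
          }
          if (kind == 1) ++inlet_no;
        }
        cls[idx] = c;
      }
  return cls;
}

// [[Rcpp::export]]
List cpp_wss_probe(NumericVector u, NumericVector v, NumericVector w,
                   NumericVector muCell, IntegerVector cellClass,
                   NumericVector origin, double h, IntegerVector dims,
                   NumericMatrix centroids, NumericMatrix normals,
                   double delta1, double delta2, List rheo) {
  Grid G;
  G.nx = dims[0]; G.ny = dims[1]; G.nz = dims[2];
  G.x0 = origin[0]; G.y0 = origin[1]; G.z0 = origin[2]; G.h = h;
  Carreau C{ as<double>(rheo["mu0"]), as<double>(rheo["mu_inf"]),
             as<double>(rheo["lambda"]), as<double>(rheo["n"]) };
  std::vector<double> g, t, m;
  wss_probes(G, REAL(u), REAL(v), REAL(w), REAL(muCell), INTEGER(cellClass),
             centroids, normals, delta1, delta2, C, g, t, m);
  return List::create(_["gamma_w"] = wrap(g), _["wss"] = wrap(t),
                      _["mu_nw"] = wrap(m));
}

namespace {

struct FreeFace {
  int idx;            // index into the full staggered array
  int i, j, k;        // face lattice coordinates
  int cL, cR;         // adjacent cell indices (full grid)
  int nbr[6];         // neighbour face index in full array, -1 = wall
  float invAl[6];     // 1 / (subcell wall distance fraction)
  int advA[4];        // stencil for transverse advecting comp (c+1)%3
  int advB[4];        // stencil for transverse advecting comp (c+2)%3
};

struct CompData {
  int nx, ny, nz;                  // lattice dims of this component
  std::vector<int8_t> state;       // 0 inactive, 1 free, 2 fixed
  std::vector<double> fixedBase;   // prescribed base value (fixed faces)
  std::vector<FreeFace> free;
  std::vector<int> fixedIdx;
  inline size_t fidx(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  }
};

}  // namespace

// Steady-flow solver. Returns fields plus convergence/monitoring history.
// [[Rcpp::export]]
List cpp_solve_flow(List geom, NumericVector origin, double h, IntegerVector dims,
                    IntegerVector cellClass, List inlets, List rheoL, List ctrl,
                    NumericMatrix probeCen, NumericMatrix probeNrm,
                    NumericVector probeArea, LogicalVector probeWall) {
  std::vector<Vessel> vs = parse_geom(geom);
  Grid G;
  G.nx = dims[0]; G.ny = dims[1]; G.nz = dims[2];
  G.x0 = origin[0]; G.y0 = origin[1]; G.z0 = origin[2]; G.h = h;
  const int nx = G.nx, ny = G.ny, nz = G.nz;
  const double rho = as<double>(rheoL["rho"]);
  Carreau C{ as<double>(rheoL["mu0"]), as<double>(rheoL["mu_inf"]),
             as<double>(rheoL["lambda"]), as<double>(rheoL["n"]) };

  const double t_min = as<double>(ctrl["t_min"]);
  const double t_end = as<double>(ctrl["t_end"]);
  const double t_max = as<double>(ctrl["t_max"]);
  const double ramp_t = as<double>(ctrl["ramp"]);
  const double check_dt = as<double>(ctrl["check_every"]);
  const double drift_tol = as<double>(ctrl["drift_tol"]);
  const double als_tol = as<double>(ctrl["als_drift_tol"]);
  const double cg_tol = as<double>(ctrl["cg_tol"]);
  const int cg_maxit = as<int>(ctrl["cg_maxit"]);
  const int visc_every = as<int>(ctrl["visc_every"]);
  const double cfl = as<double>(ctrl["cfl"]);
  const double dt_max = as<double>(ctrl["dt_max"]);
  const double wss_thr = as<double>(ctrl["wss_threshold"]);
  const double sigma_dc = as<double>(ctrl["central_blend"]);

  const int* cls = INTEGER(cellClass);
  const size_t ncell = (size_t)nx * ny * nz;

  // ---- compact free-cell numbering for the pressure solve -----------------
  std::vector<int> cellNo(ncell, -1);
  std::vector<int> freeCells;
  for (size_t c = 0; c < ncell; ++c)
    if (cls[c] == 1) { cellNo[c] = (int)freeCells.size(); freeCells.push_back((int)c); }
  const int nfree = (int)freeCells.size();
  if (nfree == 0) stop("no interior fluid cells on this grid");
  std::vector<int> allFluid;  // every non-solid cell (incl. plug/outlet buffers)
  for (size_t c = 0; c < ncell; ++c)
    if (cls[c] != 0) allFluid.push_back((int)c);

  // ---- staggered arrays ---------------------------------------------------
  std::vector<double> U((size_t)(nx + 1) * ny * nz, 0.0);
  std::vector<double> V((size_t)nx * (ny + 1) * nz, 0.0);
  std::vector<double> W((size_t)nx * ny * (nz + 1), 0.0);
  std::vector<double> Un(U.size()), Vn(V.size()), Wn(W.size());
  std::vector<double> muCell(ncell, C.mu0), gamCell(ncell, 0.0);
  std::vector<double> muFu(U.size(), C.mu0), muFv(V.size(), C.mu0), muFw(W.size(), C.mu0);
  std::vector<double> phi(nfree, 0.0), pFull(ncell, 0.0);

  CompData comp[3];
  comp[0].nx = nx + 1; comp[0].ny = ny; comp[0].nz = nz;
  comp[1].nx = nx; comp[1].ny = ny + 1; comp[1].nz = nz;
  comp[2].nx = nx; comp[2].ny = ny; comp[2].nz = nz + 1;

  // inlet plug profile parameters
  const int nin = inlets.size();
  std::vector<double> inCen(3 * nin), inAx(3 * nin), inR(nin), inV(nin);
  for (int q = 0; q < nin; ++q) {
    List iq = inlets[q];
    NumericVector ce = iq["center"], no = iq["normal"];  // outward normal
    for (int a = 0; a < 3; ++a) { inCen[3 * q + a] = ce[a]; inAx[3 * q + a] = -no[a]; }
    inR[q] = as<double>(iq["radius"]);
    inV[q] = as<double>(iq["vbar"]);
  }

  // face position for component c at lattice (i,j,k)
  auto fpos = [&](int c, int i, int j, int k, double* p) {
    p[0] = G.x0 + (c == 0 ? i : i + 0.5) * h;
    p[1] = G.y0 + (c == 1 ? j : j + 0.5) * h;
    p[2] = G.z0 + (c == 2 ? k : k + 0.5) * h;
  };

  // build face states and free-face stencils
  std::vector<double> inQ(nin, 0.0);  // discrete plug flux per inlet (base profile)
  for (int c = 0; c < 3; ++c) {
    CompData& D = comp[c];
    D.state.assign((size_t)D.nx * D.ny * D.nz, 0);
    D.fixedBase.assign(D.state.size(), 0.0);
    int di = (c == 0), dj = (c == 1), dk = (c == 2);
    for (int k = dk; k < D.nz - dk; ++k)
      for (int j = dj; j < D.ny - dj; ++j)
        for (int i = di; i < D.nx - di; ++i) {
          // face (i,j,k) of component c lies between cells (i-di,j-dj,k-dk)
          // and (i,j,k) on the cell grid
          size_t cL = G.cidx(i - di, j - dj, k - dk), cR = G.cidx(i, j, k);
          int tL = cls[cL], tR = cls[cR];
          size_t f = D.fidx(i, j, k);
          if (tL == 0 || tR == 0) { D.state[f] = 0; continue; }
          if (tL >= 10 || tR >= 10) {
            D.state[f] = 2;
            int q = (tL >= 10 ? tL : tR) - 10;
            double p[3];
            fpos(c, i, j, k, p);
            double rx = p[0] - inCen[3 * q], ry = p[1] - inCen[3 * q + 1],
                   rz = p[2] - inCen[3 * q + 2];
            const double* a = &inAx[3 * q];
            double s = rx * a[0] + ry * a[1] + rz * a[2];
            double qx = rx - s * a[0], qy = ry - s * a[1], qz = rz - s * a[2];
            double r2 = (qx * qx + qy * qy + qz * qz) / (inR[q] * inR[q]);
            double vmag = 2.0 * inV[q] * std::max(0.0, 1.0 - r2);
            D.fixedBase[f] = vmag * a[c];
            D.fixedIdx.push_back((int)f);
          } else {
            D.state[f] = 1;
          }
        }
  }

  // rescale plug profiles so the discrete influx equals vbar * pi R^2 exactly:
  // measure base flux through plug->free interface faces per inlet
  {
    std::vector<double> qbase(nin, 0.0);
    for (int c = 0; c < 3; ++c) {
      CompData& D = comp[c];
      int di = (c == 0), dj = (c == 1), dk = (c == 2);
      for (int f : D.fixedIdx) {
        int k = f / (D.nx * D.ny), j = (f / D.nx) % D.ny, i = f % D.nx;
        size_t cL = G.cidx(i - di, j - dj, k - dk), cR = G.cidx(i, j, k);
        int tL = cls[cL], tR = cls[cR];
        int q = -1; double sgn = 0.0;
        if (tL >= 10 && (tR == 1 || tR == 2)) { q = tL - 10; sgn = 1.0; }
        if (tR >= 10 && (tL == 1 || tL == 2)) { q = tR - 10; sgn = -1.0; }
        if (q >= 0) qbase[q] += sgn * D.fixedBase[f] * h * h;
      }
    }
    for (int c = 0; c < 3; ++c) {
      CompData& D = comp[c];
      int di = (c == 0), dj = (c == 1), dk = (c == 2);
      for (int f : D.fixedIdx) {
        int k = f / (D.nx * D.ny), j = (f / D.nx) % D.ny, i = f % D.nx;
        size_t cL = G.cidx(i - di, j - dj, k - dk), cR = G.cidx(i, j, k);
        int q = (cls[cL] >= 10 ? cls[cL] : cls[cR]) - 10;
        double target = inV[q] * M_PI * inR[q] * inR[q];
        if (std::fabs(qbase[q]) > 1e-30)
          D.fixedBase[f] *= target / qbase[q];
      }
    }
    for (int q = 0; q < nin; ++q) inQ[q] = inV[q] * M_PI * inR[q] * inR[q];
  }

  // free-face stencils with subcell wall coefficients
  const int offc[6][3] = { {1,0,0}, {-1,0,0}, {0,1,0}, {0,-1,0}, {0,0,1}, {0,0,-1} };
  for (int c = 0; c < 3; ++c) {
    CompData& D = comp[c];
    int di = (c == 0), dj = (c == 1), dk = (c == 2);
    for (int k = 0; k < D.nz; ++k)
      for (int j = 0; j < D.ny; ++j)
        for (int i = 0; i < D.nx; ++i) {
          size_t f = D.fidx(i, j, k);
          if (D.state[f] != 1) continue;
          FreeFace F;
          F.idx = (int)f; F.i = i; F.j = j; F.k = k;
          F.cL = (int)G.cidx(i - di, j - dj, k - dk);
          F.cR = (int)G.cidx(i, j, k);
          double p0[3];
          fpos(c, i, j, k, p0);
          for (int d = 0; d < 6; ++d) {
            int ii = i + offc[d][0], jj = j + offc[d][1], kk = k + offc[d][2];
            bool ok = ii >= 0 && jj >= 0 && kk >= 0 && ii < D.nx && jj < D.ny && kk < D.nz;
            size_t fn = ok ? D.fidx(ii, jj, kk) : 0;
            if (ok && D.state[fn] != 0) {
              F.nbr[d] = (int)fn; F.invAl[d] = 1.0f;
            } else {
              F.nbr[d] = -1;
              double p1[3] = { p0[0] + offc[d][0] * h, p0[1] + offc[d][1] * h,
                               p0[2] + offc[d][2] * h };
              double s0 = tree_sdf(vs, p0), s1 = tree_sdf(vs, p1);
              // wall crossing between the face sample point and its neighbour:
              // alpha = fraction of h from the face to the wall
              double a = (s0 < 0.0 && s1 > 0.0) ? -s0 / (s1 - s0) : 0.5;
              F.invAl[d] = (float)(1.0 / std::min(1.0, std::max(0.1, a)));
            }
          }
          // transverse advection stencils: the four faces of component a
          // bordering the two cells adjacent to this face
          for (int which = 0; which < 2; ++which) {
            int a = (c + 1 + which) % 3;
            const CompData& Da = comp[a];
            int dai = (a == 0), daj = (a == 1), dak = (a == 2);
            int iL = i - di, jL = j - dj, kL = k - dk;
            int* out = which == 0 ? F.advA : F.advB;
            out[0] = (int)Da.fidx(iL, jL, kL);
            out[1] = (int)Da.fidx(iL + dai, jL + daj, kL + dak);
            out[2] = (int)Da.fidx(i, j, k);
            out[3] = (int)Da.fidx(i + dai, j + daj, k + dak);
          }
          D.free.push_back(F);
        }
  }

  // pressure-solve stencil: neighbour compact index, -1 Neumann, -2 Dirichlet(0),
  // plus the staggered face index bordering the cell in each direction
  std::vector<int> pn(6 * (size_t)nfree);
  std::vector<int> pface(6 * (size_t)nfree);   // full-array face index per dir
  std::vector<int8_t> pcomp(6 * (size_t)nfree);
  {
    const int off[6][3] = { {1,0,0}, {-1,0,0}, {0,1,0}, {0,-1,0}, {0,0,1}, {0,0,-1} };
    for (int n = 0; n < nfree; ++n) {
      int cidx = freeCells[n];
      int k = cidx / (nx * ny), j = (cidx / nx) % ny, i = cidx % nx;
      for (int d = 0; d < 6; ++d) {
        int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
        int v = -1;
        if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz) {
          int tc = cls[G.cidx(ii, jj, kk)];
          if (tc == 1) v = cellNo[G.cidx(ii, jj, kk)];
          else if (tc == 2) v = -2;          // outlet buffer: phi = 0
          else v = -1;                        // solid or plug: zero-flux
        }
        pn[6 * (size_t)n + d] = v;
        int c = d / 2;                        // face component
        // bounding faces of cell (i,j,k): lower face (i,j,k), upper (i+e_c)
        int fi = i + (d == 0), fj = j + (d == 2), fk = k + (d == 4);
        pface[6 * (size_t)n + d] = (int)comp[c].fidx(fi, fj, fk);
        pcomp[6 * (size_t)n + d] = (int8_t)c;
      }
    }
  }
  // implicit-coefficient arrays per staggered face (1/s); huge on non-free
  // faces so that the projection coefficient there is ~0 (prescribed flux)
  std::vector<double> Bu(U.size(), 1e30), Bv(V.size(), 1e30), Bw(W.size(), 1e30);
  double* Barr[3] = { Bu.data(), Bv.data(), Bw.data() };
  // per-cell projection coefficients, rebuilt every step
  std::vector<double> thC(6 * (size_t)nfree);

  // outlet flux faces (free <-> outlet) for Q_out monitoring
  struct FluxFace { int comp; int idx; double sgn; };
  std::vector<FluxFace> outFaces, inFaces;
  {
    for (int c = 0; c < 3; ++c) {
      CompData& D = comp[c];
      int di = (c == 0), dj = (c == 1), dk = (c == 2);
      for (int k = dk; k < D.nz - dk; ++k)
        for (int j = dj; j < D.ny - dj; ++j)
          for (int i = di; i < D.nx - di; ++i) {
            if (c == 0 && (i < 1 || i > nx - 1)) continue;
            if (c == 1 && (j < 1 || j > ny - 1)) continue;
            if (c == 2 && (k < 1 || k > nz - 1)) continue;
            size_t f = D.fidx(i, j, k);
            if (D.state[f] == 0) continue;
            int tL = cls[G.cidx(i - di, j - dj, k - dk)], tR = cls[G.cidx(i, j, k)];
            if (tL == 1 && tR == 2) outFaces.push_back({ c, (int)f, 1.0 });
            else if (tL == 2 && tR == 1) outFaces.push_back({ c, (int)f, -1.0 });
            if (tL >= 10 && (tR == 1 || tR == 2)) inFaces.push_back({ c, (int)f, 1.0 });
            else if (tR >= 10 && (tL == 1 || tL == 2)) inFaces.push_back({ c, (int)f, -1.0 });
          }
    }
  }

  double* Uarr[3] = { U.data(), V.data(), W.data() };
  double* Narr[3] = { Un.data(), Vn.data(), Wn.data() };
  double* Marr[3] = { muFu.data(), muFv.data(), muFw.data() };

  // subcell wall distances from each fluid cell centre (fractions of h per
  // direction), used for one-sided shear-rate stencils at the wall
  std::vector<int> fluidNo(ncell, -1);
  for (size_t n = 0; n < allFluid.size(); ++n) fluidNo[allFluid[n]] = (int)n;
  std::vector<float> cellAl(6 * allFluid.size(), 1.0f);
  {
    const int off[6][3] = { {1,0,0}, {-1,0,0}, {0,1,0}, {0,-1,0}, {0,0,1}, {0,0,-1} };
    for (size_t n = 0; n < allFluid.size(); ++n) {
      int cidx = allFluid[n];
      int k = cidx / (nx * ny), j = (cidx / nx) % ny, i = cidx % nx;
      double p0[3] = { G.x0 + (i + 0.5) * h, G.y0 + (j + 0.5) * h,
                       G.z0 + (k + 0.5) * h };
      for (int d = 0; d < 6; ++d) {
        int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
        bool solid = ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                     kk >= nz || cls[G.cidx(ii, jj, kk)] == 0;
        if (!solid) continue;
        double p1[3] = { p0[0] + off[d][0] * h, p0[1] + off[d][1] * h,
                         p0[2] + off[d][2] * h };
        double s0 = tree_sdf(vs, p0), s1 = tree_sdf(vs, p1);
        double a = (s0 < 0.0 && s1 > 0.0) ? -s0 / (s1 - s0) : 0.5;
        cellAl[6 * n + d] = (float)std::min(1.0, std::max(0.1, a));
      }
    }
  }

  // cell-centred shear rate and viscosity from current MAC field.
  // Cross-derivatives near walls use a quadratic one-sided stencil anchored
  // at the subcell wall position (no-slip), which avoids the systematic
  // shear-rate underestimation of a plain zero-ghost.
  auto update_visc = [&]() {
    for (size_t n = 0; n < allFluid.size(); ++n) {
      int cidx = allFluid[n];
      int k = cidx / (nx * ny), j = (cidx / nx) % ny, i = cidx % nx;
      auto solid_at = [&](int ii, int jj, int kk) -> bool {
        return ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz ||
               cls[G.cidx(ii, jj, kk)] == 0;
      };
      auto uc = [&](int ii, int jj, int kk) -> double {
        return 0.5 * (U[comp[0].fidx(ii, jj, kk)] + U[comp[0].fidx(ii + 1, jj, kk)]);
      };
      auto vc = [&](int ii, int jj, int kk) -> double {
        return 0.5 * (V[comp[1].fidx(ii, jj, kk)] + V[comp[1].fidx(ii, jj + 1, kk)]);
      };
      auto wc = [&](int ii, int jj, int kk) -> double {
        return 0.5 * (W[comp[2].fidx(ii, jj, kk)] + W[comp[2].fidx(ii, jj, kk + 1)]);
      };
      const float* al = &cellAl[6 * n];
      // derivative of a cell-centred quantity along axis a (dirs 2a/2a+1),
      // with the wall (value 0) at the subcell position where a neighbour
      // is solid; quadratic three-point formula at x = 0
      auto deriv = [&](int a, double f0, double fp, double fm,
                       bool sp, bool sm) -> double {
        double x2 = sp ? al[2 * a] * h : h;       // plus side
        double x1 = sm ? -al[2 * a + 1] * h : -h; // minus side
        double f2 = sp ? 0.0 : fp;
        double f1 = sm ? 0.0 : fm;
        if (sp && sm) return 0.0;
        return -f1 * x2 / (x1 * (x1 - x2)) - f0 * (x1 + x2) / (x1 * x2) -
               f2 * x1 / (x2 * (x2 - x1));
      };
      double u0 = uc(i, j, k), v0 = vc(i, j, k), w0 = wc(i, j, k);
      bool sxp = solid_at(i + 1, j, k), sxm = solid_at(i - 1, j, k);
      bool syp = solid_at(i, j + 1, k), sym = solid_at(i, j - 1, k);
      bool szp = solid_at(i, j, k + 1), szm = solid_at(i, j, k - 1);
      double dudx = (U[comp[0].fidx(i + 1, j, k)] - U[comp[0].fidx(i, j, k)]) / h;
      double dvdy = (V[comp[1].fidx(i, j + 1, k)] - V[comp[1].fidx(i, j, k)]) / h;
      double dwdz = (W[comp[2].fidx(i, j, k + 1)] - W[comp[2].fidx(i, j, k)]) / h;
      double dudy = deriv(1, u0, syp ? 0 : uc(i, j + 1, k), sym ? 0 : uc(i, j - 1, k), syp, sym);
      double dudz = deriv(2, u0, szp ? 0 : uc(i, j, k + 1), szm ? 0 : uc(i, j, k - 1), szp, szm);
      double dvdx = deriv(0, v0, sxp ? 0 : vc(i + 1, j, k), sxm ? 0 : vc(i - 1, j, k), sxp, sxm);
      double dvdz = deriv(2, v0, szp ? 0 : vc(i, j, k + 1), szm ? 0 : vc(i, j, k - 1), szp, szm);
      double dwdx = deriv(0, w0, sxp ? 0 : wc(i + 1, j, k), sxm ? 0 : wc(i - 1, j, k), sxp, sxm);
      double dwdy = deriv(1, w0, syp ? 0 : wc(i, j + 1, k), sym ? 0 : wc(i, j - 1, k), syp, sym);
      double g2 = 2.0 * (dudx * dudx + dvdy * dvdy + dwdz * dwdz) +
                  (dudy + dvdx) * (dudy + dvdx) + (dudz + dwdx) * (dudz + dwdx) +
                  (dvdz + dwdy) * (dvdz + dwdy);
      double g = std::sqrt(std::max(0.0, g2));
      gamCell[cidx] = g;
      muCell[cidx] = C.mu(g);
    }
    // face viscosities (average of adjacent cells; solid side uses fluid value)
    for (int c = 0; c < 3; ++c) {
      CompData& D = comp[c];
      int di = (c == 0), dj = (c == 1), dk = (c == 2);
      for (const FreeFace& F : D.free) {
        double mL = muCell[F.cL], mR = muCell[F.cR];
        Marr[c][F.idx] = 0.5 * (mL + mR);
      }
      for (int f : D.fixedIdx) {
        int k = f / (D.nx * D.ny), j = (f / D.nx) % D.ny, i = f % D.nx;
        size_t cL = G.cidx(i - di, j - dj, k - dk), cR = G.cidx(i, j, k);
        Marr[c][f] = 0.5 * (muCell[cL] + muCell[cR]);
      }
    }
  };
  update_visc();

  // Projection operator A = -div(theta grad), theta = (dt/rho)/(1 + dt B)
  // per face (SIMPLE-style, so the steady state is independent of dt).
  // Preconditioner: geometric multigrid on the masked domain with Galerkin
  // (piecewise-constant transfer) coarsening and damped-Jacobi smoothing;
  // topology is built once, weights are refreshed with theta every step.
  std::vector<double> cg_r(nfree), cg_p(nfree), cg_Ap(nfree), cg_z(nfree),
      bdiv(nfree), phiPrev(nfree, 0.0);

  struct MGLvl {
    int nx, ny, nz, ncell;
    std::vector<int> nbr;          // 6*ncell compact nbr, -1 none, -2 Dirichlet
    std::vector<double> w;         // 6*ncell link weights
    std::vector<double> diag;      // sum of links + Dirichlet weights
    std::vector<int> parent;       // compact -> next-level compact
    std::vector<double> x, b, tmp;
  };
  std::vector<MGLvl> mg;
  {
    // level 0 topology mirrors the free-cell stencil
    MGLvl l0;
    l0.nx = nx; l0.ny = ny; l0.nz = nz; l0.ncell = nfree;
    l0.nbr = pn;
    mg.push_back(std::move(l0));
    std::vector<std::vector<int>> coords(1);  // full-grid cell index per level
    coords[0] = freeCells;
    int lev = 0;
    while (mg[lev].ncell > 300 && lev < 6) {
      MGLvl& A = mg[lev];
      MGLvl C;
      C.nx = (A.nx + 1) / 2; C.ny = (A.ny + 1) / 2; C.nz = (A.nz + 1) / 2;
      std::vector<int> cNo((size_t)C.nx * C.ny * C.nz, -1);
      std::vector<int> cCells;
      A.parent.resize(A.ncell);
      for (int n = 0; n < A.ncell; ++n) {
        int cidx = coords[lev][n];
        int k = cidx / (A.nx * A.ny), j = (cidx / A.nx) % A.ny, i = cidx % A.nx;
        int cc = (i / 2) + C.nx * ((j / 2) + C.ny * (k / 2));
        if (cNo[cc] < 0) { cNo[cc] = (int)cCells.size(); cCells.push_back(cc); }
        A.parent[n] = cNo[cc];
      }
      C.ncell = (int)cCells.size();
      C.nbr.assign(6 * (size_t)C.ncell, -1);
      const int off[6][3] = { {1,0,0}, {-1,0,0}, {0,1,0}, {0,-1,0}, {0,0,1}, {0,0,-1} };
      for (int n = 0; n < C.ncell; ++n) {
        int cidx = cCells[n];
        int k = cidx / (C.nx * C.ny), j = (cidx / C.nx) % C.ny, i = cidx % C.nx;
        for (int d = 0; d < 6; ++d) {
          int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= C.nx || jj >= C.ny || kk >= C.nz)
            continue;
          int m = cNo[ii + C.nx * (jj + C.ny * kk)];
          if (m >= 0) C.nbr[6 * (size_t)n + d] = m;
        }
      }
      coords.push_back(std::move(cCells));
      mg.push_back(std::move(C));
      ++lev;
    }
    for (MGLvl& L : mg) {
      L.w.assign(6 * (size_t)L.ncell, 0.0);
      L.diag.assign(L.ncell, 0.0);
      L.x.assign(L.ncell, 0.0);
      L.b.assign(L.ncell, 0.0);
      L.tmp.assign(L.ncell, 0.0);
    }
  }

  auto update_theta = [&](double dt) {
    const double ih2 = 1.0 / (h * h);
    for (int n = 0; n < nfree; ++n) {
      const int* pf = &pface[6 * (size_t)n];
      const int8_t* pc = &pcomp[6 * (size_t)n];
      const int* nb = &pn[6 * (size_t)n];
      double* th = &thC[6 * (size_t)n];
      for (int d = 0; d < 6; ++d) {
        if (nb[d] == -1) { th[d] = 0.0; continue; }  // wall/plug: no correction
        double B = Barr[pc[d]][pf[d]];
        th[d] = (dt / rho) / (1.0 + dt * B) * ih2;
      }
    }
    // refresh multigrid weights by Galerkin accumulation
    {
      MGLvl& L0 = mg[0];
      for (int n = 0; n < nfree; ++n) {
        const double* th = &thC[6 * (size_t)n];
        const int* nb = &pn[6 * (size_t)n];
        double dg = 0.0;
        for (int d = 0; d < 6; ++d) {
          L0.w[6 * (size_t)n + d] = (nb[d] >= 0) ? th[d] : 0.0;
          if (nb[d] != -1) dg += th[d];
        }
        L0.diag[n] = dg;
      }
      for (size_t l = 0; l + 1 < mg.size(); ++l) {
        MGLvl& A = mg[l];
        MGLvl& C = mg[l + 1];
        std::fill(C.w.begin(), C.w.end(), 0.0);
        std::fill(C.diag.begin(), C.diag.end(), 0.0);
        for (int n = 0; n < A.ncell; ++n) {
          int p = A.parent[n];
          const int* nb = &A.nbr[6 * (size_t)n];
          const double* w = &A.w[6 * (size_t)n];
          double dgx = A.diag[n];
          for (int d = 0; d < 6; ++d) {
            if (nb[d] >= 0) {
              dgx -= w[d];  // strip link weights; re-added for cut links below
              if (A.parent[nb[d]] != p) C.w[6 * (size_t)p + d] += w[d];
            }
          }
          // dgx now holds Dirichlet-type excess; carry it to the coarse diag
          C.diag[p] += dgx;
        }
        for (int n = 0; n < C.ncell; ++n) {
          double dg = C.diag[n];
          for (int d = 0; d < 6; ++d) dg += C.w[6 * (size_t)n + d];
          C.diag[n] = dg;
        }
      }
    }
    (void)ih2;
  };

  // damped-Jacobi smoothing on one level
  auto mgSmooth = [&](MGLvl& L, int sweeps) {
    const double om = 0.8;
    for (int s = 0; s < sweeps; ++s) {
      for (int n = 0; n < L.ncell; ++n) {
        const int* nb = &L.nbr[6 * (size_t)n];
        const double* w = &L.w[6 * (size_t)n];
        double off = 0.0;
        for (int d = 0; d < 6; ++d)
          if (nb[d] >= 0) off += w[d] * L.x[nb[d]];
        double dg = L.diag[n];
        L.tmp[n] = (dg > 0.0) ? L.x[n] + om * (L.b[n] - (dg * L.x[n] - off)) / dg : 0.0;
      }
      std::swap(L.x, L.tmp);
    }
  };

  std::function<void(size_t)> mgCycle = [&](size_t l) {
    MGLvl& L = mg[l];
    std::fill(L.x.begin(), L.x.end(), 0.0);
    if (l + 1 == mg.size()) { mgSmooth(L, 40); return; }
    mgSmooth(L, 2);
    MGLvl& C = mg[l + 1];
    std::fill(C.b.begin(), C.b.end(), 0.0);
    for (int n = 0; n < L.ncell; ++n) {
      const int* nb = &L.nbr[6 * (size_t)n];
      const double* w = &L.w[6 * (size_t)n];
      double off = 0.0;
      for (int d = 0; d < 6; ++d)
        if (nb[d] >= 0) off += w[d] * L.x[nb[d]];
      double res = L.b[n] - (L.diag[n] * L.x[n] - off);
      C.b[L.parent[n]] += res;
    }
    mgCycle(l + 1);
    for (int n = 0; n < L.ncell; ++n) L.x[n] += C.x[L.parent[n]];
    mgSmooth(L, 2);
  };

  auto icSolve = [&](const std::vector<double>& r, std::vector<double>& z) {
    mg[0].b = r;
    mgCycle(0);
    z = mg[0].x;
  };

  auto applyA = [&](const std::vector<double>& x, std::vector<double>& y) {
    for (int n = 0; n < nfree; ++n) {
      double diag = 0.0, off = 0.0;
      const int* nb = &pn[6 * (size_t)n];
      const double* th = &thC[6 * (size_t)n];
      for (int d = 0; d < 6; ++d) {
        int m = nb[d];
        if (m == -1) continue;
        diag += th[d];
        if (m >= 0) off += th[d] * x[m];
      }
      y[n] = diag * x[n] - off;
    }
  };

  // history records
  std::vector<double> rec_t, rec_sawss, rec_als, rec_qin, rec_qout, rec_umax,
      rec_maxdiv, rec_cg, rec_dt;
  std::vector<double> gW, tW, mW;

  auto probe_stats = [&](double& sawss, double& als) {
    wss_probes(G, U.data(), V.data(), W.data(), muCell.data(), cls,
               probeCen, probeNrm, h, 2.0 * h, C, gW, tW, mW);
    double aw = 0.0, num = 0.0, alow = 0.0;
    for (int t = 0; t < (int)tW.size(); ++t) {
      if (!probeWall[t]) continue;
      aw += probeArea[t];
      num += tW[t] * probeArea[t];
      if (tW[t] < wss_thr) alow += probeArea[t];
    }
    sawss = (aw > 0) ? num / aw : 0.0;
    als = (aw > 0) ? 100.0 * alow / aw : 0.0;
  };

  double t = 0.0, dt = dt_max;
  int step = 0, lastCG = 0;
  bool converged = false;
  double maxdiv = 0.0;
  double totQin = 0.0;
  for (int q = 0; q < nin; ++q) totQin += inQ[q];
  double uref = 0.0;
  for (int q = 0; q < nin; ++q) uref = std::max(uref, 2.0 * inV[q]);
  if (uref <= 0.0) uref = 1e-6;
  double next_check = check_dt;

  while (t < t_max - 1e-12) {
    // adaptive dt from the convective CFL (diffusion is point-implicit);
    // use the collocated per-cell speed sum |u|+|v|+|w|, the actual upwind limit
    if (step % 25 == 0) {
      double smax = uref;
      for (int n = 0; n < nfree; ++n) {
        int cidx = freeCells[n];
        int k = cidx / (nx * ny), j = (cidx / nx) % ny, i = cidx % nx;
        double su = std::fabs(U[comp[0].fidx(i, j, k)] + U[comp[0].fidx(i + 1, j, k)]) +
                    std::fabs(V[comp[1].fidx(i, j, k)] + V[comp[1].fidx(i, j + 1, k)]) +
                    std::fabs(W[comp[2].fidx(i, j, k)] + W[comp[2].fidx(i, j, k + 1)]);
        if (0.5 * su > smax) smax = 0.5 * su;
      }
      dt = std::min(dt_max, cfl * h / smax);
    }
    double ramp = (ramp_t > 0.0) ? std::min(1.0, (t + dt) / ramp_t) : 1.0;

    // prescribed plug faces
    for (int c = 0; c < 3; ++c)
      for (int f : comp[c].fixedIdx) {
        Uarr[c][f] = ramp * comp[c].fixedBase[f];
        Narr[c][f] = Uarr[c][f];
      }

    if (step % visc_every == 0 && step > 0) update_visc();

    // momentum predictor: point-implicit upwind convection and variable-
    // viscosity diffusion (both unconditionally stable; the implicit factor
    // is saved per face and carried into the projection coefficients)
    for (int c = 0; c < 3; ++c) {
      CompData& D = comp[c];
      const double* X = Uarr[c];
      double* Xn = Narr[c];
      double* Bout = Barr[c];
      const double* MF = Marr[c];
      const double* YA = Uarr[(c + 1) % 3];
      const double* YB = Uarr[(c + 2) % 3];
      const double ih = 1.0 / h, ih2 = 1.0 / (h * h), irho = 1.0 / rho;
      for (const FreeFace& F : D.free) {
        const double x = X[F.idx];
        double adv[3];
        adv[c] = x;
        adv[(c + 1) % 3] = 0.25 * (YA[F.advA[0]] + YA[F.advA[1]] +
                                   YA[F.advA[2]] + YA[F.advA[3]]);
        adv[(c + 2) % 3] = 0.25 * (YB[F.advB[0]] + YB[F.advB[1]] +
                                   YB[F.advB[2]] + YB[F.advB[3]]);
        // explicit neighbour part Aex, implicit self part Bim (1/s);
        // convection: implicit first-order upwind plus an explicit deferred
        // central correction (blend sigma) for second-order accuracy
        double Aex = 0.0, Bim = 0.0;
        const double mu_self = MF[F.idx];
        for (int a = 0; a < 3; ++a) {
          const double ua = adv[a];
          const int dp = 2 * a, dm = 2 * a + 1;
          const int np = F.nbr[dp], nm = F.nbr[dm];
          const double xp = (np >= 0) ? X[np] : 0.0;
          const double xm = (nm >= 0) ? X[nm] : 0.0;
          // upwind: conv = |ua|/h * x - (inflow neighbour term)
          Bim += std::fabs(ua) * ih;
          Aex += (ua > 0.0) ? ua * xm * ih : -ua * xp * ih;
          // deferred correction: (central - upwind) from the old field
          const double conv_up = (ua > 0.0) ? ua * (x - xm) * ih
                                            : ua * (xp - x) * ih;
          const double conv_ce = ua * (xp - xm) * 0.5 * ih;
          Aex -= sigma_dc * (conv_ce - conv_up);
          const double mup = (np >= 0) ? 0.5 * (mu_self + MF[np]) : mu_self;
          const double mum = (nm >= 0) ? 0.5 * (mu_self + MF[nm]) : mu_self;
          const double cp = mup * F.invAl[dp] * ih2 * irho;
          const double cm = mum * F.invAl[dm] * ih2 * irho;
          Aex += cp * xp + cm * xm;
          Bim += cp + cm;
        }
        Bout[F.idx] = Bim;
        Xn[F.idx] = (x + dt * Aex) / (1.0 + dt * Bim);
      }
    }
    for (int c = 0; c < 3; ++c) {
      CompData& D = comp[c];
      for (const FreeFace& F : D.free) Uarr[c][F.idx] = Narr[c][F.idx];
    }

    // projection: solve  -div(theta grad phi) = -div(u*)
    {
      update_theta(dt);
      double bnorm = 0.0;
      for (int n = 0; n < nfree; ++n) {
        int cidx = freeCells[n];
        int k = cidx / (nx * ny), j = (cidx / nx) % ny, i = cidx % nx;
        double div = (U[comp[0].fidx(i + 1, j, k)] - U[comp[0].fidx(i, j, k)] +
                      V[comp[1].fidx(i, j + 1, k)] - V[comp[1].fidx(i, j, k)] +
                      W[comp[2].fidx(i, j, k + 1)] - W[comp[2].fidx(i, j, k)]) / h;
        bdiv[n] = -div;
        bnorm += bdiv[n] * bdiv[n];
      }
      bnorm = std::sqrt(bnorm);
      // warm start: linear extrapolation of the pressure from the last two steps
      for (int n = 0; n < nfree; ++n) {
        double g = 2.0 * phi[n] - phiPrev[n];
        phiPrev[n] = phi[n];
        phi[n] = g;
      }
      applyA(phi, cg_Ap);
      double rn2 = 0.0;
      for (int n = 0; n < nfree; ++n) {
        cg_r[n] = bdiv[n] - cg_Ap[n];
        rn2 += cg_r[n] * cg_r[n];
      }
      double tol2 = std::max(cg_tol * bnorm, 1e-300);
      tol2 *= tol2;
      int it = 0;
      if (rn2 > tol2) {
        icSolve(cg_r, cg_z);
        double rz = 0.0;
        for (int n = 0; n < nfree; ++n) { cg_p[n] = cg_z[n]; rz += cg_r[n] * cg_z[n]; }
        while (it < cg_maxit) {
          applyA(cg_p, cg_Ap);
          double pAp = 0.0;
          for (int n = 0; n < nfree; ++n) pAp += cg_p[n] * cg_Ap[n];
          if (pAp <= 0.0) break;
          double alpha = rz / pAp;
          rn2 = 0.0;
          for (int n = 0; n < nfree; ++n) {
            phi[n] += alpha * cg_p[n];
            cg_r[n] -= alpha * cg_Ap[n];
            rn2 += cg_r[n] * cg_r[n];
          }
          ++it;
          if (rn2 <= tol2) break;
          icSolve(cg_r, cg_z);
          double rznew = 0.0;
          for (int n = 0; n < nfree; ++n) rznew += cg_r[n] * cg_z[n];
          double beta = rznew / rz;
          rz = rznew;
          for (int n = 0; n < nfree; ++n) cg_p[n] = cg_z[n] + beta * cg_p[n];
        }
      }
      lastCG = it;
      // velocity correction on free faces with the same theta coefficients
      for (int n = 0; n < nfree; ++n) pFull[freeCells[n]] = phi[n];
      const double fac = dt / (rho * h);
      for (int c = 0; c < 3; ++c) {
        CompData& D = comp[c];
        const double* Bc = Barr[c];
        for (const FreeFace& F : D.free) {
          double phL = (cls[F.cL] == 1) ? pFull[F.cL] : 0.0;
          double phR = (cls[F.cR] == 1) ? pFull[F.cR] : 0.0;
          if (cls[F.cL] >= 10 || cls[F.cR] >= 10) continue;  // safety; plug faces are fixed
          Uarr[c][F.idx] -= fac / (1.0 + dt * Bc[F.idx]) * (phR - phL);
        }
      }
    }

    t += dt;
    ++step;
    if (t + 1e-12 >= next_check || t >= t_max - 1e-12) {
      next_check += check_dt;
      double sawss, als;
      probe_stats(sawss, als);
      double qin = 0.0, qout = 0.0;
      for (const FluxFace& ff : inFaces) qin += ff.sgn * Uarr[ff.comp][ff.idx] * h * h;
      for (const FluxFace& ff : outFaces) qout += ff.sgn * Uarr[ff.comp][ff.idx] * h * h;
      double um = 0.0;
      for (int c = 0; c < 3; ++c)
        for (const FreeFace& F : comp[c].free)
          um = std::max(um, std::fabs(Uarr[c][F.idx]));
      maxdiv = 0.0;
      for (int n = 0; n < nfree; ++n) {
        int cidx = freeCells[n];
        int k = cidx / (nx * ny), j = (cidx / nx) % ny, i = cidx % nx;
        double div = (U[comp[0].fidx(i + 1, j, k)] - U[comp[0].fidx(i, j, k)] +
                      V[comp[1].fidx(i, j + 1, k)] - V[comp[1].fidx(i, j, k)] +
                      W[comp[2].fidx(i, j, k + 1)] - W[comp[2].fidx(i, j, k)]) / h;
        maxdiv = std::max(maxdiv, std::fabs(div));
      }
      rec_t.push_back(t); rec_sawss.push_back(sawss); rec_als.push_back(als);
      rec_qin.push_back(qin); rec_qout.push_back(qout); rec_umax.push_back(um);
      rec_maxdiv.push_back(maxdiv); rec_cg.push_back(lastCG); rec_dt.push_back(dt);
      if (!std::isfinite(sawss) || !std::isfinite(um))
        stop("solver diverged (non-finite field)");
      // steady-state drift over a 0.5 s window
      if (t >= t_min) {
        double twin = t - 0.5;
        double s_prev = NA_REAL, a_prev = NA_REAL;
        for (size_t m = 0; m < rec_t.size(); ++m)
          if (rec_t[m] <= twin) { s_prev = rec_sawss[m]; a_prev = rec_als[m]; }
        if (R_finite(s_prev)) {
          double ds = std::fabs(sawss - s_prev) / std::max(1e-12, std::fabs(sawss));
          double da = std::fabs(als - a_prev);
          if (ds < drift_tol && da < als_tol) {
            converged = true;
            break;
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  (void)t_end;

  // final fields and probes
  update_visc();
  double sawss, als;
  probe_stats(sawss, als);
  double qin = 0.0, qout = 0.0;
  for (const FluxFace& ff : inFaces) qin += ff.sgn * Uarr[ff.comp][ff.idx] * h * h;
  for (const FluxFace& ff : outFaces) qout += ff.sgn * Uarr[ff.comp][ff.idx] * h * h;

  int nh = (int)rec_t.size();
  NumericMatrix hist(nh, 9);
  colnames(hist) = CharacterVector::create("t", "sa_wss", "als", "q_in", "q_out",
                                           "u_max", "max_div", "cg_iters", "dt");
  for (int m = 0; m < nh; ++m) {
    hist(m, 0) = rec_t[m]; hist(m, 1) = rec_sawss[m]; hist(m, 2) = rec_als[m];
    hist(m, 3) = rec_qin[m]; hist(m, 4) = rec_qout[m]; hist(m, 5) = rec_umax[m];
    hist(m, 6) = rec_maxdiv[m]; hist(m, 7) = rec_cg[m]; hist(m, 8) = rec_dt[m];
  }

  return List::create(
      _["u"] = wrap(U), _["v"] = wrap(V), _["w"] = wrap(W),
      _["p"] = wrap(pFull), _["mu"] = wrap(muCell), _["gamma"] = wrap(gamCell),
      _["wss"] = wrap(tW), _["gamma_w"] = wrap(gW), _["mu_nw"] = wrap(mW),
      _["sa_wss"] = sawss, _["als"] = als,
      _["q_in"] = qin, _["q_out"] = qout, _["q_in_target"] = totQin,
      _["hist"] = hist, _["converged"] = converged, _["t_final"] = t,
      _["n_steps"] = step, _["n_free_cells"] = nfree, _["max_div"] = maxdiv);
}
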