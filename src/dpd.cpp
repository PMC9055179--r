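// Core DPD engine: cell-list pair forces (conservative + dissipative +
// random), harmonic bond and angle-bending forces, Groot-Warren modified
// velocity-Verlet integration, Irving-Kirkwood slab-resolved pressure
// tensors, and periodic contact/occupancy helpers for the morphology
// classifier. Reduced units throughout: r_c = m = k_B T = 1.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based random numbers.
//
// The pairwise random force needs one symmetric (zeta_ij = zeta_ji) standard
// Gaussian per interacting pair per step, reproducible independently of the
// order in which the cell list visits pairs.  We derive each draw from a
// splitmix64 hash of (seed, step, sorted pair), so the stream is a pure
// function of those labels.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t h) {
  // strictly inside (0,1): shift to 53 bits, offset by half an ulp
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double pair_gauss(uint64_t seed, uint64_t step,
                                uint32_t i, uint32_t j) {
  if (i > j) std::swap(i, j);
  uint64_t k = splitmix64(seed ^ splitmix64(step + 0x632be59bd9b4e019ULL));
  uint64_t h1 = splitmix64(k ^ ((static_cast<uint64_t>(i) << 32) | j));
  uint64_t h2 = splitmix64(h1);
  return std::sqrt(-2.0 * std::log(u01(h1))) * std::cos(2.0 * M_PI * u01(h2));
}

// uniform direction on the sphere for the (rare) exactly-overlapping pair
static inline void rand_dir(uint64_t seed, uint64_t step, uint32_t i, uint32_t j,
                            double* e) {
  uint64_t h = splitmix64(seed ^ splitmix64(step) ^
                          splitmix64(0xabcdef12ULL + (static_cast<uint64_t>(i) << 32) + j));
  double z = 2.0 * u01(h) - 1.0;
  uint64_t h2 = splitmix64(h);
  double phi = 2.0 * M_PI * u01(h2);
  double s = std::sqrt(std::max(0.0, 1.0 - z * z));
  e[0] = s * std::cos(phi); e[1] = s * std::sin(phi); e[2] = z;
}

// ---------------------------------------------------------------------------
// Minimum image

static inline double min_image(double d, double L) {
  if (d >  0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

static inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;            // guard against x/L rounding up
  if (x < 0) x = 0;
  return x;
}

// ---------------------------------------------------------------------------
// Cell list over a cubic periodic box; cell width >= cutoff (=1 r_c).

struct CellList {
  int nc;            // cells per side
  double w;          // cell width
  std::vector<int> head, next;

  void build(int N, const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double L, double cutoff) {
    nc = std::max(1, static_cast<int>(std::floor(L / cutoff)));
    w = L / nc;
    head.assign(static_cast<size_t>(nc) * nc * nc, -1);
    next.assign(N, -1);
    for (int i = 0; i < N; ++i) {
      int cx = std::min(nc - 1, static_cast<int>(x[i] / w));
      int cy = std::min(nc - 1, static_cast<int>(y[i] / w));
      int cz = std::min(nc - 1, static_cast<int>(z[i] / w));
      int c = (cz * nc + cy) * nc + cx;
      next[i] = head[c];
      head[c] = i;
    }
  }
};

// half-shell of 13 neighbour cell offsets + self (self handled with i<j)
static const int HALF_SHELL[13][3] = {
  {1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}
};

// ---------------------------------------------------------------------------
// System arrays shared by the force/integration routines

struct System {
  int N;
  double L;
  std::vector<double> x, y, z, vx, vy, vz;
  std::vector<int> sp;                 // species index, 0-based
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> bks, brs;
  // angles (aj = apex)
  std::vector<int> ai, aj, ak;
  std::vector<double> akth, ath0;
};

struct Forces {
  std::vector<double> fx, fy, fz;
  double e_pair = 0, e_bond = 0, e_angle = 0;
  long n_overlap = 0;
  void reset(int N) {
    fx.assign(N, 0.0); fy.assign(N, 0.0); fz.assign(N, 0.0);
    e_pair = e_bond = e_angle = 0; n_overlap = 0;
  }
};

// non-bonded DPD pair forces via the cell list
static void pair_forces(const System& S,
                        const std::vector<double>& pvx,
                        const std::vector<double>& pvy,
                        const std::vector<double>& pvz,
                        const NumericMatrix& a,
                        double gamma, double sigma, double inv_sqrt_dt,
                        uint64_t seed, uint64_t step,
                        CellList& cl, Forces& F) {
  const double L = S.L, rc = 1.0;
  cl.build(S.N, S.x, S.y, S.z, L, rc);
  const int nc = cl.nc;
  const int nsp = a.nrow();

  auto eval_pair = [&](int i, int j) {
    double dx = min_image(S.x[i] - S.x[j], L);
    double dy = min_image(S.y[i] - S.y[j], L);
    double dz = min_image(S.z[i] - S.z[j], L);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc * rc) return;
    double aij = a(S.sp[i], S.sp[j]);
    double r = std::sqrt(r2);
    double ex, ey, ez;
    if (r < 1e-12) {
      double e[3]; rand_dir(seed, step, i, j, e);
      ex = e[0]; ey = e[1]; ez = e[2]; r = 0.0;
      ++F.n_overlap;
    } else { ex = dx / r; ey = dy / r; ez = dz / r; }
    double wr = 1.0 - r;
    double fmag = aij * wr;
    if (gamma > 0 || sigma > 0) {
      double dvx = pvx[i] - pvx[j];
      double dvy = pvy[i] - pvy[j];
      double dvz = pvz[i] - pvz[j];
      double rv = ex * dvx + ey * dvy + ez * dvz;
      fmag += -gamma * wr * wr * rv;
      if (sigma > 0)
        fmag += sigma * wr * pair_gauss(seed, step, i, j) * inv_sqrt_dt;
    }
    F.fx[i] += fmag * ex; F.fy[i] += fmag * ey; F.fz[i] += fmag * ez;
    F.fx[j] -= fmag * ex; F.fy[j] -= fmag * ey; F.fz[j] -= fmag * ez;
    F.e_pair += 0.5 * aij * wr * wr;
  };

  if (nc < 3) {                       // box too small for a half-shell sweep
    for (int i = 0; i < S.N; ++i)
      for (int j = i + 1; j < S.N; ++j) eval_pair(i, j);
    (void)nsp;
    return;
  }

  for (int cz = 0; cz < nc; ++cz)
    for (int cy = 0; cy < nc; ++cy)
      for (int cx = 0; cx < nc; ++cx) {
        int c = (cz * nc + cy) * nc + cx;
        for (int i = cl.head[c]; i >= 0; i = cl.next[i])
          for (int j = cl.next[i]; j >= 0; j = cl.next[j]) eval_pair(i, j);
        for (int s = 0; s < 13; ++s) {
          int ox = (cx + HALF_SHELL[s][0] + nc) % nc;
          int oy = (cy + HALF_SHELL[s][1] + nc) % nc;
          int oz = (cz + HALF_SHELL[s][2] + nc) % nc;
          int c2 = (oz * nc + oy) * nc + ox;
          for (int i = cl.head[c]; i >= 0; i = cl.next[i])
            for (int j = cl.head[c2]; j >= 0; j = cl.next[j]) eval_pair(i, j);
        }
      }
}

// harmonic bonds: U = (k_s/2)(r - r_s)^2
static void bond_forces(const System& S, Forces& F) {
  const double L = S.L;
  for (size_t b = 0; b < S.bi.size(); ++b) {
    int i = S.bi[b], j = S.bj[b];
    double dx = min_image(S.x[i] - S.x[j], L);
    double dy = min_image(S.y[i] - S.y[j], L);
    double dz = min_image(S.z[i] - S.z[j], L);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;                           // force undefined at r=0
    double dr = r - S.brs[b];
    double fmag = -S.bks[b] * dr / r;                  // along r_ij, on i
    F.fx[i] += fmag * dx; F.fy[i] += fmag * dy; F.fz[i] += fmag * dz;
    F.fx[j] -= fmag * dx; F.fy[j] -= fmag * dy; F.fz[j] -= fmag * dz;
    F.e_bond += 0.5 * S.bks[b] * dr * dr;
  }
}

// angle bending: U = k_theta (theta - theta0)^2, apex at j
static void angle_forces(const System& S, Forces& F) {
  const double L = S.L;
  for (size_t t = 0; t < S.ai.size(); ++t) {
    int i = S.ai[t], j = S.aj[t], k = S.ak[t];
    double ux = min_image(S.x[i] - S.x[j], L);
    double uy = min_image(S.y[i] - S.y[j], L);
    double uz = min_image(S.z[i] - S.z[j], L);
    double wx = min_image(S.x[k] - S.x[j], L);
    double wy = min_image(S.y[k] - S.y[j], L);
    double wz = min_image(S.z[k] - S.z[j], L);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
    if (nu < 1e-12 || nw < 1e-12) continue;
    double c = (ux * wx + uy * wy + uz * wz) / (nu * nw);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dth = th - S.ath0[t];
    F.e_angle += S.akth[t] * dth * dth;
    double dU = 2.0 * S.akth[t] * dth;                 // dU/dtheta
    double s = std::sqrt(std::max(1.0 - c * c, 1e-16)); // clamped sin(theta)
    double coef = dU / s;
    // dcos/dr_i = (w_hat - c u_hat)/|u| ; F_i = coef * dcos/dr_i
    double fix = coef * (wx / nw - c * ux / nu) / nu;
    double fiy = coef * (wy / nw - c * uy / nu) / nu;
    double fiz = coef * (wz / nw - c * uz / nu) / nu;
    double fkx = coef * (ux / nu - c * wx / nw) / nw;
    double fky = coef * (uy / nu - c * wy / nw) / nw;
    double fkz = coef * (uz / nu - c * wz / nw) / nw;
    F.fx[i] += fix; F.fy[i] += fiy; F.fz[i] += fiz;
    F.fx[k] += fkx; F.fy[k] += fky; F.fz[k] += fkz;
    F.fx[j] -= fix + fkx; F.fy[j] -= fiy + fky; F.fz[j] -= fiz + fkz;
  }
}

static System make_system(NumericMatrix pos, NumericMatrix vel,
                          IntegerVector species0, double L,
                          IntegerMatrix bonds, NumericVector bks, NumericVector brs,
                          IntegerMatrix angles, NumericVector akth, NumericVector ath0) {
  System S;
  S.N = pos.nrow(); S.L = L;
  S.x.resize(S.N); S.y.resize(S.N); S.z.resize(S.N);
  S.vx.resize(S.N); S.vy.resize(S.N); S.vz.resize(S.N);
  S.sp.resize(S.N);
  for (int i = 0; i < S.N; ++i) {
    S.x[i] = wrap(pos(i, 0), L); S.y[i] = wrap(pos(i, 1), L); S.z[i] = wrap(pos(i, 2), L);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.sp[i] = species0[i];
  }
  int nb = bonds.nrow();
  S.bi.resize(nb); S.bj.resize(nb); S.bks.resize(nb); S.brs.resize(nb);
  for (int b = 0; b < nb; ++b) {
    S.bi[b] = bonds(b, 0); S.bj[b] = bonds(b, 1);
    S.bks[b] = bks[b]; S.brs[b] = brs[b];
  }
  int na = angles.nrow();
  S.ai.resize(na); S.aj.resize(na); S.ak.resize(na);
  S.akth.resize(na); S.ath0.resize(na);
  for (int t = 0; t < na; ++t) {
    S.ai[t] = angles(t, 0); S.aj[t] = angles(t, 1); S.ak[t] = angles(t, 2);
    S.akth[t] = akth[t]; S.ath0[t] = ath0[t];
  }
  return S;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, IntegerVector species0,
                double L, NumericMatrix a,
                IntegerMatrix bonds, NumericVector bond_ks, NumericVector bond_rs,
                IntegerMatrix angles, NumericVector angle_k, NumericVector angle_t0,
                double gamma, double sigma, double dt,
                double seed, double step) {
  System S = make_system(pos, vel, species0, L, bonds, bond_ks, bond_rs,
                         angles, angle_k, angle_t0);
  Forces F; F.reset(S.N);
  CellList cl;
  double isdt = (dt > 0) ? 1.0 / std::sqrt(dt) : 0.0;
  pair_forces(S, S.vx, S.vy, S.vz, a, gamma, sigma, isdt,
              static_cast<uint64_t>(seed), static_cast<uint64_t>(step), cl, F);
  bond_forces(S, F);
  angle_forces(S, F);
  NumericMatrix out(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    out(i, 0) = F.fx[i]; out(i, 1) = F.fy[i]; out(i, 2) = F.fz[i];
  }
  return List::create(_["force"] = out, _["e_pair"] = F.e_pair,
                      _["e_bond"] = F.e_bond, _["e_angle"] = F.e_angle,
                      _["n_overlap"] = F.n_overlap);
}

// Groot-Warren modified velocity-Verlet (lambda = 0.5):
//   r(t+dt)   = r + dt v + dt^2/2 f
//   v~        = v + lambda dt f           (predictor fed to F^D)
//   f(t+dt)   = F(r(t+dt), v~)
//   v(t+dt)   = v + dt/2 (f(t) + f(t+dt))
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector species0,
             double L, NumericMatrix a,
             IntegerMatrix bonds, NumericVector bond_ks, NumericVector bond_rs,
             IntegerMatrix angles, NumericVector angle_k, NumericVector angle_t0,
             double gamma, double sigma, double dt,
             int n_steps, double seed, int report_every, int traj_every,
             double lambda = 0.5) {
  System S = make_system(pos, vel, species0, L, bonds, bond_ks, bond_rs,
                         angles, angle_k, angle_t0);
  const int N = S.N;
  Forces F, F2; F.reset(N); F2.reset(N);
  CellList cl;
  double isdt = (dt > 0) ? 1.0 / std::sqrt(dt) : 0.0;
  uint64_t sd = static_cast<uint64_t>(seed);

  std::vector<double> px(N), py(N), pz(N);             // velocity predictor

  pair_forces(S, S.vx, S.vy, S.vz, a, gamma, sigma, isdt, sd, 0, cl, F);
  bond_forces(S, F);
  angle_forces(S, F);

  int n_reports = (report_every > 0) ? n_steps / report_every : 0;
  NumericMatrix trace(n_reports, 6);   // step, e_pair, e_bond, e_angle, T_kin, total overlaps
  List frames;
  long overlaps = 0;
  int rep = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < N; ++i) {
      S.x[i] = wrap(S.x[i] + dt * S.vx[i] + 0.5 * dt * dt * F.fx[i], L);
      S.y[i] = wrap(S.y[i] + dt * S.vy[i] + 0.5 * dt * dt * F.fy[i], L);
      S.z[i] = wrap(S.z[i] + dt * S.vz[i] + 0.5 * dt * dt * F.fz[i], L);
      px[i] = S.vx[i] + lambda * dt * F.fx[i];
      py[i] = S.vy[i] + lambda * dt * F.fy[i];
      pz[i] = S.vz[i] + lambda * dt * F.fz[i];
    }
    F2.reset(N);
    pair_forces(S, px, py, pz, a, gamma, sigma, isdt, sd,
                static_cast<uint64_t>(step), cl, F2);
    bond_forces(S, F2);
    angle_forces(S, F2);
    overlaps += F2.n_overlap;
    for (int i = 0; i < N; ++i) {
      S.vx[i] += 0.5 * dt * (F.fx[i] + F2.fx[i]);
      S.vy[i] += 0.5 * dt * (F.fy[i] + F2.fy[i]);
      S.vz[i] += 0.5 * dt * (F.fz[i] + F2.fz[i]);
    }
    std::swap(F.fx, F2.fx); std::swap(F.fy, F2.fy); std::swap(F.fz, F2.fz);
    F.e_pair = F2.e_pair; F.e_bond = F2.e_bond; F.e_angle = F2.e_angle;

    if (report_every > 0 && step % report_every == 0) {
      double ke = 0;
      for (int i = 0; i < N; ++i)
        ke += S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i];
      if (!std::isfinite(ke) || !std::isfinite(F.e_pair + F.e_bond + F.e_angle)) {
        for (int i = 0; i < N; ++i)
          if (!std::isfinite(S.x[i] + S.y[i] + S.z[i] + S.vx[i] + S.vy[i] + S.vz[i]))
            stop("non-finite position/velocity at step %d, bead %d", step, i + 1);
        stop("non-finite energy at step %d", step);
      }
      trace(rep, 0) = step;
      trace(rep, 1) = F.e_pair;
      trace(rep, 2) = F.e_bond;
      trace(rep, 3) = F.e_angle;
      trace(rep, 4) = ke / (3.0 * N);
      trace(rep, 5) = static_cast<double>(overlaps);
      ++rep;
    }
    if (traj_every > 0 && step % traj_every == 0) {
      NumericMatrix fp(N, 3), fv(N, 3);
      for (int i = 0; i < N; ++i) {
        fp(i, 0) = S.x[i]; fp(i, 1) = S.y[i]; fp(i, 2) = S.z[i];
        fv(i, 0) = S.vx[i]; fv(i, 1) = S.vy[i]; fv(i, 2) = S.vz[i];
      }
      frames.push_back(List::create(_["step"] = step, _["pos"] = fp, _["vel"] = fv));
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix opos(N, 3), ovel(N, 3);
  for (int i = 0; i < N; ++i) {
    opos(i, 0) = S.x[i]; opos(i, 1) = S.y[i]; opos(i, 2) = S.z[i];
    ovel(i, 0) = S.vx[i]; ovel(i, 1) = S.vy[i]; ovel(i, 2) = S.vz[i];
  }
  return List::create(_["pos"] = opos, _["vel"] = ovel, _["trace"] = trace,
                      _["frames"] = frames);
}

// ---------------------------------------------------------------------------
// Irving-Kirkwood slab-resolved diagonal pressure tensor (IK-1 contour).
//
// Each pairwise contribution F_ij (x_i - x_j) is spread over the slabs the
// i-j minimum-image segment crosses, in proportion to the path length in
// each slab.  Angle terms are decomposed into two pair-like contributions
// (i,apex) and (k,apex), which reproduces their exact virial.  The kinetic
// part m v_a^2 goes to the slab holding the bead.  Per-group decomposition
// assigns half of each pair term to each bead's group.

struct StressAcc {
  int nbins, ngroups, axis;
  double L, dz;
  std::vector<double> kin, vir;         // [bin + nbins*(comp + 3*group)]
  double gkin[3] = {0, 0, 0}, gvir[3] = {0, 0, 0};

  void init(int nb, int ng, int ax, double Lbox) {
    nbins = nb; ngroups = ng; axis = ax; L = Lbox; dz = L / nb;
    kin.assign(static_cast<size_t>(nb) * 3 * ng, 0.0);
    vir.assign(static_cast<size_t>(nb) * 3 * ng, 0.0);
  }
  inline int bin_of(double s) const {
    int b = static_cast<int>(std::floor(wrap(s, L) / dz));
    return std::min(b, nbins - 1);
  }
  // spread weight w (per component) along segment from s_j to s_j + d
  void add_pair(double si, double d, const double wcomp[3], int gi, int gj) {
    for (int c = 0; c < 3; ++c) gvir[c] += wcomp[c];
    double len = std::fabs(d);
    if (len < 1e-12) {
      int b = bin_of(si);
      for (int c = 0; c < 3; ++c) {
        vir[b + nbins * (c + 3 * gi)] += 0.5 * wcomp[c];
        vir[b + nbins * (c + 3 * gj)] += 0.5 * wcomp[c];
      }
      return;
    }
    double lo = (d > 0) ? si - d : si;         // segment [lo, lo+len] (unwrapped)
    double s = lo;
    double remaining = len;
    while (remaining > 1e-14) {
      double sw = wrap(s, L);
      int b = std::min(static_cast<int>(std::floor(sw / dz)), nbins - 1);
      double edge = (b + 1) * dz;
      double seg = std::min(remaining, edge - sw);
      if (seg <= 0) seg = std::min(remaining, dz);   // guard fp edge case
      double frac = seg / len;
      for (int c = 0; c < 3; ++c) {
        double v = frac * wcomp[c];
        vir[b + nbins * (c + 3 * gi)] += 0.5 * v;
        vir[b + nbins * (c + 3 * gj)] += 0.5 * v;
      }
      s += seg;
      remaining -= seg;
    }
  }
};

// [[Rcpp::export]]
List cpp_stress_frame(NumericMatrix pos, NumericMatrix vel, IntegerVector species0,
                      double L, NumericMatrix a,
                      IntegerMatrix bonds, NumericVector bond_ks, NumericVector bond_rs,
                      IntegerMatrix angles, NumericVector angle_k, NumericVector angle_t0,
                      int axis, int nbins, IntegerVector group0, int ngroups) {
  System S = make_system(pos, vel, species0, L, bonds, bond_ks, bond_rs,
                         angles, angle_k, angle_t0);
  const int N = S.N;
  StressAcc A; A.init(nbins, ngroups, axis, L);

  // coordinate along the profile axis for bead i
  auto coord = [&](int i) {
    return axis == 0 ? S.x[i] : (axis == 1 ? S.y[i] : S.z[i]);
  };

  // kinetic part
  for (int i = 0; i < N; ++i) {
    int b = A.bin_of(coord(i));
    double v2[3] = {S.vx[i] * S.vx[i], S.vy[i] * S.vy[i], S.vz[i] * S.vz[i]};
    for (int c = 0; c < 3; ++c) {
      A.kin[b + nbins * (c + 3 * group0[i])] += v2[c];
      A.gkin[c] += v2[c];
    }
  }

  // conservative non-bonded pairs (cell list)
  CellList cl;
  cl.build(N, S.x, S.y, S.z, L, 1.0);
  const int nc = cl.nc;
  auto do_pair = [&](int i, int j) {
    double dx = min_image(S.x[i] - S.x[j], L);
    double dy = min_image(S.y[i] - S.y[j], L);
    double dz = min_image(S.z[i] - S.z[j], L);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= 1.0 || r2 < 1e-24) return;
    double r = std::sqrt(r2);
    double fmag = a(S.sp[i], S.sp[j]) * (1.0 - r) / r;  // F_i = fmag * r_ij
    double d[3] = {dx, dy, dz};
    double w[3] = {fmag * dx * dx, fmag * dy * dy, fmag * dz * dz};
    A.add_pair(coord(i), d[axis], w, group0[i], group0[j]);
  };
  if (nc < 3) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) do_pair(i, j);
  } else {
    for (int cz = 0; cz < nc; ++cz)
      for (int cy = 0; cy < nc; ++cy)
        for (int cx = 0; cx < nc; ++cx) {
          int c = (cz * nc + cy) * nc + cx;
          for (int i = cl.head[c]; i >= 0; i = cl.next[i])
            for (int j = cl.next[i]; j >= 0; j = cl.next[j]) do_pair(i, j);
          for (int s = 0; s < 13; ++s) {
            int ox = (cx + HALF_SHELL[s][0] + nc) % nc;
            int oy = (cy + HALF_SHELL[s][1] + nc) % nc;
            int oz = (cz + HALF_SHELL[s][2] + nc) % nc;
            int c2 = (oz * nc + oy) * nc + ox;
            for (int i = cl.head[c]; i >= 0; i = cl.next[i])
              for (int j = cl.head[c2]; j >= 0; j = cl.next[j]) do_pair(i, j);
          }
        }
  }

  // bonds
  for (size_t b = 0; b < S.bi.size(); ++b) {
    int i = S.bi[b], j = S.bj[b];
    double dx = min_image(S.x[i] - S.x[j], L);
    double dy = min_image(S.y[i] - S.y[j], L);
    double dz = min_image(S.z[i] - S.z[j], L);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double fmag = -S.bks[b] * (r - S.brs[b]) / r;
    double d[3] = {dx, dy, dz};
    double w[3] = {fmag * dx * dx, fmag * dy * dy, fmag * dz * dz};
    A.add_pair(coord(i), d[axis], w, group0[i], group0[j]);
  }

  // angles: two pair-like legs (i,apex j) and (k,apex j)
  for (size_t t = 0; t < S.ai.size(); ++t) {
    int i = S.ai[t], j = S.aj[t], k = S.ak[t];
    double ux = min_image(S.x[i] - S.x[j], L);
    double uy = min_image(S.y[i] - S.y[j], L);
    double uz = min_image(S.z[i] - S.z[j], L);
    double wx = min_image(S.x[k] - S.x[j], L);
    double wy = min_image(S.y[k] - S.y[j], L);
    double wz = min_image(S.z[k] - S.z[j], L);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
    if (nu < 1e-12 || nw < 1e-12) continue;
    double c = (ux * wx + uy * wy + uz * wz) / (nu * nw);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dU = 2.0 * S.akth[t] * (th - S.ath0[t]);
    double s = std::sqrt(std::max(1.0 - c * c, 1e-16));
    double coef = dU / s;
    double fi[3] = {coef * (wx / nw - c * ux / nu) / nu,
                    coef * (wy / nw - c * uy / nu) / nu,
                    coef * (wz / nw - c * uz / nu) / nu};
    double fk[3] = {coef * (ux / nu - c * wx / nw) / nw,
                    coef * (uy / nu - c * wy / nw) / nw,
                    coef * (uz / nu - c * wz / nw) / nw};
    double u[3] = {ux, uy, uz}, wv[3] = {wx, wy, wz};
    double wi[3], wk[3];
    for (int cc = 0; cc < 3; ++cc) { wi[cc] = fi[cc] * u[cc]; wk[cc] = fk[cc] * wv[cc]; }
    A.add_pair(coord(i), u[axis], wi, group0[i], group0[j]);
    A.add_pair(coord(k), wv[axis], wk, group0[k], group0[j]);
  }

  NumericVector kin(A.kin.begin(), A.kin.end());
  NumericVector vir(A.vir.begin(), A.vir.end());
  kin.attr("dim") = IntegerVector::create(nbins, 3, ngroups);
  vir.attr("dim") = IntegerVector::create(nbins, 3, ngroups);
  return List::create(_["kin"] = kin, _["vir"] = vir,
                      _["global_kin"] = NumericVector::create(A.gkin[0], A.gkin[1], A.gkin[2]),
                      _["global_vir"] = NumericVector::create(A.gvir[0], A.gvir[1], A.gvir[2]));
}

// ---------------------------------------------------------------------------
// Contact pairs among a subset of beads (for the morphology classifier),
// with the integer periodic-image shift of each edge.

// [[Rcpp::export]]
List cpp_contact_pairs(NumericMatrix pos, double L, double cutoff,
                       IntegerVector idx0) {
  int n = idx0.size();
  std::vector<double> x(n), y(n), z(n);
  for (int m = 0; m < n; ++m) {
    x[m] = wrap(pos(idx0[m], 0), L);
    y[m] = wrap(pos(idx0[m], 1), L);
    z[m] = wrap(pos(idx0[m], 2), L);
  }
  CellList cl;
  cl.build(n, x, y, z, L, cutoff);
  const int nc = cl.nc;
  std::vector<int> pi, pj, sx, sy, sz;
  auto try_pair = [&](int i, int j) {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double mx = min_image(dx, L), my = min_image(dy, L), mz = min_image(dz, L);
    if (mx * mx + my * my + mz * mz >= cutoff * cutoff) return;
    pi.push_back(i + 1); pj.push_back(j + 1);
    sx.push_back(static_cast<int>(std::lround((dx - mx) / L)));
    sy.push_back(static_cast<int>(std::lround((dy - my) / L)));
    sz.push_back(static_cast<int>(std::lround((dz - mz) / L)));
  };
  if (nc < 3) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) try_pair(i, j);
  } else {
    for (int cz2 = 0; cz2 < nc; ++cz2)
      for (int cy2 = 0; cy2 < nc; ++cy2)
        for (int cx2 = 0; cx2 < nc; ++cx2) {
          int c = (cz2 * nc + cy2) * nc + cx2;
          for (int i = cl.head[c]; i >= 0; i = cl.next[i])
            for (int j = cl.next[i]; j >= 0; j = cl.next[j]) try_pair(i, j);
          for (int s = 0; s < 13; ++s) {
            int ox = (cx2 + HALF_SHELL[s][0] + nc) % nc;
            int oy = (cy2 + HALF_SHELL[s][1] + nc) % nc;
            int oz = (cz2 + HALF_SHELL[s][2] + nc) % nc;
            int c2 = (oz * nc + oy) * nc + ox;
            for (int i = cl.head[c]; i >= 0; i = cl.next[i])
              for (int j = cl.head[c2]; j >= 0; j = cl.next[j]) try_pair(i, j);
          }
        }
  }
  return List::create(_["i"] = IntegerVector(pi.begin(), pi.end()),
                      _["j"] = IntegerVector(pj.begin(), pj.end()),
                      _["shift"] = DataFrame::create(_["sx"] = IntegerVector(sx.begin(), sx.end()),
                                                     _["sy"] = IntegerVector(sy.begin(), sy.end()),
                                                     _["sz"] = IntegerVector(sz.begin(), sz.end())));
}

// ---------------------------------------------------------------------------
// Connected components of the FREE cells of a periodic occupancy grid
// (6-connectivity); labels: 0 = occupied, 1.. = free-space component.

// [[Rcpp::export]]
IntegerVector cpp_free_components(LogicalVector occ, int nx, int ny, int nz) {
  size_t ncell = static_cast<size_t>(nx) * ny * nz;
  IntegerVector lab(ncell, 0);
  std::vector<size_t> stack;
  int comp = 0;
  auto id = [&](int ix, int iy, int iz) {
    return (static_cast<size_t>(iz) * ny + iy) * nx + ix;
  };
  for (size_t s0 = 0; s0 < ncell; ++s0) {
    if (occ[s0] || lab[s0] != 0) continue;
    ++comp;
    stack.clear(); stack.push_back(s0); lab[s0] = comp;
    while (!stack.empty()) {
      size_t s = stack.back(); stack.pop_back();
      int ix = s % nx, iy = (s / nx) % ny, iz = s / (static_cast<size_t>(nx) * ny);
      const int nb[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int q = 0; q < 6; ++q) {
        int jx = (ix + nb[q][0] + nx) % nx;
        int jy = (iy + nb[q][1] + ny) % ny;
        int jz = (iz + nb[q][2] + nz) % nz;
        size_t t = id(jx, jy, jz);
        if (!occ[t] && lab[t] == 0) { lab[t] = comp; stack.push_back(t); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}
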