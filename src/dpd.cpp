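// DPD engine: cell-list pair forces, harmonic bonds, cosine angle bending,
// Groot-Warren modified velocity-Verlet, semi-isotropic Langevin-piston
// barostat, virial pressure tensor, umbrella bias, in-loop observable
// accumulation.
//
// All quantities in reduced units: r0 = m0 = kBT = 1, cutoff = 1.
//
// Randomness is counter-based: every noise draw is a pure function of
// (seed, step, ordered pair / tag), so a trajectory is reproducible from the
// seed alone and the cell-list and all-pairs paths draw identical numbers.
// Pair contributions are accumulated in sorted (i,j) order in both paths so
// their force sums agree bitwise.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double SQRT3 = 1.7320508075688772;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// uniform in [0,1) from a keyed counter
static inline double u01(uint64_t seed, uint64_t step, uint64_t tag) {
  uint64_t h = splitmix64(seed ^ splitmix64(step) ^ splitmix64(tag * 0x9E3779B97F4A7C15ULL + 0x165667B19E3779F9ULL));
  return (double)(h >> 11) * (1.0 / 9007199254740992.0);
}

// symmetric uniform noise with zero mean, unit variance (for pair forces)
static inline double zeta_pair(uint64_t seed, uint64_t step, uint32_t i, uint32_t j) {
  uint64_t tag = ((uint64_t)i << 32) | (uint64_t)j;
  return (2.0 * u01(seed, step, tag) - 1.0) * SQRT3;
}

// standard normal (for piston noise), Box-Muller on keyed uniforms
static inline double gauss_tag(uint64_t seed, uint64_t step, uint64_t tag) {
  double u1 = u01(seed, step, tag ^ 0xA5A5A5A5A5A5A5A5ULL);
  double u2 = u01(seed, step, tag ^ 0x5A5A5A5A5A5A5A5AULL);
  if (u1 < 1e-300) u1 = 1e-300;
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// positions are kept wrapped in [0, L), so |d| < L and one branch suffices
static inline double minimg(double d, double L) {
  if (d > 0.5 * L) return d - L;
  if (d < -0.5 * L) return d + L;
  return d;
}

// Sort pair keys ((i<<32)|j, i<j) lexicographically: counting sort on i,
// then insertion sort inside each (short) bucket. O(P + N), replaces the
// dominant std::sort cost in the force loop.
static void sort_pairs(std::vector<uint64_t>& keys, int N) {
  static std::vector<int> cnt;
  static std::vector<uint64_t> tmp;
  cnt.assign(N + 1, 0);
  tmp.resize(keys.size());
  for (size_t p = 0; p < keys.size(); ++p) ++cnt[(int)(keys[p] >> 32) + 1];
  for (int i = 0; i < N; ++i) cnt[i + 1] += cnt[i];
  std::vector<int> pos(cnt.begin(), cnt.end() - 1);
  for (size_t p = 0; p < keys.size(); ++p)
    tmp[pos[(int)(keys[p] >> 32)]++] = keys[p];
  for (int i = 0; i < N; ++i) {
    int lo = cnt[i], hi = (i + 1 <= N) ? cnt[i + 1] : (int)keys.size();
    for (int a = lo + 1; a < hi; ++a) {
      uint64_t v = tmp[a];
      int b = a - 1;
      while (b >= lo && tmp[b] > v) { tmp[b + 1] = tmp[b]; --b; }
      tmp[b + 1] = v;
    }
  }
  keys.swap(tmp);
}

struct Topology {
  // bonds: i, j (0-based), L0, K2
  std::vector<int> bi, bj;
  std::vector<double> bL0, bK2;
  // angles: i, j, k (0-based, j = apex), theta0 (rad), K3
  std::vector<int> ai, aj, ak;
  std::vector<double> ath0, aK3;
};

// Collect interacting nonbonded pairs (r < 1), keys sorted ascending.
static void collect_pairs(const std::vector<double>& x,
                          const std::vector<double>& y,
                          const std::vector<double>& z,
                          const double L[3], int N,
                          std::vector<uint64_t>& keys) {
  keys.clear();
  int ncx = (int)std::floor(L[0]), ncy = (int)std::floor(L[1]), ncz = (int)std::floor(L[2]);
  bool cells_ok = (ncx >= 3 && ncy >= 3 && ncz >= 3);
  if (!cells_ok) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = minimg(x[i] - x[j], L[0]);
        double dy = minimg(y[i] - y[j], L[1]);
        double dz = minimg(z[i] - z[j], L[2]);
        if (dx * dx + dy * dy + dz * dz < 1.0)
          keys.push_back(((uint64_t)i << 32) | (uint64_t)j);
      }
    return; // already sorted lexicographically
  }
  int ncell = ncx * ncy * ncz;
  std::vector<int> head(ncell, -1), nxt(N, -1);
  auto cidx = [&](double px, double py, double pz) {
    int cx = (int)(px / L[0] * ncx); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
    int cy = (int)(py / L[1] * ncy); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
    int cz = (int)(pz / L[2] * ncz); if (cz >= ncz) cz = ncz - 1; if (cz < 0) cz = 0;
    return (cz * ncy + cy) * ncx + cx;
  };
  for (int i = 0; i < N; ++i) {
    int c = cidx(x[i], y[i], z[i]);
    nxt[i] = head[c];
    head[c] = i;
  }
  // half stencil: self + 13 neighbors; periodic shift known per offset so
  // the candidate loop needs no minimum-image branches
  static const int off[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
  for (int cz = 0; cz < ncz; ++cz)
    for (int cy = 0; cy < ncy; ++cy)
      for (int cx = 0; cx < ncx; ++cx) {
        int c = (cz * ncy + cy) * ncx + cx;
        // in-cell pairs (no image shift possible)
        for (int i = head[c]; i >= 0; i = nxt[i])
          for (int j = nxt[i]; j >= 0; j = nxt[j]) {
            double dx = x[i] - x[j];
            double dy = y[i] - y[j];
            double dz = z[i] - z[j];
            if (dx * dx + dy * dy + dz * dz < 1.0) {
              uint32_t a = (uint32_t)std::min(i, j), b = (uint32_t)std::max(i, j);
              keys.push_back(((uint64_t)a << 32) | (uint64_t)b);
            }
          }
        // neighbor-cell pairs
        for (int s = 0; s < 13; ++s) {
          int nx = cx + off[s][0], ny = cy + off[s][1], nz = cz + off[s][2];
          double sx = 0, sy = 0, sz = 0; // shift applied to the neighbor cell
          if (nx >= ncx) { nx -= ncx; sx = L[0]; } else if (nx < 0) { nx += ncx; sx = -L[0]; }
          if (ny >= ncy) { ny -= ncy; sy = L[1]; } else if (ny < 0) { ny += ncy; sy = -L[1]; }
          if (nz >= ncz) { nz -= ncz; sz = L[2]; } else if (nz < 0) { nz += ncz; sz = -L[2]; }
          int c2 = (nz * ncy + ny) * ncx + nx;
          for (int i = head[c]; i >= 0; i = nxt[i]) {
            double xi = x[i], yi = y[i], zi = z[i];
            for (int j = head[c2]; j >= 0; j = nxt[j]) {
              double dx = xi - x[j] - sx;
              double dy = yi - y[j] - sy;
              double dz = zi - z[j] - sz;
              if (dx * dx + dy * dy + dz * dz < 1.0) {
                uint32_t a = (uint32_t)std::min(i, j), b = (uint32_t)std::max(i, j);
                keys.push_back(((uint64_t)a << 32) | (uint64_t)b);
              }
            }
          }
        }
      }
  sort_pairs(keys, N);
}

struct UmbrellaBias {
  bool enabled = false;
  int bead = -1;            // biased bead (0-based)
  double k = 0.0, zstar = 0.0;
  std::vector<int> ref;     // reference beads for mid-plane COM (empty = absolute z)
  double last_dz = 0.0;     // reaction-coordinate value at last force eval
};

// Evaluate all forces into fx/fy/fz; returns conservative+bonded diagonal
// virial in vir[3]. 'step' keys the random force.
static void eval_forces(const std::vector<double>& x, const std::vector<double>& y,
                        const std::vector<double>& z,
                        const std::vector<double>& vx, const std::vector<double>& vy,
                        const std::vector<double>& vz,
                        const std::vector<int>& type,
                        const std::vector<double>& amat, const std::vector<double>& gmat,
                        int ntype, const Topology& topo,
                        const double L[3], double dt, double temp,
                        uint64_t seed, uint64_t step,
                        const std::vector<uint64_t>& keys,
                        std::vector<double>& fx, std::vector<double>& fy,
                        std::vector<double>& fz, double vir[3],
                        UmbrellaBias* umb) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  vir[0] = vir[1] = vir[2] = 0.0;
  double inv_sqrt_dt = 1.0 / std::sqrt(dt);
  // random-force amplitude sqrt(2 gamma kBT)/sqrt(dt) per type pair
  std::vector<double> sig(ntype * ntype);
  for (int a = 0; a < ntype * ntype; ++a)
    sig[a] = std::sqrt(2.0 * gmat[a] * temp) * inv_sqrt_dt;

  for (size_t p = 0; p < keys.size(); ++p) {
    uint32_t i = (uint32_t)(keys[p] >> 32), j = (uint32_t)(keys[p] & 0xFFFFFFFFULL);
    double dx = minimg(x[i] - x[j], L[0]);
    double dy = minimg(y[i] - y[j], L[1]);
    double dz = minimg(z[i] - z[j], L[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= 1.0 || r2 < 1e-20) continue;
    double r = std::sqrt(r2);
    double w = 1.0 - r;
    double ex = dx / r, ey = dy / r, ez = dz / r;
    int ti = type[i], tj = type[j];
    double a = amat[ti * ntype + tj];
    double g = gmat[ti * ntype + tj];
    double fc = a * w;
    double vdot = ex * (vx[i] - vx[j]) + ey * (vy[i] - vy[j]) + ez * (vz[i] - vz[j]);
    double fd = -g * w * w * vdot;
    double fr = sig[ti * ntype + tj] * w * zeta_pair(seed, step, i, j);
    double f = fc + fd + fr;
    fx[i] += f * ex; fy[i] += f * ey; fz[i] += f * ez;
    fx[j] -= f * ex; fy[j] -= f * ey; fz[j] -= f * ez;
    vir[0] += dx * fc * ex;
    vir[1] += dy * fc * ey;
    vir[2] += dz * fc * ez;
  }

  // harmonic bonds: E = 0.5 K2 (r - L0)^2
  for (size_t b = 0; b < topo.bi.size(); ++b) {
    int i = topo.bi[b], j = topo.bj[b];
    double dx = minimg(x[i] - x[j], L[0]);
    double dy = minimg(y[i] - y[j], L[1]);
    double dz = minimg(z[i] - z[j], L[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double fs = -topo.bK2[b] * (r - topo.bL0[b]) / r; // force on i along d
    fx[i] += fs * dx; fy[i] += fs * dy; fz[i] += fs * dz;
    fx[j] -= fs * dx; fy[j] -= fs * dy; fz[j] -= fs * dz;
    vir[0] += dx * fs * dx;
    vir[1] += dy * fs * dy;
    vir[2] += dz * fs * dz;
  }

  // angle bending: E = K3 [1 - cos(theta - theta0)], apex at j
  for (size_t t = 0; t < topo.ai.size(); ++t) {
    int i = topo.ai[t], j = topo.aj[t], k = topo.ak[t];
    double ux = minimg(x[i] - x[j], L[0]);
    double uy = minimg(y[i] - y[j], L[1]);
    double uz = minimg(z[i] - z[j], L[2]);
    double wx = minimg(x[k] - x[j], L[0]);
    double wy = minimg(y[k] - y[j], L[1]);
    double wz = minimg(z[k] - z[j], L[2]);
    double ru = std::sqrt(ux * ux + uy * uy + uz * uz);
    double rw = std::sqrt(wx * wx + wy * wy + wz * wz);
    if (ru < 1e-12 || rw < 1e-12) continue;
    double cth = (ux * wx + uy * wy + uz * wz) / (ru * rw);
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    double sth = std::sqrt(std::max(1.0 - cth * cth, 0.0));
    double th0 = topo.ath0[t], K3 = topo.aK3[t];
    // F_i = coef * d(cos th)/d u ; coef = K3 (cos th0 - cot th sin th0)
    double coef = K3 * (std::cos(th0) - std::sin(th0) * cth / std::max(sth, 1e-8));
    double fix = coef * (wx / (ru * rw) - cth * ux / (ru * ru));
    double fiy = coef * (wy / (ru * rw) - cth * uy / (ru * ru));
    double fiz = coef * (wz / (ru * rw) - cth * uz / (ru * ru));
    double fkx = coef * (ux / (ru * rw) - cth * wx / (rw * rw));
    double fky = coef * (uy / (ru * rw) - cth * wy / (rw * rw));
    double fkz = coef * (uz / (ru * rw) - cth * wz / (rw * rw));
    fx[i] += fix; fy[i] += fiy; fz[i] += fiz;
    fx[k] += fkx; fy[k] += fky; fz[k] += fkz;
    fx[j] -= fix + fkx; fy[j] -= fiy + fky; fz[j] -= fiz + fkz;
    vir[0] += ux * fix + wx * fkx;
    vir[1] += uy * fiy + wy * fky;
    vir[2] += uz * fiz + wz * fkz;
  }

  // umbrella bias on one bead's z-offset from a reference COM plane
  if (umb && umb->enabled) {
    double zref = 0.0;
    if (!umb->ref.empty()) {
      // mean z of reference beads; valid while the reference group does not
      // wrap across the periodic boundary (builders centre the bilayer)
      for (size_t m = 0; m < umb->ref.size(); ++m) zref += z[umb->ref[m]];
      zref /= (double)umb->ref.size();
    }
    double dz = z[umb->bead] - zref;
    dz = minimg(dz, L[2]);
    umb->last_dz = dz;
    double delta = dz - umb->zstar;
    double fb = -umb->k * delta;
    fz[umb->bead] += fb;
    if (!umb->ref.empty()) {
      double share = -fb / (double)umb->ref.size();
      for (size_t m = 0; m < umb->ref.size(); ++m) fz[umb->ref[m]] += share;
    }
  }
}

static Topology make_topology(const NumericMatrix& bonds, const NumericMatrix& angles) {
  Topology topo;
  for (int b = 0; b < bonds.nrow(); ++b) {
    topo.bi.push_back((int)bonds(b, 0) - 1);
    topo.bj.push_back((int)bonds(b, 1) - 1);
    topo.bL0.push_back(bonds(b, 2));
    topo.bK2.push_back(bonds(b, 3));
  }
  for (int t = 0; t < angles.nrow(); ++t) {
    topo.ai.push_back((int)angles(t, 0) - 1);
    topo.aj.push_back((int)angles(t, 1) - 1);
    topo.ak.push_back((int)angles(t, 2) - 1);
    topo.ath0.push_back(angles(t, 3)); // radians
    topo.aK3.push_back(angles(t, 4));
  }
  return topo;
}

// [[Rcpp::export]]
List compute_forces_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                        NumericMatrix amat, NumericMatrix gmat,
                        NumericMatrix bonds, NumericMatrix angles,
                        NumericVector box, double dt, double temp,
                        double seed, double step, bool use_cell_list) {
  int N = pos.nrow();
  int ntype = amat.nrow();
  double L[3] = {box[0], box[1], box[2]};
  std::vector<double> x(N), y(N), z(N), vx(N), vy(N), vz(N);
  std::vector<int> ty(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    ty[i] = type[i] - 1;
  }
  std::vector<double> am(ntype * ntype), gm(ntype * ntype);
  for (int a = 0; a < ntype; ++a)
    for (int b = 0; b < ntype; ++b) {
      am[a * ntype + b] = amat(a, b);
      gm[a * ntype + b] = gmat(a, b);
    }
  Topology topo = make_topology(bonds, angles);
  std::vector<uint64_t> keys;
  if (use_cell_list) {
    collect_pairs(x, y, z, L, N, keys);
  } else {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = minimg(x[i] - x[j], L[0]);
        double dy = minimg(y[i] - y[j], L[1]);
        double dzv = minimg(z[i] - z[j], L[2]);
        if (dx * dx + dy * dy + dzv * dzv < 1.0)
          keys.push_back(((uint64_t)i << 32) | (uint64_t)j);
      }
  }
  std::vector<double> fx(N), fy(N), fz(N);
  double vir[3];
  eval_forces(x, y, z, vx, vy, vz, ty, am, gm, ntype, topo, L, dt, temp,
              (uint64_t)seed, (uint64_t)step, keys, fx, fy, fz, vir, nullptr);
  NumericMatrix F(N, 3);
  for (int i = 0; i < N; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(_["forces"] = F,
                      _["virial"] = NumericVector::create(vir[0], vir[1], vir[2]),
                      _["n_pairs"] = (double)keys.size());
}

// [[Rcpp::export]]
double bonded_energy_cpp(NumericMatrix pos, NumericMatrix bonds,
                         NumericMatrix angles, NumericVector box) {
  double L[3] = {box[0], box[1], box[2]};
  Topology topo = make_topology(bonds, angles);
  int N = pos.nrow();
  std::vector<double> x(N), y(N), z(N);
  for (int i = 0; i < N; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double E = 0.0;
  for (size_t b = 0; b < topo.bi.size(); ++b) {
    int i = topo.bi[b], j = topo.bj[b];
    double dx = minimg(x[i] - x[j], L[0]);
    double dy = minimg(y[i] - y[j], L[1]);
    double dz = minimg(z[i] - z[j], L[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - topo.bL0[b];
    E += 0.5 * topo.bK2[b] * d * d;
  }
  for (size_t t = 0; t < topo.ai.size(); ++t) {
    int i = topo.ai[t], j = topo.aj[t], k = topo.ak[t];
    double ux = minimg(x[i] - x[j], L[0]);
    double uy = minimg(y[i] - y[j], L[1]);
    double uz = minimg(z[i] - z[j], L[2]);
    double wx = minimg(x[k] - x[j], L[0]);
    double wy = minimg(y[k] - y[j], L[1]);
    double wz = minimg(z[k] - z[j], L[2]);
    double ru = std::sqrt(ux * ux + uy * uy + uz * uz);
    double rw = std::sqrt(wx * wx + wy * wy + wz * wz);
    double cth = (ux * wx + uy * wy + uz * wz) / (ru * rw);
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    double th = std::acos(cth);
    E += topo.aK3[t] * (1.0 - std::cos(th - topo.ath0[t]));
  }
  return E;
}

// Main MD driver.
//
// opts fields:
//   ensemble       : 0 = NVT, 1 = semi-isotropic NPT (Langevin piston)
//   p_target, piston_mass, piston_gamma
//   sample_stride  : record T/P/box every this many steps (0 = off)
//   zhist_bins     : accumulate per-type z histogram at sample_stride (0 = off)
//   frame_stride   : store position snapshots (0 = off)
//   umbrella       : list(bead, k, zstar, ref) or NULL
// [[Rcpp::export]]
List dpd_run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                 NumericMatrix amat, NumericMatrix gmat,
                 NumericMatrix bonds, NumericMatrix angles,
                 NumericVector box, double dt, int nsteps, double temp,
                 double seed, double step0, List opts) {
  int N = pos.nrow();
  int ntype = amat.nrow();
  double L[3] = {box[0], box[1], box[2]};
  std::vector<double> x(N), y(N), z(N), vx(N), vy(N), vz(N);
  std::vector<int> ty(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    ty[i] = type[i] - 1;
  }
  std::vector<double> am(ntype * ntype), gm(ntype * ntype);
  for (int a = 0; a < ntype; ++a)
    for (int b = 0; b < ntype; ++b) {
      am[a * ntype + b] = amat(a, b);
      gm[a * ntype + b] = gmat(a, b);
    }
  Topology topo = make_topology(bonds, angles);

  int ensemble = as<int>(opts["ensemble"]);
  double p_target = as<double>(opts["p_target"]);
  double Mp = as<double>(opts["piston_mass"]);
  double gp = as<double>(opts["piston_gamma"]);
  int sample_stride = as<int>(opts["sample_stride"]);
  int zhist_bins = as<int>(opts["zhist_bins"]);
  int frame_stride = as<int>(opts["frame_stride"]);

  UmbrellaBias umb;
  if (opts.containsElementNamed("umbrella") && !Rf_isNull(opts["umbrella"])) {
    List u = opts["umbrella"];
    umb.enabled = true;
    umb.bead = as<int>(u["bead"]) - 1;
    umb.k = as<double>(u["k"]);
    umb.zstar = as<double>(u["zstar"]);
    if (!Rf_isNull(u["ref"])) {
      IntegerVector rr = u["ref"];
      for (int m = 0; m < rr.size(); ++m) umb.ref.push_back(rr[m] - 1);
    }
  }

  uint64_t sd = (uint64_t)seed;
  uint64_t s0 = (uint64_t)step0;

  std::vector<double> fx(N), fy(N), fz(N), fox(N), foy(N), foz(N);
  double vir[3];
  std::vector<uint64_t> keys;

  auto wrap_all = [&]() {
    for (int i = 0; i < N; ++i) {
      x[i] -= L[0] * std::floor(x[i] / L[0]);
      y[i] -= L[1] * std::floor(y[i] / L[1]);
      z[i] -= L[2] * std::floor(z[i] / L[2]);
    }
  };
  wrap_all();

  // Restart exactness: mid-step force evaluations use predicted velocities,
  // so a restart must reuse the stored end-of-run forces rather than
  // re-evaluating; otherwise the noise-identical trajectory diverges.
  bool have_init = opts.containsElementNamed("init_forces") &&
    !Rf_isNull(opts["init_forces"]);
  if (have_init) {
    NumericMatrix F0 = opts["init_forces"];
    NumericVector V0 = opts["init_virial"];
    for (int i = 0; i < N; ++i) {
      fx[i] = F0(i, 0); fy[i] = F0(i, 1); fz[i] = F0(i, 2);
    }
    vir[0] = V0[0]; vir[1] = V0[1]; vir[2] = V0[2];
  } else {
    collect_pairs(x, y, z, L, N, keys);
    eval_forces(x, y, z, vx, vy, vz, ty, am, gm, ntype, topo, L, dt, temp,
                sd, s0, keys, fx, fy, fz, vir, &umb);
  }

  int nsamp_cap = sample_stride > 0 ? nsteps / sample_stride + 1 : 0;
  NumericMatrix samples(nsamp_cap, 9); // step,time,T,Pxx,Pyy,Pzz,Lx,Ly,Lz
  int nsamp = 0;
  NumericMatrix zhist(zhist_bins > 0 ? ntype : 0, zhist_bins);
  int zhist_nsamp = 0;
  std::vector<double> umb_samples;
  List frames;
  std::vector<NumericMatrix> frame_store;
  double piston_eta_z = 0.0, piston_eta_s = 0.0;
  bool failed = false;
  std::string failmsg;

  auto record = [&](uint64_t step_global, int step_local) {
    double kin[3] = {0, 0, 0};
    for (int i = 0; i < N; ++i) {
      kin[0] += vx[i] * vx[i];
      kin[1] += vy[i] * vy[i];
      kin[2] += vz[i] * vz[i];
    }
    double V = L[0] * L[1] * L[2];
    double Tk = (kin[0] + kin[1] + kin[2]) / (3.0 * N - 3.0);
    samples(nsamp, 0) = (double)step_global;
    samples(nsamp, 1) = (double)step_global * dt;
    samples(nsamp, 2) = Tk;
    samples(nsamp, 3) = (kin[0] + vir[0]) / V;
    samples(nsamp, 4) = (kin[1] + vir[1]) / V;
    samples(nsamp, 5) = (kin[2] + vir[2]) / V;
    samples(nsamp, 6) = L[0];
    samples(nsamp, 7) = L[1];
    samples(nsamp, 8) = L[2];
    ++nsamp;
    if (zhist_bins > 0) {
      for (int i = 0; i < N; ++i) {
        int b = (int)(z[i] / L[2] * zhist_bins);
        if (b >= zhist_bins) b = zhist_bins - 1;
        if (b < 0) b = 0;
        zhist(ty[i], b) += 1.0;
      }
      ++zhist_nsamp;
    }
    if (umb.enabled) umb_samples.push_back(umb.last_dz);
    (void)step_local;
  };

  if (sample_stride > 0) record(s0, 0);

  for (int s = 1; s <= nsteps; ++s) {
    uint64_t gstep = s0 + (uint64_t)s;
    // Groot-Warren modified velocity Verlet, lambda = 0.5
    for (int i = 0; i < N; ++i) {
      fox[i] = fx[i]; foy[i] = fy[i]; foz[i] = fz[i];
      x[i] += dt * vx[i] + 0.5 * dt * dt * fx[i];
      y[i] += dt * vy[i] + 0.5 * dt * dt * fy[i];
      z[i] += dt * vz[i] + 0.5 * dt * dt * fz[i];
      vx[i] += 0.5 * dt * fx[i]; // predicted velocity used in F^D
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
    }
    wrap_all();
    collect_pairs(x, y, z, L, N, keys);
    eval_forces(x, y, z, vx, vy, vz, ty, am, gm, ntype, topo, L, dt, temp,
                sd, gstep, keys, fx, fy, fz, vir, &umb);
    for (int i = 0; i < N; ++i) {
      // v(t+dt) = v(t) + dt/2 (F_old + F_new); predicted v already holds
      // v(t) + dt/2 F_old, so add the new half-kick
      vx[i] += 0.5 * dt * fx[i];
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
    }
    for (int i = 0; i < N; ++i) {
      if (!std::isfinite(x[i]) || !std::isfinite(vx[i]) ||
          !std::isfinite(z[i]) || !std::isfinite(vz[i])) {
        failed = true;
        failmsg = "non-finite coordinates (integration failure)";
      }
    }
    if (failed) break;

    if (ensemble == 1) {
      // semi-isotropic Langevin piston on Lz and on s = Lx = Ly
      double kin[3] = {0, 0, 0};
      for (int i = 0; i < N; ++i) {
        kin[0] += vx[i] * vx[i];
        kin[1] += vy[i] * vy[i];
        kin[2] += vz[i] * vz[i];
      }
      double V = L[0] * L[1] * L[2];
      double Pz = (kin[2] + vir[2]) / V;
      double Pt = 0.5 * ((kin[0] + vir[0]) + (kin[1] + vir[1])) / V;
      double noise_scale = std::sqrt(2.0 * gp * Mp * temp / dt);
      double Fz = (Pz - p_target) * L[0] * L[1] +
                  noise_scale * gauss_tag(sd, gstep, 1ULL);
      piston_eta_z += dt * (Fz - gp * Mp * piston_eta_z) / Mp;
      double Lz_new = L[2] + piston_eta_z * dt;
      double ss = L[0];
      double Fs = (Pt - p_target) * 2.0 * ss * Lz_new +
                  noise_scale * gauss_tag(sd, gstep, 2ULL);
      piston_eta_s += dt * (Fs - gp * Mp * piston_eta_s) / Mp;
      double s_new = ss + piston_eta_s * dt;
      if (Lz_new < 3.0 || s_new < 3.0) {
        failed = true;
        failmsg = "box collapse (an edge shrank below 3 cutoffs)";
        break;
      }
      double zs = Lz_new / L[2], xys = s_new / ss;
      for (int i = 0; i < N; ++i) {
        z[i] *= zs;
        x[i] *= xys;
        y[i] *= xys;
      }
      L[2] = Lz_new;
      L[0] = L[1] = s_new;
      wrap_all();
    }

    if (sample_stride > 0 && s % sample_stride == 0) record(gstep, s);
    if (frame_stride > 0 && s % frame_stride == 0) {
      NumericMatrix fp(N, 3);
      for (int i = 0; i < N; ++i) { fp(i, 0) = x[i]; fp(i, 1) = y[i]; fp(i, 2) = z[i]; }
      fp.attr("box") = NumericVector::create(L[0], L[1], L[2]);
      fp.attr("time") = (double)gstep * dt;
      frame_store.push_back(fp);
    }
  }

  NumericMatrix pos_out(N, 3), vel_out(N, 3);
  for (int i = 0; i < N; ++i) {
    pos_out(i, 0) = x[i]; pos_out(i, 1) = y[i]; pos_out(i, 2) = z[i];
    vel_out(i, 0) = vx[i]; vel_out(i, 1) = vy[i]; vel_out(i, 2) = vz[i];
  }
  NumericMatrix samples_out(nsamp, 9);
  for (int r = 0; r < nsamp; ++r)
    for (int c = 0; c < 9; ++c) samples_out(r, c) = samples(r, c);
  List frames_out(frame_store.size());
  for (size_t f = 0; f < frame_store.size(); ++f) frames_out[f] = frame_store[f];

  NumericMatrix f_out(N, 3);
  for (int i = 0; i < N; ++i) {
    f_out(i, 0) = fx[i]; f_out(i, 1) = fy[i]; f_out(i, 2) = fz[i];
  }
  return List::create(
    _["pos"] = pos_out, _["vel"] = vel_out,
    _["box"] = NumericVector::create(L[0], L[1], L[2]),
    _["forces"] = f_out,
    _["virial"] = NumericVector::create(vir[0], vir[1], vir[2]),
    _["step_end"] = (double)(s0 + (uint64_t)nsteps),
    _["samples"] = samples_out,
    _["zhist"] = zhist, _["zhist_nsamp"] = zhist_nsamp,
    _["umbrella_samples"] = wrap(umb_samples),
    _["frames"] = frames_out,
    _["failed"] = failed, _["failmsg"] = failmsg);
}
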