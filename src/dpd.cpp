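// Compact DPD engine: soft conservative forces, pairwise
// dissipative/random thermostat, harmonic bonds and 1-3 angles, cell-list
// neighbor search, velocity Verlet in a periodic cubic box.
//
// All randomness is counter-based: the pair noise is a deterministic hash of
// (seed, step, i, j), so trajectories are bitwise reproducible for a given
// seed, the noise is symmetric in (i, j) by construction (momentum
// conservation), and no global RNG state is carried.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// uniform noise with unit variance, symmetric in the particle pair
static inline double pair_noise(uint64_t seed, uint64_t step, int i, int j) {
  if (i > j) std::swap(i, j);
  uint64_t h = splitmix64(seed ^ 0x5851f42d4c957f2dULL);
  h = splitmix64(h ^ step);
  h = splitmix64(h ^ (((uint64_t)(uint32_t)i << 32) | (uint64_t)(uint32_t)j));
  double u = (double)(h >> 11) * (1.0 / 9007199254740992.0); // [0,1)
  return 1.7320508075688772 * (2.0 * u - 1.0);               // var = 1
}

struct System {
  int n, nt;
  double L;
  const double *a, *R;   // nt x nt, column-major
  const int *type;       // 0-based
  double maxR;
};

static inline double min_image(double d, double L) {
  if (d >  0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// accumulate the nonbonded force of pair (i, j) into f
static inline void nb_pair(const System &S, const double *x, const double *v,
                           double *f, int i, int j, double gamma,
                           double sigma, double inv_sqrt_dt, uint64_t seed,
                           uint64_t step) {
  double dx = min_image(x[3 * i] - x[3 * j], S.L);
  double dy = min_image(x[3 * i + 1] - x[3 * j + 1], S.L);
  double dz = min_image(x[3 * i + 2] - x[3 * j + 2], S.L);
  double r2 = dx * dx + dy * dy + dz * dz;
  double Rij = S.R[S.type[i] + S.nt * S.type[j]];
  if (r2 >= Rij * Rij) return;
  double r = std::sqrt(r2);
  double ex, ey, ez;
  if (r < 1e-12) {
    // coincident beads: deterministic seeded tie-break direction
    double u1 = pair_noise(seed ^ 0xabcdULL, step, i, j);
    double u2 = pair_noise(seed ^ 0x1234ULL, step, i, j);
    double ph = 3.14159265358979323846 * u1, ct = u2 / 1.7320508075688772;
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    ex = st * std::cos(ph); ey = st * std::sin(ph); ez = ct;
    r = 0.0;
  } else {
    ex = dx / r; ey = dy / r; ez = dz / r;
  }
  double w = 1.0 - r / Rij;
  double aij = S.a[S.type[i] + S.nt * S.type[j]];
  double fmag = aij * w;                          // conservative
  if (gamma > 0.0 || sigma > 0.0) {
    double vdote = (v[3 * i] - v[3 * j]) * ex + (v[3 * i + 1] - v[3 * j + 1]) * ey +
                   (v[3 * i + 2] - v[3 * j + 2]) * ez;
    fmag += -gamma * w * w * vdote;               // dissipative, w^D = (w^R)^2
    fmag += sigma * w * pair_noise(seed, step, i, j) * inv_sqrt_dt; // random
  }
  f[3 * i] += fmag * ex; f[3 * i + 1] += fmag * ey; f[3 * i + 2] += fmag * ez;
  f[3 * j] -= fmag * ex; f[3 * j + 1] -= fmag * ey; f[3 * j + 2] -= fmag * ez;
}

struct CellList {
  int nc;            // cells per dimension
  double cw;         // cell width
  std::vector<int> head, next;
  void build(const double *x, int n, double L, double cut) {
    nc = std::max(1, (int)std::floor(L / cut));
    cw = L / nc;
    head.assign((size_t)nc * nc * nc, -1);
    next.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(nc - 1, (int)(x[3 * i] / cw));
      int cy = std::min(nc - 1, (int)(x[3 * i + 1] / cw));
      int cz = std::min(nc - 1, (int)(x[3 * i + 2] / cw));
      int c = cx + nc * (cy + nc * cz);
      next[i] = head[c];
      head[c] = i;
    }
  }
};

// half-shell neighbor offsets: same cell handled separately
static const int HALF_OFF[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
  {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};

template <typename PairFn>
static void for_each_pair_cells(const System &S, const double *x,
                                CellList &cl, PairFn fn) {
  int nc = cl.nc;
  if (nc < 3) {  // box too small for cell lists: all pairs
    for (int i = 0; i < S.n; ++i)
      for (int j = i + 1; j < S.n; ++j) fn(i, j);
    return;
  }
  for (int cz = 0; cz < nc; ++cz)
    for (int cy = 0; cy < nc; ++cy)
      for (int cx = 0; cx < nc; ++cx) {
        int c = cx + nc * (cy + nc * cz);
        for (int i = cl.head[c]; i >= 0; i = cl.next[i]) {
          for (int j = cl.next[i]; j >= 0; j = cl.next[j]) fn(i, j);
          for (int o = 0; o < 13; ++o) {
            int ox = (cx + HALF_OFF[o][0] + nc) % nc;
            int oy = (cy + HALF_OFF[o][1] + nc) % nc;
            int oz = (cz + HALF_OFF[o][2] + nc) % nc;
            int c2 = ox + nc * (oy + nc * oz);
            for (int j = cl.head[c2]; j >= 0; j = cl.next[j]) fn(i, j);
          }
        }
      }
}

static void bonded_forces(const double *x, double *f, double L,
                          const int *bi, const int *bj, const double *br0,
                          const double *bkb, int nb,
                          const int *ai, const int *aj, const int *ak,
                          const double *th0, const double *aka, int na) {
  for (int b = 0; b < nb; ++b) {
    int i = bi[b], j = bj[b];
    double dx = min_image(x[3 * i] - x[3 * j], L);
    double dy = min_image(x[3 * i + 1] - x[3 * j + 1], L);
    double dz = min_image(x[3 * i + 2] - x[3 * j + 2], L);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double fmag = -bkb[b] * (r - br0[b]) / r;
    f[3 * i] += fmag * dx; f[3 * i + 1] += fmag * dy; f[3 * i + 2] += fmag * dz;
    f[3 * j] -= fmag * dx; f[3 * j + 1] -= fmag * dy; f[3 * j + 2] -= fmag * dz;
  }
  for (int t = 0; t < na; ++t) {
    int i = ai[t], j = aj[t], k = ak[t];
    double rijx = min_image(x[3 * i] - x[3 * j], L);
    double rijy = min_image(x[3 * i + 1] - x[3 * j + 1], L);
    double rijz = min_image(x[3 * i + 2] - x[3 * j + 2], L);
    double rkjx = min_image(x[3 * k] - x[3 * j], L);
    double rkjy = min_image(x[3 * k + 1] - x[3 * j + 1], L);
    double rkjz = min_image(x[3 * k + 2] - x[3 * j + 2], L);
    double r1 = std::sqrt(rijx * rijx + rijy * rijy + rijz * rijz);
    double r2 = std::sqrt(rkjx * rkjx + rkjy * rkjy + rkjz * rkjz);
    if (r1 < 1e-12 || r2 < 1e-12) continue;
    double ct = (rijx * rkjx + rijy * rkjy + rijz * rkjz) / (r1 * r2);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1e-16, 1.0 - ct * ct)); // collinear-safe
    double coef = aka[t] * (th - th0[t]) / st;
    // F_i = coef * d(cos th)/d r_i ; analogous for k; j balances
    double fix = coef * (rkjx / (r1 * r2) - ct * rijx / (r1 * r1));
    double fiy = coef * (rkjy / (r1 * r2) - ct * rijy / (r1 * r1));
    double fiz = coef * (rkjz / (r1 * r2) - ct * rijz / (r1 * r1));
    double fkx = coef * (rijx / (r1 * r2) - ct * rkjx / (r2 * r2));
    double fky = coef * (rijy / (r1 * r2) - ct * rkjy / (r2 * r2));
    double fkz = coef * (rijz / (r1 * r2) - ct * rkjz / (r2 * r2));
    f[3 * i] += fix; f[3 * i + 1] += fiy; f[3 * i + 2] += fiz;
    f[3 * k] += fkx; f[3 * k + 1] += fky; f[3 * k + 2] += fkz;
    f[3 * j] -= fix + fkx; f[3 * j + 1] -= fiy + fky; f[3 * j + 2] -= fiz + fkz;
  }
}

// Cell-sorted force workspace for the integrator's fast path: particles are
// counting-sorted by cell each evaluation, neighbor-cell indices and their
// periodic shift vectors are precomputed once, and pair interactions run
// over contiguous index ranges without minimum-image branches.
struct SortedForces {
  int n, nc;
  double L, cw;
  std::vector<int> ncell_idx;      // 13 neighbors per cell
  std::vector<double> ncell_shift; // 3 per neighbor entry
  std::vector<int> cnt, start, perm;
  std::vector<double> xs, ys, zs, vxs, vys, vzs, fxs, fys, fzs;
  std::vector<int> tys, orig;

  void init(int n_, double L_, double cut) {
    n = n_; L = L_;
    nc = std::max(1, (int)std::floor(L / cut));
    cw = L / nc;
    if (nc >= 3) {
      ncell_idx.resize((size_t)nc * nc * nc * 13);
      ncell_shift.resize((size_t)nc * nc * nc * 39);
      size_t e = 0;
      for (int cz = 0; cz < nc; ++cz)
        for (int cy = 0; cy < nc; ++cy)
          for (int cx = 0; cx < nc; ++cx)
            for (int o = 0; o < 13; ++o, ++e) {
              int gx = cx + HALF_OFF[o][0], gy = cy + HALF_OFF[o][1],
                  gz = cz + HALF_OFF[o][2];
              double shx = 0, shy = 0, shz = 0;
              if (gx < 0) { gx += nc; shx = -L; } else if (gx >= nc) { gx -= nc; shx = L; }
              if (gy < 0) { gy += nc; shy = -L; } else if (gy >= nc) { gy -= nc; shy = L; }
              if (gz < 0) { gz += nc; shz = -L; } else if (gz >= nc) { gz -= nc; shz = L; }
              ncell_idx[e] = gx + nc * (gy + nc * gz);
              ncell_shift[3 * e] = shx; ncell_shift[3 * e + 1] = shy;
              ncell_shift[3 * e + 2] = shz;
            }
    }
    int ncells = nc * nc * nc;
    cnt.resize(ncells); start.resize(ncells + 1); perm.resize(n);
    xs.resize(n); ys.resize(n); zs.resize(n);
    vxs.resize(n); vys.resize(n); vzs.resize(n);
    fxs.resize(n); fys.resize(n); fzs.resize(n);
    tys.resize(n); orig.resize(n);
  }

  inline int cell_of(const double *x, int i) const {
    int cx = std::min(nc - 1, (int)(x[3 * i] / cw));
    int cy = std::min(nc - 1, (int)(x[3 * i + 1] / cw));
    int cz = std::min(nc - 1, (int)(x[3 * i + 2] / cw));
    return cx + nc * (cy + nc * cz);
  }

  void compute(const System &S, const double *x, const double *v, double *f,
               double gamma, double sigma, double inv_sqrt_dt, uint64_t seed,
               uint64_t step) {
    std::fill(f, f + 3 * S.n, 0.0);
    if (nc < 3) {   // box too small for cells: all pairs
      for (int i = 0; i < S.n; ++i)
        for (int j = i + 1; j < S.n; ++j)
          nb_pair(S, x, v, f, i, j, gamma, sigma, inv_sqrt_dt, seed, step);
      return;
    }
    int ncells = nc * nc * nc;
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) ++cnt[cell_of(x, i)];
    start[0] = 0;
    for (int c = 0; c < ncells; ++c) start[c + 1] = start[c] + cnt[c];
    std::vector<int> at(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) {
      int p = at[cell_of(x, i)]++;
      orig[p] = i;
      xs[p] = x[3 * i]; ys[p] = x[3 * i + 1]; zs[p] = x[3 * i + 2];
      vxs[p] = v[3 * i]; vys[p] = v[3 * i + 1]; vzs[p] = v[3 * i + 2];
      tys[p] = S.type[i];
    }
    std::fill(fxs.begin(), fxs.end(), 0.0);
    std::fill(fys.begin(), fys.end(), 0.0);
    std::fill(fzs.begin(), fzs.end(), 0.0);
    const double *aM = S.a, *RM = S.R;
    int nt = S.nt;
    bool thermo = (gamma > 0.0 || sigma > 0.0);
    auto do_pair = [&](int p, int q, double shx, double shy, double shz) {
      double dx = xs[p] - xs[q] - shx;
      double dy = ys[p] - ys[q] - shy;
      double dz = zs[p] - zs[q] - shz;
      double r2 = dx * dx + dy * dy + dz * dz;
      double Rij = RM[tys[p] + nt * tys[q]];
      if (r2 >= Rij * Rij || r2 < 1e-24) {
        if (r2 < 1e-24)   // coincident: rare, fall back to tie-break path
          nb_pair(S, x, v, f, orig[p], orig[q], gamma, sigma, inv_sqrt_dt,
                  seed, step);
        return;
      }
      double r = std::sqrt(r2), inv_r = 1.0 / r;
      double w = 1.0 - r / Rij;
      double fmag = aM[tys[p] + nt * tys[q]] * w;
      if (thermo) {
        double vdote = ((vxs[p] - vxs[q]) * dx + (vys[p] - vys[q]) * dy +
                        (vzs[p] - vzs[q]) * dz) * inv_r;
        fmag += -gamma * w * w * vdote;
        fmag += sigma * w * pair_noise(seed, step, orig[p], orig[q]) *
                inv_sqrt_dt;
      }
      double s = fmag * inv_r;
      fxs[p] += s * dx; fys[p] += s * dy; fzs[p] += s * dz;
      fxs[q] -= s * dx; fys[q] -= s * dy; fzs[q] -= s * dz;
    };
    for (int c = 0; c < ncells; ++c) {
      int b0 = start[c], b1 = start[c + 1];
      for (int p = b0; p < b1; ++p)
        for (int q = p + 1; q < b1; ++q) do_pair(p, q, 0.0, 0.0, 0.0);
      const int *nbr = &ncell_idx[(size_t)c * 13];
      const double *shf = &ncell_shift[(size_t)c * 39];
      for (int o = 0; o < 13; ++o) {
        int c2 = nbr[o];
        double shx = shf[3 * o], shy = shf[3 * o + 1], shz = shf[3 * o + 2];
        int d0 = start[c2], d1 = start[c2 + 1];
        for (int p = b0; p < b1; ++p)
          for (int q = d0; q < d1; ++q) do_pair(p, q, shx, shy, shz);
      }
    }
    for (int p = 0; p < n; ++p) {
      int i = orig[p];
      f[3 * i] += fxs[p]; f[3 * i + 1] += fys[p]; f[3 * i + 2] += fzs[p];
    }
  }
};

// Full force evaluation into f (overwrites).
static void all_forces(const System &S, const double *x, const double *v,
                       double *f, SortedForces &sf, double gamma,
                       double sigma, double inv_sqrt_dt, uint64_t seed,
                       uint64_t step, const int *bi, const int *bj,
                       const double *br0, const double *bkb, int nb,
                       const int *ai, const int *aj, const int *ak,
                       const double *th0, const double *aka, int na) {
  sf.compute(S, x, v, f, gamma, sigma, inv_sqrt_dt, seed, step);
  bonded_forces(x, f, S.L, bi, bj, br0, bkb, nb, ai, aj, ak, th0, aka, na);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
             NumericMatrix aM, NumericMatrix RM, IntegerVector bond_i,
             IntegerVector bond_j, NumericVector bond_r0,
             NumericVector bond_kb, IntegerVector ang_i, IntegerVector ang_j,
             IntegerVector ang_k, NumericVector ang_th0, NumericVector ang_ka,
             double L, double dt, int nsteps, int stride, double gamma,
             double sigma, double seed, double step0) {
  int n = pos.nrow(), nt = aM.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), fold(3 * n);
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = pos(i, 0); x[3 * i + 1] = pos(i, 1); x[3 * i + 2] = pos(i, 2);
    v[3 * i] = vel(i, 0); v[3 * i + 1] = vel(i, 1); v[3 * i + 2] = vel(i, 2);
    ty[i] = type[i];
  }
  double maxR = 0.0;
  for (int i = 0; i < nt * nt; ++i) maxR = std::max(maxR, RM[i]);
  System S{n, nt, L, aM.begin(), RM.begin(), ty.data(), maxR};
  SortedForces sf;
  sf.init(n, L, maxR);
  double inv_sqrt_dt = 1.0 / std::sqrt(dt);
  uint64_t useed = (uint64_t)seed, ustep0 = (uint64_t)step0;
  int nb = bond_i.size(), na = ang_i.size();

  all_forces(S, x.data(), v.data(), fold.data(), sf, gamma, sigma,
             inv_sqrt_dt, useed, ustep0, bond_i.begin(), bond_j.begin(),
             bond_r0.begin(), bond_kb.begin(), nb, ang_i.begin(),
             ang_j.begin(), ang_k.begin(), ang_th0.begin(), ang_ka.begin(),
             na);

  int nframes = nsteps / stride;
  List frames(nframes);
  NumericVector temps(nframes), frame_steps(nframes);
  int fr = 0;
  double half_dt = 0.5 * dt, max_disp = 0.5 * L;

  for (int s = 0; s < nsteps; ++s) {
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
    for (int i = 0; i < 3 * n; ++i) v[i] += half_dt * fold[i];
    for (int i = 0; i < 3 * n; ++i) {
      double d = dt * v[i];
      if (std::abs(d) > max_disp)
        stop("integration unstable at step %d: displacement %g > L/2",
             s, std::abs(d));
      double xn = x[i] + d;
      xn -= L * std::floor(xn / L);
      x[i] = xn;
    }
    all_forces(S, x.data(), v.data(), f.data(), sf, gamma, sigma,
               inv_sqrt_dt, useed, ustep0 + (uint64_t)s + 1,
               bond_i.begin(), bond_j.begin(), bond_r0.begin(),
               bond_kb.begin(), nb, ang_i.begin(), ang_j.begin(),
               ang_k.begin(), ang_th0.begin(), ang_ka.begin(), na);
    for (int i = 0; i < 3 * n; ++i) v[i] += half_dt * f[i];
    std::swap(f, fold);
    if ((s + 1) % stride == 0) {
      NumericMatrix fp(n, 3);
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        fp(i, 0) = x[3 * i]; fp(i, 1) = x[3 * i + 1]; fp(i, 2) = x[3 * i + 2];
      }
      for (int i = 0; i < 3 * n; ++i) ke += v[i] * v[i];
      frames[fr] = fp;
      temps[fr] = ke / (3.0 * n);
      frame_steps[fr] = (double)(ustep0 + s + 1);
      ++fr;
    }
  }
  NumericMatrix pout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i) {
    pout(i, 0) = x[3 * i]; pout(i, 1) = x[3 * i + 1]; pout(i, 2) = x[3 * i + 2];
    vout(i, 0) = v[3 * i]; vout(i, 1) = v[3 * i + 1]; vout(i, 2) = v[3 * i + 2];
  }
  return List::create(_["frames"] = frames, _["temperatures"] = temps,
                      _["frame_steps"] = frame_steps, _["positions"] = pout,
                      _["velocities"] = vout,
                      _["final_step"] = (double)(ustep0 + nsteps));
}

// Single force evaluation; pairs are accumulated in sorted (i, j) order so
// that cell-list and all-pairs traversal give bitwise-identical sums.
// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, NumericMatrix vel,
                         IntegerVector type, NumericMatrix aM,
                         NumericMatrix RM, IntegerVector bond_i,
                         IntegerVector bond_j, NumericVector bond_r0,
                         NumericVector bond_kb, IntegerVector ang_i,
                         IntegerVector ang_j, IntegerVector ang_k,
                         NumericVector ang_th0, NumericVector ang_ka,
                         double L, double dt, double gamma, double sigma,
                         double seed, double step, bool use_cells) {
  int n = pos.nrow(), nt = aM.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n, 0.0);
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = pos(i, 0); x[3 * i + 1] = pos(i, 1); x[3 * i + 2] = pos(i, 2);
    v[3 * i] = vel(i, 0); v[3 * i + 1] = vel(i, 1); v[3 * i + 2] = vel(i, 2);
    ty[i] = type[i];
  }
  double maxR = 0.0;
  for (int i = 0; i < nt * nt; ++i) maxR = std::max(maxR, RM[i]);
  System S{n, nt, L, aM.begin(), RM.begin(), ty.data(), maxR};
  std::vector<std::pair<int, int>> pairs;
  if (use_cells) {
    CellList cl;
    cl.build(x.data(), n, L, maxR);
    for_each_pair_cells(S, x.data(), cl, [&](int i, int j) {
      pairs.emplace_back(std::min(i, j), std::max(i, j));
    });
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) pairs.emplace_back(i, j);
  }
  std::sort(pairs.begin(), pairs.end());
  double inv_sqrt_dt = 1.0 / std::sqrt(dt);
  for (auto &p : pairs)
    nb_pair(S, x.data(), v.data(), f.data(), p.first, p.second, gamma, sigma,
            inv_sqrt_dt, (uint64_t)seed, (uint64_t)step);
  bonded_forces(x.data(), f.data(), L, bond_i.begin(), bond_j.begin(),
                bond_r0.begin(), bond_kb.begin(), bond_i.size(),
                ang_i.begin(), ang_j.begin(), ang_k.begin(), ang_th0.begin(),
                ang_ka.begin(), ang_i.size());
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = f[3 * i]; out(i, 1) = f[3 * i + 1]; out(i, 2) = f[3 * i + 2];
  }
  return out;
}

// All unordered particle pairs with minimum-image distance below cutoff.
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(NumericMatrix pos, double L, double cutoff) {
  int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = pos(i, 0); x[3 * i + 1] = pos(i, 1); x[3 * i + 2] = pos(i, 2);
  }
  std::vector<int> out;
  double c2 = cutoff * cutoff;
  auto consider = [&](int i, int j) {
    double dx = min_image(x[3 * i] - x[3 * j], L);
    double dy = min_image(x[3 * i + 1] - x[3 * j + 1], L);
    double dz = min_image(x[3 * i + 2] - x[3 * j + 2], L);
    if (dx * dx + dy * dy + dz * dz < c2) {
      out.push_back(std::min(i, j)); out.push_back(std::max(i, j));
    }
  };
  int nc = (int)std::floor(L / cutoff);
  if (nc >= 3) {
    System S{n, 1, L, nullptr, nullptr, nullptr, cutoff};
    CellList cl;
    cl.build(x.data(), n, L, cutoff);
    for_each_pair_cells(S, x.data(), cl, consider);
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) consider(i, j);
  }
  int m = out.size() / 2;
  IntegerMatrix res(m, 2);
  for (int k = 0; k < m; ++k) {
    res(k, 0) = out[2 * k] + 1; res(k, 1) = out[2 * k + 1] + 1; // 1-based
  }
  return res;
}
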