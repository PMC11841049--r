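// Core DPD engine: soft pair repulsions, pairwise dissipative/random
// thermostat, harmonic bonds and angles, smooth repulsive walls with
// specular reflection, virial pressure tensor (wall-force augmented),
// modified velocity-Verlet integration and a Langevin-piston barostat.
//
// Conventions (documented in the R wrappers and the methods vignette):
//  - all quantities in reduced DPD units (length r_c, energy k_B T, mass 1)
//  - conservative pair force  A_ij (1 - r/R_ij) ê        for r < R_ij
//  - dissipative force       -gamma w^2 (ê·v_ij) ê,  w = 1 - r/r_cut
//  - random force             sigma w xi dt^{-1/2} ê,  xi uniform, var 1,
//                             symmetric under i<->j (counter-based hash RNG)
//  - bond U = (k_b/2)(r - r0)^2 ; angle U = (k_a/2)(theta - theta0)^2
//  - wall  U = (A_s/2)(1 - z)^2 for z < 1, mirrored at z = L_z
//  - virial uses conservative (pair + bonded + wall) forces only; the
//    dissipative and random contributions average to zero at equilibrium.
//
// Memory layout: position and force for each bead share one cache line
// (stride-8 doubles) so the pair loop touches at most two lines per
// neighbor; velocities live in a packed triplet array.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// uniform in (0,1)
static inline double u01(uint64_t h) {
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// zero-mean unit-variance symmetric uniform deviate for the random force
static inline double pair_noise(uint64_t seed, uint64_t step, int i, int j) {
  uint64_t a = (i < j) ? (uint64_t)i : (uint64_t)j;
  uint64_t b = (i < j) ? (uint64_t)j : (uint64_t)i;
  uint64_t h = splitmix64(seed ^ splitmix64(step ^ splitmix64((a << 32) | b)));
  return 1.7320508075688772 * (2.0 * u01(h) - 1.0);
}

static inline double gauss_noise(uint64_t seed, uint64_t step, uint64_t tag) {
  uint64_t h1 = splitmix64(seed ^ splitmix64((step << 8) ^ tag));
  uint64_t h2 = splitmix64(h1 ^ 0xD1B54A32D192ED03ULL);
  double u1 = u01(h1), u2 = u01(h2);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

struct Engine {
  int N, nspec;
  std::vector<double> buf;  // backing store for the aligned stride-8 block
  double *pq = nullptr;     // per bead: x y z fx fy fz (2 spare), stride 8
  std::vector<double> vv;   // velocities, packed triplets
  std::vector<int> spec;    // 0-based
  double Lx, Ly, Lz;
  bool walled;
  std::vector<double> Amat, Rmat;   // nspec x nspec, row-major
  std::vector<double> iRmat, ARmat; // 1/R and A*R, precomputed for the sweep
  std::vector<double> wallA;      // per species
  double wallRange;
  std::vector<int> b_i, b_j;      // 0-based
  std::vector<double> b_k, b_r0;
  std::vector<int> a_i, a_j, a_k; // j is the central bead
  std::vector<double> a_ka, a_th0;
  int angle_style = 1; // 0: U = (k/2)(th-th0)^2 ; 1: U = k(1-cos(th-th0))

  double dt, Temp, gamma_d, sigma, rcut, rcut2, lambda, inv_sqrt_dt;
  uint64_t seed;
  uint64_t step = 0;
  bool with_thermo = true;

  // Verlet neighbor list (skin 0.3 r_c; rebuilt when the two largest
  // displacements since the last build sum to more than the skin)
  double skin = 0.3;
  std::vector<int> nl_i, nl_j;
  std::vector<unsigned char> nl_code; // periodic image shift, base-3 encoded
  std::vector<double> qb;             // positions at last build, triplets
  bool nl_valid = false;

  // per-evaluation accumulators
  double vir[6];   // xx yy zz xy xz yz, conservative pair+bonded
  double wallvir;  // sum f_wall,z * (distance from own wall), adds to Pzz*V
  double e_pair, e_bond, e_angle, e_wall;

  void alloc(int n) {
    N = n;
    buf.assign((size_t)8 * N + 8, 0.0);
    uintptr_t p = (uintptr_t)buf.data();
    pq = buf.data() + ((64 - p % 64) % 64) / 8;
    vv.assign((size_t)3 * N, 0.0);
    qb.assign((size_t)3 * N, 0.0);
  }

  inline double volume() const { return Lx * Ly * Lz; }

  // slow-path reference version, used by the neighbor-list-free callers
  inline void pair_interaction(int i, int j, double sx, double sy, double sz,
                               bool noise) {
    double *pi = pq + 8 * i, *pj = pq + 8 * j;
    double dx = pi[0] - pj[0] + sx;
    double dy = pi[1] - pj[1] + sy;
    double dz = pi[2] - pj[2] + sz;
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rcut2) return;
    if (r2 < 1e-24) stop("singular configuration: coincident beads");
    double r = std::sqrt(r2);
    double invr = 1.0 / r;
    int si = spec[i], sj = spec[j];
    double Rij = Rmat[si * nspec + sj];
    double fc = 0.0;
    if (r < Rij) {
      double omr = 1.0 - r / Rij;
      fc = Amat[si * nspec + sj] * omr;
      e_pair += 0.5 * Amat[si * nspec + sj] * Rij * omr * omr;
    }
    double ft = fc;
    if (with_thermo) {
      double w = 1.0 - r * (1.0 / rcut);
      double *vi = &vv[3 * i], *vj = &vv[3 * j];
      double vdot = dx * (vi[0] - vj[0]) + dy * (vi[1] - vj[1]) +
                    dz * (vi[2] - vj[2]);
      ft += -gamma_d * w * w * vdot * invr;
      if (noise)
        ft += sigma * w * pair_noise(seed, step, i, j) * inv_sqrt_dt;
    }
    double g = ft * invr;
    pi[3] += g * dx; pi[4] += g * dy; pi[5] += g * dz;
    pj[3] -= g * dx; pj[4] -= g * dy; pj[5] -= g * dz;
    // conservative part only in the virial
    double gc = fc * invr;
    vir[0] += gc * dx * dx;
    vir[1] += gc * dy * dy;
    vir[2] += gc * dz * dz;
    vir[3] += gc * dx * dy;
    vir[4] += gc * dx * dz;
    vir[5] += gc * dy * dz;
  }

  // hot pair loop over the whole neighbor list: restrict-qualified pointers
  // and local accumulators so stores to the force block cannot force
  // reloads of the tables or the running sums
  void pair_sweep(bool noise) {
    double shx[27], shy[27], shz[27];
    for (int c = 0; c < 27; ++c) {
      shx[c] = (c % 3 - 1) * Lx;
      shy[c] = ((c / 3) % 3 - 1) * Ly;
      shz[c] = (c / 9 - 1) * Lz;
    }
    double *__restrict q = pq;
    const double *__restrict v = vv.data();
    const int *__restrict sp = spec.data();
    const double *__restrict Am = Amat.data();
    const double *__restrict iRm = iRmat.data();
    const double *__restrict ARm = ARmat.data();
    const int *__restrict ii = nl_i.data();
    const int *__restrict jj = nl_j.data();
    const unsigned char *__restrict cc = nl_code.data();
    const size_t np = nl_n;
    const int ns = nspec;
    const double rc2 = rcut2, invrc = 1.0 / rcut;
    const double gam = gamma_d, sfac = sigma * inv_sqrt_dt;
    const bool thermo = with_thermo;
    const uint64_t sd = seed, st = step;
    double vxx = 0, vyy = 0, vzz = 0, vxy = 0, vxz = 0, vyz = 0, epair = 0;
    bool bad = false;
    for (size_t k = 0; k < np; ++k) {
      const int i = ii[k], j = jj[k], c = cc[k];
      double *__restrict pi = q + 8 * i;
      double *__restrict pj = q + 8 * j;
      double dx = pi[0] - pj[0] + shx[c];
      double dy = pi[1] - pj[1] + shy[c];
      double dz = pi[2] - pj[2] + shz[c];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      if (r2 < 1e-24) { bad = true; continue; }
      double r = std::sqrt(r2);
      double invr = 1.0 / r;
      int off = sp[i] * ns + sp[j];
      double omr = 1.0 - r * iRm[off];
      double fc = 0.0;
      if (omr > 0.0) {
        fc = Am[off] * omr;
        epair += 0.5 * ARm[off] * omr * omr;
      }
      double ft = fc;
      if (thermo) {
        double w = 1.0 - r * invrc;
        const double *__restrict vi = v + 3 * i;
        const double *__restrict vj = v + 3 * j;
        double vdot = dx * (vi[0] - vj[0]) + dy * (vi[1] - vj[1]) +
                      dz * (vi[2] - vj[2]);
        ft -= gam * w * w * vdot * invr;
        if (noise) ft += sfac * w * pair_noise(sd, st, i, j);
      }
      double g = ft * invr;
      pi[3] += g * dx; pi[4] += g * dy; pi[5] += g * dz;
      pj[3] -= g * dx; pj[4] -= g * dy; pj[5] -= g * dz;
      double gc = fc * invr;
      vxx += gc * dx * dx;
      vyy += gc * dy * dy;
      vzz += gc * dz * dz;
      vxy += gc * dx * dy;
      vxz += gc * dx * dz;
      vyz += gc * dy * dz;
    }
    if (bad) stop("singular configuration: coincident beads");
    vir[0] += vxx; vir[1] += vyy; vir[2] += vzz;
    vir[3] += vxy; vir[4] += vxz; vir[5] += vyz;
    e_pair += epair;
  }

  inline double mimg(double d, double L) const {
    return d - L * std::nearbyint(d / L);
  }

  void bonded_forces() {
    const int nb = (int)b_i.size();
    for (int b = 0; b < nb; ++b) {
      int i = b_i[b], j = b_j[b];
      double *pi = pq + 8 * i, *pj = pq + 8 * j;
      double dx = mimg(pi[0] - pj[0], Lx);
      double dy = mimg(pi[1] - pj[1], Ly);
      double dz = pi[2] - pj[2];
      if (!walled) dz = mimg(dz, Lz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) stop("singular configuration: coincident bonded beads");
      double dr = r - b_r0[b];
      double fmag = -b_k[b] * dr;  // along ê, restoring
      e_bond += 0.5 * b_k[b] * dr * dr;
      double g = fmag / r;
      pi[3] += g * dx; pi[4] += g * dy; pi[5] += g * dz;
      pj[3] -= g * dx; pj[4] -= g * dy; pj[5] -= g * dz;
      vir[0] += g * dx * dx; vir[1] += g * dy * dy; vir[2] += g * dz * dz;
      vir[3] += g * dx * dy; vir[4] += g * dx * dz; vir[5] += g * dy * dz;
    }
    const int na = (int)a_i.size();
    for (int t = 0; t < na; ++t) {
      int i = a_i[t], j = a_j[t], k = a_k[t];
      double *pi = pq + 8 * i, *pj = pq + 8 * j, *pk = pq + 8 * k;
      double ax = mimg(pi[0] - pj[0], Lx);
      double ay = mimg(pi[1] - pj[1], Ly);
      double az = pi[2] - pj[2];
      double bx = mimg(pk[0] - pj[0], Lx);
      double by = mimg(pk[1] - pj[1], Ly);
      double bz = pk[2] - pj[2];
      if (!walled) { az = mimg(az, Lz); bz = mimg(bz, Lz); }
      double la = std::sqrt(ax * ax + ay * ay + az * az);
      double lb = std::sqrt(bx * bx + by * by + bz * bz);
      if (la < 1e-12 || lb < 1e-12)
        stop("singular configuration: coincident angle beads");
      double cth = (ax * bx + ay * by + az * bz) / (la * lb);
      if (cth > 1.0) cth = 1.0;
      if (cth < -1.0) cth = -1.0;
      double th = std::acos(cth);
      double sth = std::sqrt(1.0 - cth * cth);
      if (sth < 1e-8) sth = 1e-8;
      double dth = th - a_th0[t];
      double coef; // f_i = coef * dcos/da, coef = (dU/dth)/sin(th)
      if (angle_style == 0) {
        e_angle += 0.5 * a_ka[t] * dth * dth;
        coef = a_ka[t] * dth / sth;
      } else {
        e_angle += a_ka[t] * (1.0 - std::cos(dth));
        coef = a_ka[t] * std::sin(dth) / sth;
      }
      double ilab = 1.0 / (la * lb), ila2 = 1.0 / (la * la),
             ilb2 = 1.0 / (lb * lb);
      double fix = coef * (bx * ilab - cth * ax * ila2);
      double fiy = coef * (by * ilab - cth * ay * ila2);
      double fiz = coef * (bz * ilab - cth * az * ila2);
      double fkx = coef * (ax * ilab - cth * bx * ilb2);
      double fky = coef * (ay * ilab - cth * by * ilb2);
      double fkz = coef * (az * ilab - cth * bz * ilb2);
      pi[3] += fix; pi[4] += fiy; pi[5] += fiz;
      pk[3] += fkx; pk[4] += fky; pk[5] += fkz;
      pj[3] -= fix + fkx; pj[4] -= fiy + fky; pj[5] -= fiz + fkz;
      vir[0] += fix * ax + fkx * bx;
      vir[1] += fiy * ay + fky * by;
      vir[2] += fiz * az + fkz * bz;
      vir[3] += fix * ay + fkx * by;
      vir[4] += fix * az + fkx * bz;
      vir[5] += fiy * az + fky * bz;
    }
  }

  void wall_forces() {
    if (!walled) return;
    for (int i = 0; i < N; ++i) {
      double As = wallA[spec[i]];
      if (As <= 0.0) continue;
      double *pi = pq + 8 * i;
      double zi = pi[2];
      if (zi < wallRange) {
        double omz = 1.0 - zi / wallRange;
        double f = As * omz;  // +z, away from lower wall
        pi[5] += f;
        e_wall += 0.5 * As * wallRange * omz * omz;
        wallvir += f * zi;
      }
      double zp = Lz - zi;
      if (zp < wallRange) {
        double omz = 1.0 - zp / wallRange;
        double f = As * omz;  // magnitude, directed -z
        pi[5] -= f;
        e_wall += 0.5 * As * wallRange * omz * omz;
        wallvir += f * zp;
      }
    }
  }

  size_t nl_n = 0;  // logical length of the neighbor list

  inline void nl_grow() {
    size_t cap = nl_i.size() < 1024 ? 4096 : 2 * nl_i.size();
    nl_i.resize(cap);
    nl_j.resize(cap);
    nl_code.resize(cap);
  }

  inline void nl_push(int i, int j, int cx, int cy, int cz, double rv2) {
    double dx = pq[8 * i + 0] - pq[8 * j + 0] + cx * Lx;
    double dy = pq[8 * i + 1] - pq[8 * j + 1] + cy * Ly;
    double dz = pq[8 * i + 2] - pq[8 * j + 2] + cz * Lz;
    if (dx * dx + dy * dy + dz * dz < rv2) {
      if (nl_n == nl_i.size()) nl_grow();
      nl_i[nl_n] = i;
      nl_j[nl_n] = j;
      nl_code[nl_n] = (unsigned char)((cx + 1) + 3 * (cy + 1) + 9 * (cz + 1));
      ++nl_n;
    }
  }

  void build_nlist() {
    // Coordinates are wrapped only here, so that the stored periodic-image
    // codes stay valid between rebuilds (beads move < skin/2 in between).
    for (int i = 0; i < N; ++i) {
      double *pi = pq + 8 * i;
      pi[0] -= Lx * std::floor(pi[0] / Lx);
      pi[1] -= Ly * std::floor(pi[1] / Ly);
      if (!walled) pi[2] -= Lz * std::floor(pi[2] / Lz);
    }
    nl_n = 0;
    double rv = rcut + skin, rv2 = rv * rv;
    int ncx = (int)std::floor(Lx / rv);
    int ncy = (int)std::floor(Ly / rv);
    int ncz = (int)std::floor(Lz / rv);
    bool cells_ok = ncx >= 3 && ncy >= 3 && (walled ? ncz >= 1 : ncz >= 3) &&
                    N > 64;
    if (!cells_ok) {
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) {
          int cx = -(int)std::nearbyint((pq[8 * i] - pq[8 * j]) / Lx);
          int cy = -(int)std::nearbyint((pq[8 * i + 1] - pq[8 * j + 1]) / Ly);
          int cz = walled ? 0
                          : -(int)std::nearbyint((pq[8 * i + 2] - pq[8 * j + 2]) / Lz);
          nl_push(i, j, cx, cy, cz, rv2);
        }
    } else {
      // counting-sort binning: beads of each cell are contiguous in `order`
      double clx = Lx / ncx, cly = Ly / ncy, clz = Lz / ncz;
      int ncell = ncx * ncy * ncz;
      std::vector<int> cellof(N), start(ncell + 1, 0), order(N), fill(ncell);
      for (int i = 0; i < N; ++i) {
        int cxi = (int)(pq[8 * i] / clx);
        int cyi = (int)(pq[8 * i + 1] / cly);
        int czi = (int)(pq[8 * i + 2] / clz);
        if (cxi >= ncx) cxi = ncx - 1; if (cxi < 0) cxi = 0;
        if (cyi >= ncy) cyi = ncy - 1; if (cyi < 0) cyi = 0;
        if (czi >= ncz) czi = ncz - 1; if (czi < 0) czi = 0;
        int c = (czi * ncy + cyi) * ncx + cxi;
        cellof[i] = c;
        ++start[c + 1];
      }
      for (int c = 0; c < ncell; ++c) start[c + 1] += start[c];
      for (int c = 0; c < ncell; ++c) fill[c] = start[c];
      for (int i = 0; i < N; ++i) order[fill[cellof[i]]++] = i;
      // gather cell-sorted coordinates so the check loops read sequentially
      std::vector<double> gx(N), gy(N), gz(N);
      for (int u = 0; u < N; ++u) {
        int i = order[u];
        gx[u] = pq[8 * i];
        gy[u] = pq[8 * i + 1];
        gz[u] = pq[8 * i + 2];
      }
      static const int OFF[13][3] = {
        {1,0,0},{-1,1,0},{0,1,0},{1,1,0},
        {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},
        {-1,1,1},{0,1,1},{1,1,1}};
      for (int cz_ = 0; cz_ < ncz; ++cz_)
        for (int cy_ = 0; cy_ < ncy; ++cy_)
          for (int cx_ = 0; cx_ < ncx; ++cx_) {
            int c = (cz_ * ncy + cy_) * ncx + cx_;
            int c0 = start[c], c1 = start[c + 1];
            for (int u = c0; u < c1; ++u) {
              const int i = order[u];
              const double xi = gx[u], yi = gy[u], zi = gz[u];
              for (int w = u + 1; w < c1; ++w) {
                double dx = xi - gx[w];
                double dy = yi - gy[w];
                double dz = zi - gz[w];
                if (dx * dx + dy * dy + dz * dz < rv2) {
                  if (nl_n == nl_i.size()) nl_grow();
                  nl_i[nl_n] = i; nl_j[nl_n] = order[w]; nl_code[nl_n] = 13;
                  ++nl_n;
                }
              }
            }
            for (int o = 0; o < 13; ++o) {
              int nx_ = cx_ + OFF[o][0], ny_ = cy_ + OFF[o][1],
                  nz_ = cz_ + OFF[o][2];
              // shift applies to j as the image of cell n adjacent to cell c
              int cxs = 0, cys = 0, czs = 0;
              if (nx_ < 0) { nx_ += ncx; cxs = 1; }
              else if (nx_ >= ncx) { nx_ -= ncx; cxs = -1; }
              if (ny_ < 0) { ny_ += ncy; cys = 1; }
              else if (ny_ >= ncy) { ny_ -= ncy; cys = -1; }
              if (nz_ < 0) {
                if (walled) continue;
                nz_ += ncz; czs = 1;
              } else if (nz_ >= ncz) {
                if (walled) continue;
                nz_ -= ncz; czs = -1;
              }
              int n = (nz_ * ncy + ny_) * ncx + nx_;
              int n0 = start[n], n1 = start[n + 1];
              const double sx = cxs * Lx, sy = cys * Ly, sz = czs * Lz;
              const unsigned char code =
                  (unsigned char)((cxs + 1) + 3 * (cys + 1) + 9 * (czs + 1));
              for (int u = c0; u < c1; ++u) {
                const int i = order[u];
                const double xi = gx[u] + sx, yi = gy[u] + sy, zi = gz[u] + sz;
                for (int w = n0; w < n1; ++w) {
                  double dx = xi - gx[w];
                  double dy = yi - gy[w];
                  double dz = zi - gz[w];
                  if (dx * dx + dy * dy + dz * dz < rv2) {
                    if (nl_n == nl_i.size()) nl_grow();
                    nl_i[nl_n] = i; nl_j[nl_n] = order[w]; nl_code[nl_n] = code;
                    ++nl_n;
                  }
                }
              }
            }
          }
    }
    for (int i = 0; i < N; ++i) {
      qb[3 * i] = pq[8 * i];
      qb[3 * i + 1] = pq[8 * i + 1];
      qb[3 * i + 2] = pq[8 * i + 2];
    }
    nl_valid = true;
  }

  bool nlist_stale() {
    if (!nl_valid) return true;
    // a pair can have closed by at most the two largest displacements
    double m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < N; ++i) {
      double dx = pq[8 * i] - qb[3 * i];
      double dy = pq[8 * i + 1] - qb[3 * i + 1];
      double dz = pq[8 * i + 2] - qb[3 * i + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > m2) {
        if (d2 > m1) { m2 = m1; m1 = d2; } else m2 = d2;
      }
    }
    return std::sqrt(m1) + std::sqrt(m2) > skin;
  }

  void compute_forces(bool noise) {
    for (int i = 0; i < N; ++i) {
      pq[8 * i + 3] = 0.0;
      pq[8 * i + 4] = 0.0;
      pq[8 * i + 5] = 0.0;
    }
    for (int c = 0; c < 6; ++c) vir[c] = 0.0;
    wallvir = 0.0;
    e_pair = e_bond = e_angle = e_wall = 0.0;

    if (nlist_stale()) build_nlist();
    pair_sweep(noise);
    bonded_forces();
    wall_forces();
  }

  // one modified velocity-Verlet DPD step (Groot-Warren, parameter lambda)
  void mvv_step(std::vector<double> &vh) {
    double hdt = 0.5 * dt, ldt = lambda * dt, hdt2 = 0.5 * dt * dt;
    double maxd = 0.25 * std::min(std::min(Lx, Ly), Lz);
    double maxd2 = maxd * maxd;
    for (int i = 0; i < N; ++i) {
      double *pi = pq + 8 * i;
      double *vi = &vv[3 * i];
      double *vhi = &vh[3 * i];
      double ddx = dt * vi[0] + hdt2 * pi[3];
      double ddy = dt * vi[1] + hdt2 * pi[4];
      double ddz = dt * vi[2] + hdt2 * pi[5];
      if (ddx * ddx + ddy * ddy + ddz * ddz > maxd2)
        stop("integration instability: bead displacement exceeds box/4 in one step (step %d)",
             (int)step);
      pi[0] += ddx; pi[1] += ddy; pi[2] += ddz;
      vhi[0] = vi[0] + hdt * pi[3];
      vhi[1] = vi[1] + hdt * pi[4];
      vhi[2] = vi[2] + hdt * pi[5];
      vi[0] += ldt * pi[3];  // predicted velocity used in dissipative force
      vi[1] += ldt * pi[4];
      vi[2] += ldt * pi[5];
      // in-plane wrapping is deferred to the neighbor-list rebuild;
      // the hard walls reflect immediately
      if (walled) {
        if (pi[2] < 0.0) {
          pi[2] = -pi[2];
          vi[2] = -vi[2];
          vhi[2] = -vhi[2];
        } else if (pi[2] > Lz) {
          pi[2] = 2.0 * Lz - pi[2];
          vi[2] = -vi[2];
          vhi[2] = -vhi[2];
        }
        if (pi[2] < 0.0 || pi[2] > Lz)
          stop("integration instability: double wall crossing in one step");
      }
    }
    ++step;
    compute_forces(with_thermo);
    for (int i = 0; i < N; ++i) {
      double *pi = pq + 8 * i;
      double *vi = &vv[3 * i];
      double *vhi = &vh[3 * i];
      vi[0] = vhi[0] + hdt * pi[3];
      vi[1] = vhi[1] + hdt * pi[4];
      vi[2] = vhi[2] + hdt * pi[5];
    }
  }
};

static Engine make_engine(NumericMatrix pos, NumericMatrix vel,
                          IntegerVector species, NumericMatrix A,
                          NumericMatrix Rij, NumericMatrix bonds,
                          NumericMatrix angles, NumericVector box,
                          bool walled, NumericVector wallA, double wallRange,
                          double dt, double temperature, double gamma,
                          double rcut_thermo, double lambda, double seed) {
  Engine e;
  e.nspec = A.nrow();
  e.alloc(pos.nrow());
  e.spec.resize(e.N);
  for (int i = 0; i < e.N; ++i) {
    e.pq[8 * i] = pos(i, 0);
    e.pq[8 * i + 1] = pos(i, 1);
    e.pq[8 * i + 2] = pos(i, 2);
    e.vv[3 * i] = vel(i, 0);
    e.vv[3 * i + 1] = vel(i, 1);
    e.vv[3 * i + 2] = vel(i, 2);
    e.spec[i] = species[i];
    if (e.spec[i] < 0 || e.spec[i] >= e.nspec) stop("species index out of range");
  }
  e.Lx = box[0]; e.Ly = box[1]; e.Lz = box[2];
  e.walled = walled;
  e.Amat.resize(e.nspec * e.nspec);
  e.Rmat.resize(e.nspec * e.nspec);
  e.iRmat.resize(e.nspec * e.nspec);
  e.ARmat.resize(e.nspec * e.nspec);
  double maxR = 0.0;
  for (int i = 0; i < e.nspec; ++i)
    for (int j = 0; j < e.nspec; ++j) {
      if (!(A(i, j) >= 0.0) || !(Rij(i, j) > 0.0))
        stop("pair table entries must have A >= 0 and R > 0");
      e.Amat[i * e.nspec + j] = A(i, j);
      e.Rmat[i * e.nspec + j] = Rij(i, j);
      e.iRmat[i * e.nspec + j] = 1.0 / Rij(i, j);
      e.ARmat[i * e.nspec + j] = A(i, j) * Rij(i, j);
      if (Rij(i, j) > maxR) maxR = Rij(i, j);
    }
  e.wallA.assign(e.nspec, 0.0);
  for (int i = 0; i < wallA.size() && i < e.nspec; ++i) e.wallA[i] = wallA[i];
  e.wallRange = wallRange;
  int nb = bonds.nrow();
  e.b_i.resize(nb); e.b_j.resize(nb); e.b_k.resize(nb); e.b_r0.resize(nb);
  for (int b = 0; b < nb; ++b) {
    e.b_i[b] = (int)bonds(b, 0) - 1;
    e.b_j[b] = (int)bonds(b, 1) - 1;
    e.b_k[b] = bonds(b, 2);
    e.b_r0[b] = bonds(b, 3);
    if (e.b_i[b] < 0 || e.b_i[b] >= e.N || e.b_j[b] < 0 || e.b_j[b] >= e.N)
      stop("bond index out of range");
  }
  int na = angles.nrow();
  e.a_i.resize(na); e.a_j.resize(na); e.a_k.resize(na);
  e.a_ka.resize(na); e.a_th0.resize(na);
  for (int t = 0; t < na; ++t) {
    e.a_i[t] = (int)angles(t, 0) - 1;
    e.a_j[t] = (int)angles(t, 1) - 1;
    e.a_k[t] = (int)angles(t, 2) - 1;
    e.a_ka[t] = angles(t, 3);
    e.a_th0[t] = angles(t, 4);
    if (e.a_i[t] < 0 || e.a_i[t] >= e.N || e.a_j[t] < 0 || e.a_j[t] >= e.N ||
        e.a_k[t] < 0 || e.a_k[t] >= e.N)
      stop("angle index out of range");
  }
  e.dt = dt;
  e.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  e.Temp = temperature;
  e.gamma_d = gamma;
  e.sigma = std::sqrt(2.0 * gamma * temperature);
  e.rcut = std::max(rcut_thermo, maxR);
  e.rcut2 = e.rcut * e.rcut;
  e.lambda = lambda;
  e.seed = (uint64_t)seed;
  e.with_thermo = gamma > 0.0;
  return e;
}

// [[Rcpp::export]]
List dpd_run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                 NumericMatrix A, NumericMatrix Rij, NumericMatrix bonds,
                 NumericMatrix angles, NumericVector box, bool walled,
                 NumericVector wallA, double wallRange, double dt, int nsteps,
                 double temperature, double gamma, double rcut_thermo,
                 double lambda, int sample_every, bool npt, double p_target,
                 double tau_p, double gamma_p, bool piston_noise, double seed,
                 double step_offset, int angle_style) {
  Engine e = make_engine(pos, vel, species, A, Rij, bonds, angles, box, walled,
                         wallA, wallRange, dt, temperature, gamma, rcut_thermo,
                         lambda, seed);
  e.angle_style = angle_style;
  e.step = (uint64_t)step_offset;
  if (npt && walled) stop("the barostat cannot be combined with walls");

  std::vector<double> vh((size_t)3 * e.N);
  int nsamp = sample_every > 0 ? nsteps / sample_every : 0;
  NumericMatrix samples(nsamp, 13);
  int isamp = 0;

  // piston state (isotropic, on ln V)
  double W = 3.0 * (e.N + 1) * temperature * tau_p * tau_p;
  double epsdot = 0.0;

  e.compute_forces(e.with_thermo);
  for (int s = 1; s <= nsteps; ++s) {
    e.mvv_step(vh);

    double kxx = 0, kyy = 0, kzz = 0;
    bool need_kin = npt || (sample_every > 0 && s % sample_every == 0);
    if (need_kin) {
      for (int i = 0; i < e.N; ++i) {
        kxx += e.vv[3 * i] * e.vv[3 * i];
        kyy += e.vv[3 * i + 1] * e.vv[3 * i + 1];
        kzz += e.vv[3 * i + 2] * e.vv[3 * i + 2];
      }
    }
    double V = e.volume();
    if (npt) {
      double pinst = (kxx + kyy + kzz + e.vir[0] + e.vir[1] + e.vir[2]) /
                     (3.0 * V);
      epsdot += dt * (3.0 * V * (pinst - p_target) - gamma_p * W * epsdot) / W;
      if (piston_noise)
        epsdot += std::sqrt(2.0 * gamma_p * temperature / W) * std::sqrt(dt) *
                  gauss_noise(e.seed, e.step, 0xB0A0ULL);
      double sfac = std::exp(epsdot * dt / 3.0);
      if (!(sfac > 0.0) || sfac > 1.05 || sfac < 0.95)
        stop("barostat instability: volume change too fast");
      e.Lx *= sfac; e.Ly *= sfac; e.Lz *= sfac;
      for (int i = 0; i < e.N; ++i) {
        e.pq[8 * i] *= sfac;
        e.pq[8 * i + 1] *= sfac;
        e.pq[8 * i + 2] *= sfac;
      }
      V = e.volume();
    }
    if (sample_every > 0 && s % sample_every == 0) {
      double kxy = 0, kxz = 0, kyz = 0;
      for (int i = 0; i < e.N; ++i) {
        kxy += e.vv[3 * i] * e.vv[3 * i + 1];
        kxz += e.vv[3 * i] * e.vv[3 * i + 2];
        kyz += e.vv[3 * i + 1] * e.vv[3 * i + 2];
      }
      samples(isamp, 0) = s;
      samples(isamp, 1) = (kxx + kyy + kzz) / (3.0 * (e.N - 1));
      samples(isamp, 2) = e.N / V;
      samples(isamp, 3) = (kxx + e.vir[0]) / V;
      samples(isamp, 4) = (kyy + e.vir[1]) / V;
      samples(isamp, 5) = (kzz + e.vir[2] + e.wallvir) / V;
      samples(isamp, 6) = (kxy + e.vir[3]) / V;
      samples(isamp, 7) = (kxz + e.vir[4]) / V;
      samples(isamp, 8) = (kyz + e.vir[5]) / V;
      samples(isamp, 9) = e.Lx;
      samples(isamp, 10) = e.Ly;
      samples(isamp, 11) = e.Lz;
      samples(isamp, 12) = e.wallvir / V;
      ++isamp;
    }
  }

  NumericMatrix opos(e.N, 3), ovel(e.N, 3);
  for (int i = 0; i < e.N; ++i) {
    double *pi = e.pq + 8 * i;
    pi[0] -= e.Lx * std::floor(pi[0] / e.Lx);
    pi[1] -= e.Ly * std::floor(pi[1] / e.Ly);
    if (!walled) pi[2] -= e.Lz * std::floor(pi[2] / e.Lz);
    opos(i, 0) = pi[0]; opos(i, 1) = pi[1]; opos(i, 2) = pi[2];
    ovel(i, 0) = e.vv[3 * i];
    ovel(i, 1) = e.vv[3 * i + 1];
    ovel(i, 2) = e.vv[3 * i + 2];
  }
  return List::create(
      _["positions"] = opos, _["velocities"] = ovel,
      _["box"] = NumericVector::create(e.Lx, e.Ly, e.Lz),
      _["samples"] = samples, _["steps_done"] = nsteps,
      _["step_offset"] = (double)e.step);
}

// Deterministic single-configuration evaluation: conservative forces
// (pair + bond + angle + wall), energy breakdown and the full pressure
// tensor (kinetic + conservative virial, wall term in the zz component).
// [[Rcpp::export]]
List dpd_eval_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                  NumericMatrix A, NumericMatrix Rij, NumericMatrix bonds,
                  NumericMatrix angles, NumericVector box, bool walled,
                  NumericVector wallA, double wallRange, double rcut_thermo,
                  int angle_style) {
  Engine e = make_engine(pos, vel, species, A, Rij, bonds, angles, box, walled,
                         wallA, wallRange, 0.02, 1.0, 0.0, rcut_thermo, 0.5,
                         1.0);
  e.angle_style = angle_style;
  e.compute_forces(false);
  double V = e.volume();
  NumericMatrix F(e.N, 3), P(3, 3), K(3, 3), Wv(3, 3);
  double kin[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 0; i < e.N; ++i) {
    F(i, 0) = e.pq[8 * i + 3];
    F(i, 1) = e.pq[8 * i + 4];
    F(i, 2) = e.pq[8 * i + 5];
    kin[0] += e.vv[3 * i] * e.vv[3 * i];
    kin[1] += e.vv[3 * i + 1] * e.vv[3 * i + 1];
    kin[2] += e.vv[3 * i + 2] * e.vv[3 * i + 2];
    kin[3] += e.vv[3 * i] * e.vv[3 * i + 1];
    kin[4] += e.vv[3 * i] * e.vv[3 * i + 2];
    kin[5] += e.vv[3 * i + 1] * e.vv[3 * i + 2];
  }
  K(0, 0) = kin[0]; K(1, 1) = kin[1]; K(2, 2) = kin[2];
  K(0, 1) = K(1, 0) = kin[3]; K(0, 2) = K(2, 0) = kin[4];
  K(1, 2) = K(2, 1) = kin[5];
  Wv(0, 0) = e.vir[0]; Wv(1, 1) = e.vir[1]; Wv(2, 2) = e.vir[2];
  Wv(0, 1) = Wv(1, 0) = e.vir[3]; Wv(0, 2) = Wv(2, 0) = e.vir[4];
  Wv(1, 2) = Wv(2, 1) = e.vir[5];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) P(a, b) = (K(a, b) + Wv(a, b)) / V;
  P(2, 2) += e.wallvir / V;
  return List::create(
      _["forces"] = F, _["pressure"] = P, _["kinetic"] = K, _["virial"] = Wv,
      _["wall_virial"] = e.wallvir, _["wall_pzz"] = e.wallvir / V,
      _["energy"] = List::create(_["pair"] = e.e_pair, _["bond"] = e.e_bond,
                                 _["angle"] = e.e_angle, _["wall"] = e.e_wall));
}
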