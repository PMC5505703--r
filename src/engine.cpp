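// Center-based overdamped epidermis engine.
//
// Cells are spheres above an immobile membrane-particle monolayer in a
// laterally periodic box (open in z). All randomness flows through R's RNG
// (unif_rand), consumed in documented ascending-id order, so R-level
// single-operation code and this fused loop can share one stream.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const int K_STEM = 1, K_DAUGHTER = 2, K_SUPRA = 3, K_CORN = 4;
static const int EV_DIV_START = 1, EV_DIV_COMPLETE = 2, EV_DETACH = 3,
                 EV_CORNIFY = 4, EV_DESQ = 5;

// stage bits for partial stepping (used by tests and the R-level ops)
static const int ST_MECH = 1, ST_PAIRS = 2, ST_CYCLE = 4, ST_DIV = 8,
                 ST_ATTACH = 16, ST_CALCIUM = 32, ST_DIFF = 64,
                 ST_CORNIFY = 128, ST_DESQ = 256;

struct Par {
  double mu, R, Rm, eps, Ks, Kd, a, b, Kprime, gamma, alpha, T_cycle, dt,
      day_unit, S_star, s_base, lam_ca, c_exc, k_ca, desq_rate, ccf,
      max_disp;
  bool lj_printed, axis_in_plane;
  double rstar() const { return R + Rm + a / b; }
};

static Par read_par(const List& p) {
  Par q;
  q.mu = p["mu"]; q.R = p["R"]; q.Rm = p["Rm"]; q.eps = p["eps"];
  q.Ks = p["Ks"]; q.Kd = p["Kd"]; q.a = p["a"]; q.b = p["b"];
  q.Kprime = p["Kprime"]; q.gamma = p["gamma"]; q.alpha = p["alpha"];
  q.T_cycle = p["T_cycle"]; q.dt = p["dt"]; q.day_unit = p["day_unit"];
  q.S_star = p["S_star"]; q.s_base = p["s_base"]; q.lam_ca = p["lam_ca"];
  q.c_exc = p["c_exc"]; q.k_ca = p["k_ca"]; q.desq_rate = p["desq_rate"];
  q.ccf = p["contact_cutoff_factor"];
  q.max_disp = p["max_step_disp"];
  q.lj_printed = as<int>(p["lj_printed"]) != 0;
  q.axis_in_plane = as<int>(p["axis_in_plane"]) != 0;
  return q;
}

struct Mem {
  NumericMatrix pos;
  double Lx, Ly, sx, sy, Rm, zmax;
  int nx, ny;
};

static Mem read_mem(const List& m) {
  Mem q;
  q.pos = as<NumericMatrix>(m["pos"]);
  q.Lx = m["Lx"]; q.Ly = m["Ly"]; q.sx = m["sx"]; q.sy = m["sy"];
  q.Rm = m["Rm"]; q.nx = m["nx"]; q.ny = m["ny"];
  q.zmax = R_NegInf;
  for (int i = 0; i < q.pos.nrow(); ++i)
    if (q.pos(i, 2) > q.zmax) q.zmax = q.pos(i, 2);
  return q;
}

struct State {
  double time, Lx, Ly;
  std::vector<int> id, kind, pair;
  std::vector<double> x, y, z, cycle, S, ca, birth;
  // active division pairs
  std::vector<int> p_id, p_c1, p_c2, p_kind;
  std::vector<double> p_t0, p_ax, p_ay, p_az;
  int next_id, next_pair;
  std::vector<double> events;  // rows of 12
  int n() const { return (int)id.size(); }
  void push_event(int type, double t, int i1, int i2, int i3, int kd,
                  double ex, double ey, double ez, double v1, double v2,
                  double v3) {
    double row[12] = {(double)type, t, (double)i1, (double)i2, (double)i3,
                      (double)kd, ex, ey, ez, v1, v2, v3};
    events.insert(events.end(), row, row + 12);
  }
  int index_of(int cid) const {  // ids ascending in storage
    int lo = 0, hi = n() - 1;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (id[mid] == cid) return mid;
      if (id[mid] < cid) lo = mid + 1; else hi = mid - 1;
    }
    return -1;
  }
};

static State read_state(const List& s) {
  State q;
  q.time = s["time"]; q.Lx = s["Lx"]; q.Ly = s["Ly"];
  IntegerVector id = s["id"], kind = s["kind"], pair = s["pair"];
  NumericMatrix pos = s["pos"];
  NumericVector cy = s["cycle"], S = s["S"], ca = s["calcium"],
                bt = s["birth"];
  int n = id.size();
  q.id.assign(id.begin(), id.end());
  q.kind.assign(kind.begin(), kind.end());
  q.pair.assign(pair.begin(), pair.end());
  q.x.resize(n); q.y.resize(n); q.z.resize(n);
  for (int i = 0; i < n; ++i) { q.x[i]=pos(i,0); q.y[i]=pos(i,1); q.z[i]=pos(i,2); }
  q.cycle.assign(cy.begin(), cy.end());
  q.S.assign(S.begin(), S.end());
  q.ca.assign(ca.begin(), ca.end());
  q.birth.assign(bt.begin(), bt.end());
  IntegerVector pid = s["p_id"], pc1 = s["p_c1"], pc2 = s["p_c2"],
                pk = s["p_kind"];
  NumericVector pt0 = s["p_t0"], pax = s["p_ax"], pay = s["p_ay"],
                paz = s["p_az"];
  q.p_id.assign(pid.begin(), pid.end());
  q.p_c1.assign(pc1.begin(), pc1.end());
  q.p_c2.assign(pc2.begin(), pc2.end());
  q.p_kind.assign(pk.begin(), pk.end());
  q.p_t0.assign(pt0.begin(), pt0.end());
  q.p_ax.assign(pax.begin(), pax.end());
  q.p_ay.assign(pay.begin(), pay.end());
  q.p_az.assign(paz.begin(), paz.end());
  q.next_id = s["next_id"]; q.next_pair = s["next_pair"];
  return q;
}

static List write_state(const State& q) {
  int n = q.n();
  NumericMatrix pos(n, 3);
  for (int i = 0; i < n; ++i) { pos(i,0)=q.x[i]; pos(i,1)=q.y[i]; pos(i,2)=q.z[i]; }
  int ne = (int)q.events.size() / 12;
  NumericMatrix ev(ne, 12);
  for (int r = 0; r < ne; ++r)
    for (int c = 0; c < 12; ++c) ev(r, c) = q.events[r * 12 + c];
  return List::create(
      _["time"] = q.time, _["Lx"] = q.Lx, _["Ly"] = q.Ly,
      _["id"] = wrap(q.id), _["pos"] = pos, _["kind"] = wrap(q.kind),
      _["cycle"] = wrap(q.cycle), _["S"] = wrap(q.S),
      _["calcium"] = wrap(q.ca), _["birth"] = wrap(q.birth),
      _["pair"] = wrap(q.pair),
      _["p_id"] = wrap(q.p_id), _["p_c1"] = wrap(q.p_c1),
      _["p_c2"] = wrap(q.p_c2), _["p_t0"] = wrap(q.p_t0),
      _["p_ax"] = wrap(q.p_ax), _["p_ay"] = wrap(q.p_ay),
      _["p_az"] = wrap(q.p_az), _["p_kind"] = wrap(q.p_kind),
      _["next_id"] = q.next_id, _["next_pair"] = q.next_pair,
      _["events"] = ev);
}

// minimal-image for differences of coordinates already wrapped into [0, L)
static inline double wrapd(double d, double L) {
  if (d > 0.5 * L) return d - L;
  if (d < -0.5 * L) return d + L;
  return d;
}

// wrap a coordinate back into [0, L) after a bounded move
static inline double wrapc(double x, double L) {
  if (x >= L) return x - L;
  if (x < 0) return x + L;
  return x;
}

// deterministic unit vector from two ids (degenerate-overlap separation)
static inline void hash_dir(int a, int b, double* v) {
  uint32_t h = (uint32_t)a * 2654435761u ^ ((uint32_t)b * 97u + 17u);
  h ^= h >> 13; h *= 0x5bd1e995u; h ^= h >> 15;
  double u1 = (h & 0xffffu) / 65536.0;
  double u2 = ((h >> 16) & 0xffffu) / 65536.0;
  double zz = 2.0 * u1 - 1.0, ph = 2.0 * M_PI * u2;
  double s = std::sqrt(std::max(0.0, 1.0 - zz * zz));
  v[0] = s * std::cos(ph); v[1] = s * std::sin(ph); v[2] = zz;
}

// ---------------------------------------------------------------------------
// pair potential and its radial derivative
// default (ccf == 1, repulsive form): V = eps(0.5 s^12 - s^6) + eps/2, r <= d
// ccf > 1: unshifted form truncated at rc = ccf*d (small jump, documented)
// printed form: the sign-inverted original, kept for comparison only
static inline double lj_V(double r, double d, const Par& p) {
  double rc = p.ccf * d;
  if (r > rc) return 0.0;
  double s2 = (d / r) * (d / r);
  double s6 = s2 * s2 * s2, s12 = s6 * s6;
  double V = p.lj_printed ? p.eps * (s6 - 0.5 * s12)
                          : p.eps * (0.5 * s12 - s6);
  if (!p.lj_printed && p.ccf == 1.0) V += 0.5 * p.eps;
  return V;
}

// returns dV/dr (force on i along (xi-xj)/r is -dV/dr)
static inline double lj_dV(double r, double d, const Par& p) {
  double rc = p.ccf * d;
  if (r > rc) return 0.0;
  double s2 = (d / r) * (d / r);
  double s6 = s2 * s2 * s2, s12 = s6 * s6;
  double dv = (6.0 * p.eps / r) * (s6 - 2.0 * 0.5 * s12);  // d/dr eps(s12/2 - s6)
  return p.lj_printed ? -dv : dv;
}

// anchoring potentials: u = r - (R+Rm)
static inline double anchor_V(int kind, double r, const Par& p) {
  double u = r - (p.R + p.Rm);
  if (kind == K_STEM) return 0.5 * p.Ks * u * u;
  if (kind == K_DAUGHTER) {
    if (r > p.rstar()) return 0.0;
    return 0.5 * p.Kd * (p.a * u * u - 0.5 * p.b * u * u * u * u);
  }
  return 0.0;
}

static inline double anchor_dV(int kind, double r, const Par& p) {
  double u = r - (p.R + p.Rm);
  if (kind == K_STEM) return p.Ks * u;
  if (kind == K_DAUGHTER) {
    if (r > p.rstar()) return 0.0;
    return p.Kd * u * (p.a - p.b * u * u);
  }
  return 0.0;
}

// ---------------------------------------------------------------------------
// uniform grid over the periodic box (open z) for neighbor search;
// buffers are reused across rebuilds
struct Grid {
  int nx, ny, nz;
  double bx, by, bz, zmin, Lx, Ly, cut;
  std::vector<int> head, nxt, cix, ciy, ciz;
  std::vector<int> bstart, border;  // CSR: cells sorted by bin

  void build(const State& st, double cutoff) {
    cut = cutoff; Lx = st.Lx; Ly = st.Ly;
    int n = st.n();
    nx = std::max(1, (int)std::floor(Lx / cut));
    ny = std::max(1, (int)std::floor(Ly / cut));
    bx = Lx / nx; by = Ly / ny;
    double zlo = 0, zhi = 1;
    if (n > 0) {
      zlo = zhi = st.z[0];
      for (int i = 1; i < n; ++i) {
        if (st.z[i] < zlo) zlo = st.z[i];
        if (st.z[i] > zhi) zhi = st.z[i];
      }
    }
    zmin = zlo - 1e-9;
    double span = std::max(zhi - zmin, cut);
    nz = std::max(1, (int)std::floor(span / cut));
    bz = span / nz + 1e-12;
    int nb = nx * ny * nz;
    head.assign(nb, -1);
    nxt.assign(n, -1);
    cix.resize(n); ciy.resize(n); ciz.resize(n);
    for (int i = 0; i < n; ++i) {
      // state coordinates are maintained in [0, L)
      cix[i] = std::min(nx - 1, std::max(0, (int)(st.x[i] / bx)));
      ciy[i] = std::min(ny - 1, std::max(0, (int)(st.y[i] / by)));
      ciz[i] = std::min(nz - 1, std::max(0, (int)((st.z[i] - zmin) / bz)));
      int b = cix[i] + nx * (ciy[i] + ny * ciz[i]);
      nxt[i] = head[b]; head[b] = i;
    }
    // CSR layout for the pair sweep
    bstart.assign(nb + 1, 0);
    for (int i = 0; i < n; ++i)
      ++bstart[cix[i] + nx * (ciy[i] + ny * ciz[i]) + 1];
    for (int b = 0; b < nb; ++b) bstart[b + 1] += bstart[b];
    border.resize(n);
    std::vector<int> fill(bstart.begin(), bstart.end() - 1);
    for (int i = 0; i < n; ++i) {
      int b = cix[i] + nx * (ciy[i] + ny * ciz[i]);
      border[fill[b]++] = i;
    }
  }

  // visit every unordered cell pair within the cutoff shell exactly once:
  // f(i, j, dx, dy, dz, r2) with dx = xi - xj (minimal image)
  template <typename F>
  void for_pairs(const State& st, F f) const {
    if (nx >= 3 && ny >= 3) {
      // half stencil with precomputed periodic shifts
      static const int HALF[14][3] = {
          {0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
          {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},
          {-1,1,1},{0,1,1},{1,1,1}};
      for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy)
          for (int ix = 0; ix < nx; ++ix) {
            int b = ix + nx * (iy + ny * iz);
            int i0 = bstart[b], i1 = bstart[b + 1];
            if (i0 == i1) continue;
            for (int q = 0; q < 14; ++q) {
              int jz = iz + HALF[q][2];
              if (jz >= nz) continue;
              int jxr = ix + HALF[q][0], jyr = iy + HALF[q][1];
              double shx = 0, shy = 0;
              int jx = jxr, jy = jyr;
              if (jxr < 0) { jx += nx; shx = -Lx; }
              else if (jxr >= nx) { jx -= nx; shx = Lx; }
              if (jyr < 0) { jy += ny; shy = -Ly; }
              else if (jyr >= ny) { jy -= ny; shy = Ly; }
              int b2 = jx + nx * (jy + ny * jz);
              int j0 = bstart[b2], j1 = bstart[b2 + 1];
              bool same = (q == 0);
              for (int qi = i0; qi < i1; ++qi) {
                int i = border[qi];
                double xi = st.x[i], yi = st.y[i], zi = st.z[i];
                for (int qj = same ? qi + 1 : j0; qj < j1; ++qj) {
                  int j = border[qj];
                  double dx = xi - (st.x[j] + shx);
                  double dy = yi - (st.y[j] + shy);
                  double dz = zi - st.z[j];
                  double r2 = dx * dx + dy * dy + dz * dz;
                  if (r2 <= cut * cut) f(i, j, dx, dy, dz, r2);
                }
              }
            }
          }
    } else {
      // tiny boxes: full stencil with per-center dedup, pairs gated by j > i
      int n = st.n();
      for (int i = 0; i < n; ++i) {
        for_nbrs(cix[i], ciy[i], ciz[i], [&](int b) {
          for (int j = head[b]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;
            double dx = wrapd(st.x[i] - st.x[j], Lx);
            double dy = wrapd(st.y[i] - st.y[j], Ly);
            double dz = st.z[i] - st.z[j];
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 <= cut * cut) f(i, j, dx, dy, dz, r2);
          }
        });
      }
    }
  }

  // visit the (deduplicated) neighbor bins of grid cell (ix, iy, iz)
  template <typename F>
  void for_nbrs(int ix, int iy, int iz, F f) const {
    bool dedup = nx < 3 || ny < 3;
    int seen[27]; int ns = 0;
    for (int dz = -1; dz <= 1; ++dz) {
      int jz = iz + dz;
      if (jz < 0 || jz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int jy = iy + dy;
        jy = jy < 0 ? jy + ny : (jy >= ny ? jy - ny : jy);
        for (int dx = -1; dx <= 1; ++dx) {
          int jx = ix + dx;
          jx = jx < 0 ? jx + nx : (jx >= nx ? jx - nx : jx);
          int b = jx + nx * (jy + ny * jz);
          if (dedup) {
            bool s = false;
            for (int q = 0; q < ns; ++q) if (seen[q] == b) { s = true; break; }
            if (s) continue;
            seen[ns++] = b;
          }
          f(b);
        }
      }
    }
  }
};

// nearest membrane particle (expanding-window grid lookup, lowest-id ties)
static void nearest_mem(double px, double py, double pz, const Mem& m,
                        int* best_id, double* best_d) {
  // the membrane grid's first particle anchors the lateral index origin
  int i0 = (int)std::floor((px - m.pos(0, 0)) / m.sx + 0.5);
  int j0 = (int)std::floor((py - m.pos(0, 1)) / m.sy + 0.5);
  double smin = std::min(m.sx, m.sy);
  int wmax = std::max(m.nx, m.ny);  // full membrane fallback
  int bid = -1;
  double bd2 = R_PosInf;
  for (int w = 2; w <= wmax; w += 2) {
    for (int dj = -w; dj <= w; ++dj) {
      int jy = ((j0 + dj) % m.ny + m.ny) % m.ny;
      for (int di = -w; di <= w; ++di) {
        int jx = ((i0 + di) % m.nx + m.nx) % m.nx;
        int idx = jy * m.nx + jx;  // 0-based; R id = idx + 1
        double dx = wrapd(px - m.pos(idx, 0), m.Lx);
        double dy = wrapd(py - m.pos(idx, 1), m.Ly);
        double dz = pz - m.pos(idx, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < bd2 || (d2 == bd2 && idx < bid)) { bd2 = d2; bid = idx; }
      }
    }
    double excl = (w + 0.5) * smin;  // lower bound on excluded lateral dist
    if (bd2 <= excl * excl || 2 * w + 1 >= wmax) break;
  }
  *best_id = bid + 1;
  *best_d = std::sqrt(bd2);
}

// ---------------------------------------------------------------------------
// forces on all cells; optionally also nearest-membrane info
static void compute_forces(const State& st, const Mem& m, const Par& p,
                           std::vector<double>& fx, std::vector<double>& fy,
                           std::vector<double>& fz, std::vector<int>* nm_id,
                           std::vector<double>* nm_d) {
  int n = st.n();
  fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0);
  double dcc = 2.0 * p.R, cut = p.ccf * dcc;
  static Grid g;
  g.build(st, cut);
  // cell-cell pass (each unordered pair once)
  g.for_pairs(st, [&](int i, int j, double dx, double dy, double dz,
                      double r2) {
    if (st.pair[i] != 0 && st.pair[i] == st.pair[j]) return;  // dumbbell
    double r = std::sqrt(r2);
    if (r < 1e-6) {  // degenerate overlap: deterministic tiny separation
      double v[3]; hash_dir(st.id[i], st.id[j], v);
      dx = 1e-6 * v[0]; dy = 1e-6 * v[1]; dz = 1e-6 * v[2];
      r = 1e-6;
    }
    double coef = -lj_dV(r, dcc, p) / r;
    fx[i] += coef * dx; fy[i] += coef * dy; fz[i] += coef * dz;
    fx[j] -= coef * dx; fy[j] -= coef * dy; fz[j] -= coef * dz;
  });
  // membrane pass: repulsion from the nearest particle + kind anchor
  double dcm = p.R + p.Rm, cutm = p.ccf * dcm;
  if (nm_id) nm_id->assign(n, 0);
  if (nm_d) nm_d->assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    // suprabasal/cornified cells far above the membrane have no membrane
    // interaction (Vm = 0 and out of contact); skip the lookup unless the
    // caller asked for nearest-membrane info
    if (!nm_id && !nm_d &&
        (st.kind[i] == K_SUPRA || st.kind[i] == K_CORN) &&
        st.z[i] - m.zmax > cutm)
      continue;
    int bid; double r;
    nearest_mem(st.x[i], st.y[i], st.z[i], m, &bid, &r);
    if (nm_id) (*nm_id)[i] = bid;
    if (nm_d) (*nm_d)[i] = r;
    double dx = wrapd(st.x[i] - m.pos(bid - 1, 0), st.Lx);
    double dy = wrapd(st.y[i] - m.pos(bid - 1, 1), st.Ly);
    double dz = st.z[i] - m.pos(bid - 1, 2);
    if (r < 1e-12) continue;  // pathological exact overlap with membrane
    double dv = 0.0;
    if (r <= cutm) dv += lj_dV(r, dcm, p);
    dv += anchor_dV(st.kind[i], r, p);
    double coef = -dv / r;
    fx[i] += coef * dx; fy[i] += coef * dy; fz[i] += coef * dz;
  }
  // division dumbbells
  for (size_t q = 0; q < st.p_id.size(); ++q) {
    int i = st.index_of(st.p_c1[q]), j = st.index_of(st.p_c2[q]);
    if (i < 0 || j < 0) continue;
    double l = p.alpha * (st.time - st.p_t0[q]);
    if (l > 2.0 * p.R) l = 2.0 * p.R;
    double dx = wrapd(st.x[i] - st.x[j], st.Lx);
    double dy = wrapd(st.y[i] - st.y[j], st.Ly);
    double dz = st.z[i] - st.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ex, ey, ez;
    if (r > 1e-12) { ex = dx / r; ey = dy / r; ez = dz / r; }
    else { ex = st.p_ax[q]; ey = st.p_ay[q]; ez = st.p_az[q]; }
    double f = -p.Kprime * (r - l);  // on c1 along e
    fx[i] += f * ex; fy[i] += f * ey; fz[i] += f * ez;
    fx[j] -= f * ex; fy[j] -= f * ey; fz[j] -= f * ez;
  }
}

static double compute_potential(const State& st, const Mem& m, const Par& p) {
  int n = st.n();
  double V = 0.0;
  double dcc = 2.0 * p.R, cut = p.ccf * dcc;
  static Grid g;
  g.build(st, cut);
  g.for_pairs(st, [&](int i, int j, double dx, double dy, double dz,
                      double r2) {
    if (st.pair[i] != 0 && st.pair[i] == st.pair[j]) return;
    V += lj_V(std::max(std::sqrt(r2), 1e-6), dcc, p);
  });
  double dcm = p.R + p.Rm, cutm = p.ccf * dcm;
  for (int i = 0; i < n; ++i) {
    if ((st.kind[i] == K_SUPRA || st.kind[i] == K_CORN) &&
        st.z[i] - m.zmax > cutm)
      continue;
    int bid; double r;
    nearest_mem(st.x[i], st.y[i], st.z[i], m, &bid, &r);
    if (r <= cutm) V += lj_V(std::max(r, 1e-6), dcm, p);
    V += anchor_V(st.kind[i], r, p);
  }
  for (size_t q = 0; q < st.p_id.size(); ++q) {
    int i = st.index_of(st.p_c1[q]), j = st.index_of(st.p_c2[q]);
    if (i < 0 || j < 0) continue;
    double l = p.alpha * (st.time - st.p_t0[q]);
    if (l > 2.0 * p.R) l = 2.0 * p.R;
    double dx = wrapd(st.x[i] - st.x[j], st.Lx);
    double dy = wrapd(st.y[i] - st.y[j], st.Ly);
    double dz = st.z[i] - st.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    V += 0.5 * p.Kprime * (r - l) * (r - l);
  }
  return V;
}

// per-suprabasal contact with cornified cells (current positions),
// using a grid already built at the contact cutoff
static void contact_cornified_g(const State& st, const Par& p, const Grid& g,
                                std::vector<char>& touch) {
  int n = st.n();
  touch.assign(n, 0);
  double cut = p.ccf * 2.0 * p.R, cut2 = cut * cut;
  for (int i = 0; i < n; ++i) {
    if (st.kind[i] != K_SUPRA) continue;
    bool hit = false;
    g.for_nbrs(g.cix[i], g.ciy[i], g.ciz[i], [&](int b) {
      for (int j = g.head[b]; j >= 0 && !hit; j = g.nxt[j]) {
        if (j == i || st.kind[j] != K_CORN) continue;
        double dx = wrapd(st.x[i] - st.x[j], st.Lx);
        double dy = wrapd(st.y[i] - st.y[j], st.Ly);
        double dz = st.z[i] - st.z[j];
        if (dx * dx + dy * dy + dz * dz <= cut2) hit = true;
      }
    });
    touch[i] = hit ? 1 : 0;
  }
}

static void contact_cornified(const State& st, const Par& p,
                              std::vector<char>& touch) {
  static Grid g;
  g.build(st, p.ccf * 2.0 * p.R);
  contact_cornified_g(st, p, g, touch);
}

// exposed cornified cells: no other cell strictly higher within lateral
// contact range
static void exposed_cornified_g(const State& st, const Par& p, const Grid& g,
                                std::vector<char>& exp_) {
  int n = st.n();
  exp_.assign(n, 0);
  double cut = p.ccf * 2.0 * p.R, cut2 = cut * cut;
  for (int i = 0; i < n; ++i) {
    if (st.kind[i] != K_CORN || st.pair[i] != 0) continue;
    bool covered = false;
    // scan the 9 lateral bin columns from this cell's z-bin upward
    int ix = g.cix[i], iy = g.ciy[i], iz = g.ciz[i];
    for (int dyb = -1; dyb <= 1 && !covered; ++dyb) {
      int jy = ((iy + dyb) % g.ny + g.ny) % g.ny;
      if (dyb == 1 && g.ny <= 2) continue;  // wrapped duplicate column
      for (int dxb = -1; dxb <= 1 && !covered; ++dxb) {
        int jx = ((ix + dxb) % g.nx + g.nx) % g.nx;
        if (dxb == 1 && g.nx <= 2) continue;
        for (int jz = iz; jz < g.nz && !covered; ++jz) {
          int b = jx + g.nx * (jy + g.ny * jz);
          for (int j = g.head[b]; j >= 0; j = g.nxt[j]) {
            if (j == i || st.z[j] <= st.z[i]) continue;
            double dx = wrapd(st.x[i] - st.x[j], st.Lx);
            double dy = wrapd(st.y[i] - st.y[j], st.Ly);
            if (dx * dx + dy * dy <= cut2) { covered = true; break; }
          }
        }
      }
    }
    exp_[i] = covered ? 0 : 1;
  }
}

static void exposed_cornified(const State& st, const Par& p,
                              std::vector<char>& exp_) {
  static Grid g;
  g.build(st, p.ccf * 2.0 * p.R);
  exposed_cornified_g(st, p, g, exp_);
}

static void compact(State& st, const std::vector<char>& alive) {
  int n = st.n(), k = 0;
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    st.id[k] = st.id[i]; st.kind[k] = st.kind[i]; st.pair[k] = st.pair[i];
    st.x[k] = st.x[i]; st.y[k] = st.y[i]; st.z[k] = st.z[i];
    st.cycle[k] = st.cycle[i]; st.S[k] = st.S[i]; st.ca[k] = st.ca[i];
    st.birth[k] = st.birth[i];
    ++k;
  }
  st.id.resize(k); st.kind.resize(k); st.pair.resize(k);
  st.x.resize(k); st.y.resize(k); st.z.resize(k);
  st.cycle.resize(k); st.S.resize(k); st.ca.resize(k); st.birth.resize(k);
}

static double thickness_of(const State& st, const Mem& m, const Par& p,
                           double pitch, std::vector<double>* cols = nullptr) {
  int ncx = std::max(1, (int)std::floor(st.Lx / pitch + 0.5));
  int ncy = std::max(1, (int)std::floor(st.Ly / pitch + 0.5));
  double px = st.Lx / ncx, py = st.Ly / ncy;
  int nc = ncx * ncy;
  std::vector<double> top(nc, R_NegInf), msum(nc, 0.0);
  std::vector<int> mcnt(nc, 0);
  for (int i = 0; i < st.n(); ++i) {
    double mx = st.x[i] - st.Lx * std::floor(st.x[i] / st.Lx);
    double my = st.y[i] - st.Ly * std::floor(st.y[i] / st.Ly);
    int c = std::min(ncx - 1, (int)(mx / px)) +
            ncx * std::min(ncy - 1, (int)(my / py));
    double t = st.z[i] + p.R;
    if (t > top[c]) top[c] = t;
  }
  double mall = 0.0;
  for (int i = 0; i < m.pos.nrow(); ++i) {
    double mx = m.pos(i, 0) - st.Lx * std::floor(m.pos(i, 0) / st.Lx);
    double my = m.pos(i, 1) - st.Ly * std::floor(m.pos(i, 1) / st.Ly);
    int c = std::min(ncx - 1, (int)(mx / px)) +
            ncx * std::min(ncy - 1, (int)(my / py));
    msum[c] += m.pos(i, 2) + m.Rm;
    mcnt[c] += 1;
    mall += m.pos(i, 2) + m.Rm;
  }
  mall /= std::max(1, (int)m.pos.nrow());
  double acc = 0.0; int used = 0;
  if (cols) cols->assign(nc, NA_REAL);
  for (int c = 0; c < nc; ++c) {
    if (!R_finite(top[c])) continue;
    double surf = mcnt[c] > 0 ? msum[c] / mcnt[c] : mall;
    double th = top[c] - surf;
    if (cols) (*cols)[c] = th;
    acc += th; ++used;
  }
  if (used == 0) return NA_REAL;
  return acc / used;
}

// ---------------------------------------------------------------------------
// one full update step; stages selectable. RNG draw order (documented):
// division-start uniforms for eligible cells in ascending id order, then two
// axis uniforms per division in ascending id order, then one uniform per
// exposed cornified cell in ascending id order.
static void do_step(State& st, const Mem& m, const Par& p, int stages) {
  int n;
  if (stages & ST_MECH) {
    std::vector<double> fx, fy, fz;
    compute_forces(st, m, p, fx, fy, fz, nullptr, nullptr);
    n = st.n();
    double sc = p.dt / p.mu;
    for (int i = 0; i < n; ++i) {
      double ddx = sc * fx[i], ddy = sc * fy[i], ddz = sc * fz[i];
      double dn = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (dn > p.max_disp) {
        double f = p.max_disp / dn;
        ddx *= f; ddy *= f; ddz *= f;
      }
      st.x[i] += ddx; st.y[i] += ddy; st.z[i] += ddz;
      if (!R_finite(st.x[i]) || !R_finite(st.y[i]) || !R_finite(st.z[i]))
        stop("integration blow-up at cell id %d (t = %g, dt = %g): "
             "non-finite coordinate; reduce dt", st.id[i], st.time, p.dt);
      st.x[i] = wrapc(st.x[i], st.Lx);
      st.y[i] = wrapc(st.y[i], st.Ly);
    }
  }
  st.time += p.dt;

  if (stages & ST_PAIRS) {
    size_t kept = 0;
    for (size_t q = 0; q < st.p_id.size(); ++q) {
      double l = p.alpha * (st.time - st.p_t0[q]);
      if (l < 2.0 * p.R) {
        st.p_id[kept] = st.p_id[q]; st.p_c1[kept] = st.p_c1[q];
        st.p_c2[kept] = st.p_c2[q]; st.p_t0[kept] = st.p_t0[q];
        st.p_ax[kept] = st.p_ax[q]; st.p_ay[kept] = st.p_ay[q];
        st.p_az[kept] = st.p_az[q]; st.p_kind[kept] = st.p_kind[q];
        ++kept;
        continue;
      }
      int i = st.index_of(st.p_c1[q]), j = st.index_of(st.p_c2[q]);
      double ax = st.p_ax[q], ay = st.p_ay[q], az = st.p_az[q];
      double mx = 0, my = 0, mz = 0;
      if (i >= 0 && j >= 0) {
        double dx = wrapd(st.x[i] - st.x[j], st.Lx);
        double dy = wrapd(st.y[i] - st.y[j], st.Ly);
        double dz = st.z[i] - st.z[j];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r > 1e-12) { ax = dx / r; ay = dy / r; az = dz / r; }
        mx = st.x[j] + dx / 2; my = st.y[j] + dy / 2; mz = st.z[j] + dz / 2;
        st.pair[i] = 0; st.pair[j] = 0;
      }
      st.push_event(EV_DIV_COMPLETE, st.time, st.p_c1[q], st.p_c2[q], 0,
                    st.p_kind[q], mx, my, mz, ax, ay, az);
    }
    st.p_id.resize(kept); st.p_c1.resize(kept); st.p_c2.resize(kept);
    st.p_t0.resize(kept); st.p_ax.resize(kept); st.p_ay.resize(kept);
    st.p_az.resize(kept); st.p_kind.resize(kept);
  }

  if (stages & ST_CYCLE) {
    n = st.n();
    for (int i = 0; i < n; ++i)
      if (st.kind[i] == K_STEM || st.kind[i] == K_DAUGHTER)
        st.cycle[i] += p.dt;
  }

  if (stages & ST_DIV) {
    n = st.n();
    double pdiv = 1.0 - std::exp(-p.gamma * p.dt);
    std::vector<int> starters;
    for (int i = 0; i < n; ++i) {
      bool elig = (st.kind[i] == K_STEM || st.kind[i] == K_DAUGHTER) &&
                  st.pair[i] == 0 && st.cycle[i] >= p.T_cycle;
      if (!elig) continue;
      if (unif_rand() < pdiv) starters.push_back(i);
    }
    if (!starters.empty()) {
      std::vector<char> alive(n, 1);
      for (int i0 : starters) {
        // initial push axis: in-plane by default (newborns stay in the basal
        // layer; crowding rotates pairs out of plane), isotropic optionally
        double ax, ay, az;
        if (p.axis_in_plane) {
          double ph = 2.0 * M_PI * unif_rand();
          ax = std::cos(ph); ay = std::sin(ph); az = 0.0;
        } else {
          double u1 = unif_rand(), u2 = unif_rand();
          double zz = 2.0 * u1 - 1.0, ph = 2.0 * M_PI * u2;
          double sq = std::sqrt(std::max(0.0, 1.0 - zz * zz));
          ax = sq * std::cos(ph); ay = sq * std::sin(ph); az = zz;
        }
        int pid = st.next_pair++;
        int c1 = st.next_id++, c2 = st.next_id++;
        int pk = st.kind[i0];
        st.push_event(EV_DIV_START, st.time, st.id[i0], c1, c2, pk,
                      st.x[i0], st.y[i0], st.z[i0], st.birth[i0], 0, 0);
        // children at the parent's exact position; asymmetric stem fate
        for (int c = 0; c < 2; ++c) {
          st.id.push_back(c == 0 ? c1 : c2);
          st.kind.push_back(pk == K_STEM ? (c == 0 ? K_STEM : K_DAUGHTER)
                                         : K_DAUGHTER);
          st.pair.push_back(pid);
          st.x.push_back(st.x[i0]); st.y.push_back(st.y[i0]);
          st.z.push_back(st.z[i0]);
          st.cycle.push_back(0.0); st.S.push_back(0.0);
          st.ca.push_back(0.0); st.birth.push_back(st.time);
        }
        alive.push_back(1); alive.push_back(1);
        alive[i0] = 0;
        st.p_id.push_back(pid); st.p_c1.push_back(c1); st.p_c2.push_back(c2);
        st.p_t0.push_back(st.time); st.p_ax.push_back(ax);
        st.p_ay.push_back(ay); st.p_az.push_back(az);
        st.p_kind.push_back(pk);
      }
      compact(st, alive);
    }
  }

  if (stages & ST_ATTACH) {
    // irreversible: a progenitor carried past r* leaves the basal layer for
    // good and starts differentiating from S = 0
    n = st.n();
    double rs = p.rstar();
    for (int i = 0; i < n; ++i) {
      if (st.kind[i] != K_DAUGHTER) continue;
      int bid; double r;
      nearest_mem(st.x[i], st.y[i], st.z[i], m, &bid, &r);
      if (r > rs) {
        st.kind[i] = K_SUPRA;
        st.S[i] = 0.0; st.ca[i] = 0.0; st.cycle[i] = 0.0;
        st.push_event(EV_DETACH, st.time, st.id[i], 0, 0, K_DAUGHTER,
                      st.x[i], st.y[i], st.z[i], st.birth[i], 0, 0);
      }
    }
  }

  // calcium and desquamation share one neighbor grid at post-move positions
  // (cell arrays are structurally stable from here to the end of the step)
  static Grid gpost;
  if (stages & (ST_CALCIUM | ST_DESQ)) gpost.build(st, p.ccf * 2.0 * p.R);

  if (stages & ST_CALCIUM) {
    n = st.n();
    std::vector<char> touch;
    contact_cornified_g(st, p, gpost, touch);
    double decay = std::exp(-p.k_ca * p.dt);
    for (int i = 0; i < n; ++i) {
      if (st.kind[i] == K_SUPRA)
        st.ca[i] = touch[i] ? p.c_exc : st.ca[i] * decay;
      else
        st.ca[i] = 0.0;
    }
  }

  if (stages & ST_DIFF) {
    n = st.n();
    for (int i = 0; i < n; ++i)
      if (st.kind[i] == K_SUPRA)
        st.S[i] += p.dt * p.s_base * (1.0 + p.lam_ca * st.ca[i]);
  }

  if (stages & ST_CORNIFY) {
    n = st.n();
    for (int i = 0; i < n; ++i) {
      if (st.kind[i] == K_SUPRA && st.S[i] >= p.S_star) {
        st.kind[i] = K_CORN;
        st.ca[i] = 0.0;
        st.push_event(EV_CORNIFY, st.time, st.id[i], 0, 0, K_CORN,
                      st.x[i], st.y[i], st.z[i], st.birth[i], 0, 0);
      }
    }
  }

  if (stages & ST_DESQ) {
    n = st.n();
    std::vector<char> exp_;
    exposed_cornified_g(st, p, gpost, exp_);
    double pdes = 1.0 - std::exp(-p.desq_rate * p.dt);
    std::vector<char> alive(n, 1);
    bool any = false;
    for (int i = 0; i < n; ++i) {
      if (!exp_[i]) continue;
      if (unif_rand() < pdes) {
        alive[i] = 0; any = true;
        st.push_event(EV_DESQ, st.time, st.id[i], 0, 0, K_CORN,
                      st.x[i], st.y[i], st.z[i], st.birth[i], 0, 0);
      }
    }
    if (any) compact(st, alive);
  }
}

// ---------------------------------------------------------------------------
// exported kernels

// [[Rcpp::export]]
List cpp_run(List state, List membrane, List params, int n_steps,
             int record_every = 0, int stages = 511,
             double record_pitch = 2.8) {
  State st = read_state(state);
  Mem m = read_mem(membrane);
  Par p = read_par(params);
  std::vector<double> rec;
  auto record = [&]() {
    double th = thickness_of(st, m, p, record_pitch);
    double cnt[4] = {0, 0, 0, 0};
    for (int i = 0; i < st.n(); ++i) cnt[st.kind[i] - 1] += 1;
    double row[6] = {st.time, th, cnt[0], cnt[1], cnt[2], cnt[3]};
    rec.insert(rec.end(), row, row + 6);
  };
  if (record_every > 0) record();
  for (int s = 1; s <= n_steps; ++s) {
    do_step(st, m, p, stages);
    if (record_every > 0 && s % record_every == 0) record();
  }
  List out = write_state(st);
  int nr = (int)rec.size() / 6;
  NumericMatrix rm(nr, 6);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < 6; ++c) rm(r, c) = rec[r * 6 + c];
  colnames(rm) = CharacterVector::create("time", "thickness", "n_stem",
                                         "n_daughter", "n_suprabasal",
                                         "n_cornified");
  out["record"] = rm;
  return out;
}

// [[Rcpp::export(rng = false)]]
List cpp_forces(List state, List membrane, List params) {
  State st = read_state(state);
  Mem m = read_mem(membrane);
  Par p = read_par(params);
  std::vector<double> fx, fy, fz;
  std::vector<int> nid;
  std::vector<double> nd;
  compute_forces(st, m, p, fx, fy, fz, &nid, &nd);
  int n = st.n();
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i,0)=fx[i]; F(i,1)=fy[i]; F(i,2)=fz[i]; }
  return List::create(_["F"] = F, _["nearest_id"] = wrap(nid),
                      _["nearest_dist"] = wrap(nd));
}

// [[Rcpp::export(rng = false)]]
double cpp_potential(List state, List membrane, List params) {
  State st = read_state(state);
  Mem m = read_mem(membrane);
  Par p = read_par(params);
  return compute_potential(st, m, p);
}

// [[Rcpp::export(rng = false)]]
LogicalVector cpp_contact_cornified(List state, List params) {
  State st = read_state(state);
  Par p = read_par(params);
  std::vector<char> touch;
  contact_cornified(st, p, touch);
  LogicalVector out(st.n());
  for (int i = 0; i < st.n(); ++i) out[i] = touch[i] != 0;
  return out;
}

// [[Rcpp::export(rng = false)]]
LogicalVector cpp_exposed(List state, List params) {
  State st = read_state(state);
  Par p = read_par(params);
  std::vector<char> e;
  exposed_cornified(st, p, e);
  LogicalVector out(st.n());
  for (int i = 0; i < st.n(); ++i) out[i] = e[i] != 0;
  return out;
}

// [[Rcpp::export(rng = false)]]
List cpp_nearest_membrane(NumericMatrix points, NumericMatrix mpos,
                          double Lx, double Ly, int nx, int ny, double sx,
                          double sy) {
  Mem m; m.pos = mpos; m.Lx = Lx; m.Ly = Ly; m.nx = nx; m.ny = ny;
  m.sx = sx; m.sy = sy; m.Rm = 1.0;
  int n = points.nrow();
  IntegerVector id(n);
  NumericVector d(n);
  for (int i = 0; i < n; ++i) {
    int bid; double bd;
    nearest_mem(points(i, 0), points(i, 1), points(i, 2), m, &bid, &bd);
    id[i] = bid; d[i] = bd;
  }
  return List::create(_["id"] = id, _["dist"] = d);
}

// [[Rcpp::export(rng = false)]]
List cpp_thickness(List state, List membrane, List params, double pitch) {
  State st = read_state(state);
  Mem m = read_mem(membrane);
  Par p = read_par(params);
  std::vector<double> cols;
  double mean = thickness_of(st, m, p, pitch, &cols);
  return List::create(_["mean"] = mean, _["columns"] = wrap(cols));
}
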