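// Simulation engine: Langevin dynamics of monomers (3D) and wall (1D),
// Poisson-clocked single-monomer (de)polymerization at filament tips and
// grand-canonical monomer exchange, with per-step observable accumulation.
//
// Units are reduced throughout: monomer size d, thermal energy kBT and wall
// diffusion time tauD equal 1 at the default parameters.  The wall confines
// x; y and z are periodic with box edge Lprime = sqrt(A).  Filament
// monomer coordinates are kept unwrapped transversely so that bond and
// bend terms never need minimum-image corrections; free monomers are
// wrapped into [0, Lprime).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include "rng.h"

using namespace Rcpp;

static const double SQRT3 = 1.7320508075688772;
static const double C93 = 2.598076211353316;  // 3*sqrt(3)/2, 9-3 wall prefactor

// m-index counter layout: m ranges over [-MOFF, MSZ - MOFF - 1]
static const int MOFF = 4096;
static const int MSZ = 4352;

struct Params {
  double d, kBT, beta, M, Mw, zeta, zetaw, ks, kap, eps0, epsw, sc, kT, A;
  double nu, nuGC, h, rc, rho1;
  int Nf;
};

static Params read_params(const List &p) {
  Params q;
  q.d = as<double>(p["d"]);
  q.kBT = as<double>(p["kBT"]);
  q.beta = (q.kBT > 0) ? 1.0 / q.kBT : std::numeric_limits<double>::infinity();
  q.M = as<double>(p["M"]);
  q.Mw = as<double>(p["Mw"]);
  q.zeta = as<double>(p["zeta"]);
  q.zetaw = as<double>(p["zeta_w"]);
  q.ks = as<double>(p["ks"]);
  q.kap = as<double>(p["kappa_bend"]);
  q.eps0 = as<double>(p["eps0"]);
  q.epsw = as<double>(p["eps_w"]);
  q.sc = as<double>(p["s_c"]);
  q.kT = as<double>(p["kappa_T"]);
  q.A = as<double>(p["A"]);
  q.Nf = as<int>(p["Nf"]);
  q.nu = as<double>(p["nu"]);
  q.nuGC = as<double>(p["nu_GC"]);
  q.h = as<double>(p["h"]);
  q.rc = as<double>(p["r_c"]);
  q.rho1 = as<double>(p["rho1"]);
  return q;
}

struct Engine {
  Params P;
  double Lp2;  // Lprime = sqrt(A)
  // run-control flags
  bool mobile_wall, react_on, gc_on, include_pA, do_counters;
  int trace_stride, xhist_stride;
  double xhist_bin;
  int max_size;
  bool log_attempts;
  double pA;

  // particle arrays (slot-indexed)
  std::vector<double> x, y, z, vx, vy, vz;
  std::vector<int> nidx, kidx;           // 1-based filament id, rank; 0,0 = free
  std::vector<std::vector<int> > fil;    // slot ids per filament, rank order
  std::vector<double> hn, sy, sz;        // seed offsets / transverse anchors
  double L, Ldot, t;
  int n_free;

  // forces & energies (refreshed every step)
  std::vector<double> fx, fy, fz;
  double Fw_bun, Fw_m, U_bond, U_bend, U_wall;
  bool force_dirty;

  // event clocks: [2n] poly fil n, [2n+1] depol fil n, [2Nf] reservoir
  std::vector<double> clock;

  atrng::RngSet rng;

  // counters
  std::vector<double> q_m, u_att, u_succ, w_att, w_succ;
  double ins_att, ins_acc, del_att, del_acc, refuse_reactive;

  // event log (accepted events only)
  std::vector<double> ev_t, ev_dU;
  std::vector<int> ev_n, ev_dir, ev_m, ev_Nr, ev_acc;

  // trace buffers
  std::vector<double> tr_t, tr_L, tr_Ldot, tr_Ub, tr_Ubend, tr_Uw, tr_Fbun, tr_Fwm;
  std::vector<int> tr_N1;
  std::vector<std::vector<int> > tr_j;
  std::vector<std::vector<double> > tr_X, tr_R;

  // free-monomer x histogram (optional, fixed wall runs)
  std::vector<double> xhist;
  double xhist_samples;

  bool stop_flag;

  int n_slots() const { return static_cast<int>(x.size()); }
  bool is_seed(int i) const { return nidx[i] > 0 && kidx[i] <= 2; }
  bool is_mobile(int i) const { return !is_seed(i); }

  inline double fold(double dv) const {
    return dv - Lp2 * std::nearbyint(dv / Lp2);
  }
  inline double wrap(double v) const {
    double w = v - Lp2 * std::floor(v / Lp2);
    if (w >= Lp2) w -= Lp2;  // guard against rounding at the edge
    return w;
  }

  // ---- wall potential (purely repulsive 9-3, truncated at its minimum) ----
  inline double wallU(double s) const {
    if (s >= P.sc) return 0.0;
    if (s <= 0)
      stop("monomer crossed a wall (s = %g <= 0); the time step is too large "
           "or the configuration is invalid", s);
    double q = P.d / s;
    double q3 = q * q * q;
    return P.epsw * (C93 * (q3 * q3 * q3 - q3) + 1.0);
  }
  // dU/ds (negative inside the cutoff)
  inline double walldU(double s) const {
    if (s >= P.sc) return 0.0;
    if (s <= 0)
      stop("monomer crossed a wall (s = %g <= 0); the time step is too large "
           "or the configuration is invalid", s);
    double q = P.d / s;
    double q3 = q * q * q;
    return P.epsw * C93 * (-9.0 * q3 * q3 * q3 + 3.0 * q3) / s;
  }

  // ---- forces ----
  void compute_forces() {
    int N = n_slots();
    fx.assign(N, 0.0);
    fy.assign(N, 0.0);
    fz.assign(N, 0.0);
    U_bond = U_bend = U_wall = 0.0;
    Fw_bun = Fw_m = 0.0;

    for (int n = 0; n < P.Nf; ++n) {
      const std::vector<int> &f = fil[n];
      int j = static_cast<int>(f.size());
      // (j-2) harmonic bonds between ranks (k, k+1), k = 2..j-1 (1-based);
      // the seed bond (1,2) is rigid and carries no energy
      for (int a = 1; a + 1 < j; ++a) {
        int i1 = f[a], i2 = f[a + 1];
        double bx = x[i2] - x[i1], by = y[i2] - y[i1], bz = z[i2] - z[i1];
        double r = std::sqrt(bx * bx + by * by + bz * bz);
        U_bond += -P.eps0 + 0.5 * P.ks * (r - P.d) * (r - P.d);
        double fmag = -P.ks * (r - P.d) / r;  // along b acting on i2
        fx[i2] += fmag * bx; fy[i2] += fmag * by; fz[i2] += fmag * bz;
        fx[i1] -= fmag * bx; fy[i1] -= fmag * by; fz[i1] -= fmag * bz;
      }
      // (j-2) bending terms on triples (k, k+1, k+2), k = 1..j-2: the seed
      // pair anchors the filament orientation normal to the grafting wall
      for (int a = 0; a + 2 < j; ++a) {
        int i1 = f[a], i2 = f[a + 1], i3 = f[a + 2];
        double b1x = x[i2] - x[i1], b1y = y[i2] - y[i1], b1z = z[i2] - z[i1];
        double b2x = x[i3] - x[i2], b2y = y[i3] - y[i2], b2z = z[i3] - z[i2];
        double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
        double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
        double e1x = b1x / n1, e1y = b1y / n1, e1z = b1z / n1;
        double e2x = b2x / n2, e2y = b2y / n2, e2z = b2z / n2;
        double c = e1x * e2x + e1y * e2y + e1z * e2z;
        if (c > 1.0) c = 1.0;
        if (c < -1.0) c = -1.0;
        U_bend += P.kap * (1.0 - c);
        // F_i = kap * dc/dr_i
        double g1x = (c * e1x - e2x) / n1, g1y = (c * e1y - e2y) / n1,
               g1z = (c * e1z - e2z) / n1;
        double g3x = (e1x - c * e2x) / n2, g3y = (e1y - c * e2y) / n2,
               g3z = (e1z - c * e2z) / n2;
        fx[i1] += P.kap * g1x; fy[i1] += P.kap * g1y; fz[i1] += P.kap * g1z;
        fx[i3] += P.kap * g3x; fy[i3] += P.kap * g3y; fz[i3] += P.kap * g3z;
        fx[i2] -= P.kap * (g1x + g3x);
        fy[i2] -= P.kap * (g1y + g3y);
        fz[i2] -= P.kap * (g1z + g3z);
      }
    }

    // wall terms act on every mobile monomer (seeds are part of the
    // grafting wall and are excluded)
    for (int i = 0; i < N; ++i) {
      if (is_seed(i)) continue;
      double s1 = x[i];
      if (s1 < P.sc) {
        U_wall += wallU(s1);
        fx[i] += -walldU(s1);
      }
      double s2 = L - x[i];
      if (s2 < P.sc) {
        U_wall += wallU(s2);
        double du = walldU(s2);
        fx[i] += du;        // pushes the monomer towards -x
        if (nidx[i] > 0) Fw_bun += -du;  // reaction force on the wall (+x)
        else Fw_m += -du;
      }
    }
    force_dirty = false;
  }

  double wall_force_total() const {
    double F = Fw_bun + Fw_m - P.kT * L;
    if (include_pA) F -= pA;
    return F;
  }

  // ---- Langevin step (stochastic velocity-Verlet with two Gaussians) ----
  std::vector<double> phi, eta;  // per-dof noise, wall appended last

  void vec_step() {
    if (force_dirty) compute_forces();
    int N = n_slots();
    double h = P.h;
    double gm = P.zeta / P.M;
    double sm = (P.kBT > 0) ? std::sqrt(2.0 * P.kBT * gm / P.M) : 0.0;
    double gw = P.zetaw / P.Mw;
    double sw = (P.kBT > 0) ? std::sqrt(2.0 * P.kBT * gw / P.Mw) : 0.0;
    double sqh = std::sqrt(h);
    double h32 = h * sqh;

    // per-type coefficients
    double c2m = 1.0 - 0.25 * h * gm, c2w = 1.0 - 0.25 * h * gw;
    double c3m = 0.5 * sqh * sm, c3w = 0.5 * sqh * sw;
    double c4m = 0.25 * h32 * gm * sm, c4w = 0.25 * h32 * gw * sw;
    double c5m = h32 * sm / (2.0 * SQRT3), c5w = h32 * sw / (2.0 * SQRT3);

    int ndof = 3 * N + 1;
    if (static_cast<int>(phi.size()) < ndof) {
      phi.resize(ndof);
      eta.resize(ndof);
    }
    atrng::Stream &th = rng.st[atrng::THERMOSTAT];
    for (int i = 0; i < N; ++i) {
      if (!is_mobile(i)) continue;
      for (int kdim = 0; kdim < 3; ++kdim) {
        phi[3 * i + kdim] = th.normal();
        eta[3 * i + kdim] = th.normal();
      }
    }
    double phw = 0.0, etw = 0.0;
    if (mobile_wall) {
      phw = th.normal();
      etw = th.normal();
    }

    std::vector<double> vhx(N), vhy(N), vhz(N);
    for (int i = 0; i < N; ++i) {
      if (!is_mobile(i)) continue;
      double ax = fx[i] / P.M, ay = fy[i] / P.M, az = fz[i] / P.M;
      double p0 = phi[3 * i], p1 = phi[3 * i + 1], p2 = phi[3 * i + 2];
      double e0 = eta[3 * i], e1 = eta[3 * i + 1], e2 = eta[3 * i + 2];
      vhx[i] = vx[i] + c3m * p0 + 0.5 * h * (ax - gm * vx[i]) * c2m -
               c4m * (0.5 * p0 + e0 / SQRT3);
      vhy[i] = vy[i] + c3m * p1 + 0.5 * h * (ay - gm * vy[i]) * c2m -
               c4m * (0.5 * p1 + e1 / SQRT3);
      vhz[i] = vz[i] + c3m * p2 + 0.5 * h * (az - gm * vz[i]) * c2m -
               c4m * (0.5 * p2 + e2 / SQRT3);
      x[i] += h * vhx[i] + c5m * e0;
      y[i] += h * vhy[i] + c5m * e1;
      z[i] += h * vhz[i] + c5m * e2;
      if (nidx[i] == 0) {
        y[i] = wrap(y[i]);
        z[i] = wrap(z[i]);
      }
    }
    double vhw = 0.0;
    if (mobile_wall) {
      double aw = wall_force_total() / P.Mw;
      vhw = Ldot + c3w * phw + 0.5 * h * (aw - gw * Ldot) * c2w -
            c4w * (0.5 * phw + etw / SQRT3);
      L += h * vhw + c5w * etw;
    }

    compute_forces();

    for (int i = 0; i < N; ++i) {
      if (!is_mobile(i)) continue;
      double ax = fx[i] / P.M, ay = fy[i] / P.M, az = fz[i] / P.M;
      double p0 = phi[3 * i], p1 = phi[3 * i + 1], p2 = phi[3 * i + 2];
      double e0 = eta[3 * i], e1 = eta[3 * i + 1], e2 = eta[3 * i + 2];
      vx[i] = vhx[i] + c3m * p0 + 0.5 * h * (ax - gm * vhx[i]) * c2m -
              c4m * (0.5 * p0 + e0 / SQRT3);
      vy[i] = vhy[i] + c3m * p1 + 0.5 * h * (ay - gm * vhy[i]) * c2m -
              c4m * (0.5 * p1 + e1 / SQRT3);
      vz[i] = vhz[i] + c3m * p2 + 0.5 * h * (az - gm * vhz[i]) * c2m -
              c4m * (0.5 * p2 + e2 / SQRT3);
      if (!std::isfinite(x[i]) || !std::isfinite(vx[i]))
        stop("non-finite coordinate for monomer slot %d at t = %g", i + 1, t);
    }
    if (mobile_wall) {
      double aw = wall_force_total() / P.Mw;
      Ldot = vhw + c3w * phw + 0.5 * h * (aw - gw * vhw) * c2w -
             c4w * (0.5 * phw + etw / SQRT3);
      if (!std::isfinite(L))
        stop("non-finite wall position at t = %g", t);
    }
    t += h;
  }

  // ---- topology helpers ----
  inline int zn_of(int n) const {
    return 1 + static_cast<int>(std::floor((L - hn[n]) / P.d));
  }
  inline int m_of(int n) const {
    return static_cast<int>(fil[n].size()) - zn_of(n);
  }
  static inline int midx(int m) {
    int k = m + MOFF;
    if (k < 0) k = 0;
    if (k >= MSZ) k = MSZ - 1;
    return k;
  }

  double dist2_tip(int slot, int tip) const {
    double dx = x[slot] - x[tip];
    double dy = fold(y[slot] - y[tip]);
    double dz = fold(z[slot] - z[tip]);
    return dx * dx + dy * dy + dz * dz;
  }

  // free monomers within r_c of a filament tip are "chemically reactive"
  bool reactive_point(double px, double py, double pz) const {
    double rc2 = P.rc * P.rc;
    for (int n = 0; n < P.Nf; ++n) {
      int tip = fil[n].back();
      double dx = px - x[tip];
      double dy = fold(py - y[tip]);
      double dz = fold(pz - z[tip]);
      if (dx * dx + dy * dy + dz * dz < rc2) return true;
    }
    return false;
  }

  int collect_candidates(int tip, std::vector<int> &out) const {
    out.clear();
    double rc2 = P.rc * P.rc;
    int N = n_slots();
    for (int i = 0; i < N; ++i) {
      if (nidx[i] != 0) continue;
      if (dist2_tip(i, tip) < rc2) out.push_back(i);
    }
    return static_cast<int>(out.size());
  }

  // elastic energy (spring + bend) of a bond with vector b attached after
  // rank j_eff of filament n: the bend angle is taken at rank j_eff,
  // between b and the preceding bond (ranks j_eff-1 -> j_eff)
  double tip_bond_energy(int n, int j_eff, double bx, double by,
                         double bz) const {
    const std::vector<int> &f = fil[n];
    int tip = f[j_eff - 1], prev = f[j_eff - 2];
    double r = std::sqrt(bx * bx + by * by + bz * bz);
    double px = x[tip] - x[prev], py = y[tip] - y[prev], pz = z[tip] - z[prev];
    double np = std::sqrt(px * px + py * py + pz * pz);
    double c = (bx * px + by * py + bz * pz) / (r * np);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    return 0.5 * P.ks * (r - P.d) * (r - P.d) + P.kap * (1.0 - c);
  }

  // ---- reaction moves ----
  //
  // Single-monomer capture/release at the tip, in place.  With N_r free
  // monomers inside the tip's reaction sphere and E the elastic (spring +
  // bend) energy of the created/annihilated bond,
  //     a_poly  = min(1, N_r exp(-beta E))
  //     a_depol = exp(-beta eps0) * min(1, exp(+beta E) / N_r')
  // which satisfy detailed balance with respect to the Boltzmann measure
  // (the ratio is N_r exp(-beta dU), dU = -eps0 + E) and give a bulk
  // depolymerization rate close to nu * exp(-beta eps0).
  std::vector<int> cand_buf;

  void attempt_poly(int n) {
    int m = m_of(n);
    if (do_counters) u_att[midx(m)] += 1.0;
    const std::vector<int> &f = fil[n];
    int j = static_cast<int>(f.size());
    int tip = f[j - 1];
    int Nr = collect_candidates(tip, cand_buf);
    if (Nr == 0) return;
    atrng::Stream &rs = rng.st[atrng::REACTION];
    int pick = static_cast<int>(rs.unif() * Nr);
    if (pick >= Nr) pick = Nr - 1;
    int c = cand_buf[pick];
    // bond vector through the nearest transverse image
    double bx = x[c] - x[tip];
    double by = fold(y[c] - y[tip]);
    double bz = fold(z[c] - z[tip]);
    double E = tip_bond_energy(n, j, bx, by, bz);
    double acc = Nr * std::exp(-P.beta * E);
    if (acc > 1.0) acc = 1.0;
    if (rs.unif() < acc) {
      // shift the candidate onto the image actually bonded
      y[c] = y[tip] + by;
      z[c] = z[tip] + bz;
      nidx[c] = n + 1;
      kidx[c] = j + 1;
      fil[n].push_back(c);
      n_free--;
      force_dirty = true;
      if (do_counters) u_succ[midx(m)] += 1.0;
      ev_t.push_back(t); ev_n.push_back(n + 1); ev_dir.push_back(+1);
      ev_m.push_back(m); ev_dU.push_back(-P.eps0 + E); ev_Nr.push_back(Nr);
      ev_acc.push_back(1);
      if (max_size > 0 && j + 1 >= max_size) stop_flag = true;
    } else if (log_attempts) {
      ev_t.push_back(t); ev_n.push_back(n + 1); ev_dir.push_back(+1);
      ev_m.push_back(m); ev_dU.push_back(-P.eps0 + E); ev_Nr.push_back(Nr);
      ev_acc.push_back(0);
    }
  }

  void attempt_depol(int n) {
    int m = m_of(n);
    if (do_counters) w_att[midx(m)] += 1.0;
    std::vector<int> &f = fil[n];
    int j = static_cast<int>(f.size());
    if (j <= 2) return;  // seeds are permanent
    int tip = f[j - 1], newtip = f[j - 2];
    double bx = x[tip] - x[newtip], by = y[tip] - y[newtip],
           bz = z[tip] - z[newtip];
    double r2 = bx * bx + by * by + bz * bz;
    if (r2 > P.rc * P.rc) return;  // reverse move could not re-select it
    // energy of the existing last bond: spring plus the bend at rank j-1
    double E = tip_bond_energy(n, j - 1, bx, by, bz);
    // candidates around the would-be tip in the post-move state: the freed
    // monomer itself plus any other free monomer already in the sphere
    int Nrp = 1 + collect_candidates(newtip, cand_buf);
    atrng::Stream &rs = rng.st[atrng::REACTION];
    double inner = std::exp(P.beta * E) / Nrp;
    if (inner > 1.0) inner = 1.0;
    double acc = std::exp(-P.beta * P.eps0) * inner;
    if (rs.unif() < acc) {
      f.pop_back();
      nidx[tip] = 0;
      kidx[tip] = 0;
      y[tip] = wrap(y[tip]);
      z[tip] = wrap(z[tip]);
      n_free++;
      force_dirty = true;
      if (do_counters) w_succ[midx(m)] += 1.0;
      ev_t.push_back(t); ev_n.push_back(n + 1); ev_dir.push_back(-1);
      ev_m.push_back(m); ev_dU.push_back(P.eps0 - E); ev_Nr.push_back(Nrp);
      ev_acc.push_back(1);
    } else if (log_attempts) {
      ev_t.push_back(t); ev_n.push_back(n + 1); ev_dir.push_back(-1);
      ev_m.push_back(m); ev_dU.push_back(P.eps0 - E); ev_Nr.push_back(Nrp);
      ev_acc.push_back(0);
    }
  }

  // ---- grand-canonical exchange ----
  void attempt_gc() {
    atrng::Stream &rs = rng.st[atrng::RESERVOIR];
    double V = P.A * L;
    if (rs.unif() < 0.5) {
      ins_att += 1.0;
      double px = rs.unif() * L;
      double py = rs.unif() * Lp2;
      double pz = rs.unif() * Lp2;
      if (react_on && reactive_point(px, py, pz)) {
        refuse_reactive += 1.0;
        return;
      }
      double dU = wallU(px) + wallU(L - px);
      double acc = P.rho1 * V * std::exp(-P.beta * dU) / (n_free + 1);
      if (acc > 1.0) acc = 1.0;
      if (rs.unif() < acc) {
        double sv = (P.kBT > 0) ? std::sqrt(P.kBT / P.M) : 0.0;
        x.push_back(px); y.push_back(py); z.push_back(pz);
        vx.push_back(sv * rs.normal());
        vy.push_back(sv * rs.normal());
        vz.push_back(sv * rs.normal());
        nidx.push_back(0);
        kidx.push_back(0);
        n_free++;
        ins_acc += 1.0;
        force_dirty = true;
      }
    } else {
      del_att += 1.0;
      if (n_free == 0) return;
      int pick = static_cast<int>(rs.unif() * n_free);
      if (pick >= n_free) pick = n_free - 1;
      int slot = -1, seen = 0;
      int N = n_slots();
      for (int i = 0; i < N; ++i) {
        if (nidx[i] == 0 && seen++ == pick) { slot = i; break; }
      }
      if (react_on && reactive_point(x[slot], y[slot], z[slot])) {
        refuse_reactive += 1.0;
        return;
      }
      double dU = wallU(x[slot]) + wallU(L - x[slot]);
      double acc = n_free * std::exp(P.beta * dU) / (P.rho1 * V);
      if (acc > 1.0) acc = 1.0;
      if (rs.unif() < acc) {
        remove_slot(slot);
        n_free--;
        del_acc += 1.0;
        force_dirty = true;
      }
    }
  }

  void remove_slot(int slot) {
    int last = n_slots() - 1;
    if (slot != last) {
      x[slot] = x[last]; y[slot] = y[last]; z[slot] = z[last];
      vx[slot] = vx[last]; vy[slot] = vy[last]; vz[slot] = vz[last];
      nidx[slot] = nidx[last];
      kidx[slot] = kidx[last];
      if (nidx[slot] > 0) fil[nidx[slot] - 1][kidx[slot] - 1] = slot;
    }
    x.pop_back(); y.pop_back(); z.pop_back();
    vx.pop_back(); vy.pop_back(); vz.pop_back();
    nidx.pop_back(); kidx.pop_back();
  }

  // ---- event scheduling ----
  void ensure_clocks() {
    int nclk = 2 * P.Nf + 1;
    if (static_cast<int>(clock.size()) != nclk)
      clock.assign(nclk, std::numeric_limits<double>::quiet_NaN());
    for (int c = 0; c < nclk; ++c) {
      bool enabled = (c < 2 * P.Nf) ? react_on : gc_on;
      if (!enabled) continue;
      if (!std::isfinite(clock[c]) || clock[c] < t) {
        double rate = (c < 2 * P.Nf) ? P.nu : P.nuGC;
        atrng::Stream &rs =
            rng.st[(c < 2 * P.Nf) ? atrng::REACTION : atrng::RESERVOIR];
        clock[c] = t + rs.expdev(rate);
      }
    }
  }

  void process_events() {
    int nclk = 2 * P.Nf + 1;
    for (;;) {
      int cmin = -1;
      double tmin = t;  // step boundary already advanced past events
      for (int c = 0; c < nclk; ++c) {
        bool enabled = (c < 2 * P.Nf) ? react_on : gc_on;
        if (!enabled) continue;
        if (clock[c] <= tmin + 1e-14 && (cmin < 0 || clock[c] < clock[cmin]))
          cmin = c;
      }
      if (cmin < 0) break;
      double rate;
      if (cmin < 2 * P.Nf) {
        rate = P.nu;
        int n = cmin / 2;
        if (cmin % 2 == 0) attempt_poly(n);
        else attempt_depol(n);
        clock[cmin] += rng.st[atrng::REACTION].expdev(rate);
      } else {
        rate = P.nuGC;
        attempt_gc();
        clock[cmin] += rng.st[atrng::RESERVOIR].expdev(rate);
      }
      if (stop_flag) break;
    }
  }

  // ---- accumulation ----
  void accumulate_q() {
    for (int n = 0; n < P.Nf; ++n) q_m[midx(m_of(n))] += 1.0;
  }

  void record_trace() {
    if (force_dirty) compute_forces();
    tr_t.push_back(t);
    tr_L.push_back(L);
    tr_Ldot.push_back(Ldot);
    tr_N1.push_back(n_free);
    tr_Ub.push_back(U_bond);
    tr_Ubend.push_back(U_bend);
    tr_Uw.push_back(U_wall);
    tr_Fbun.push_back(Fw_bun);
    tr_Fwm.push_back(Fw_m);
    for (int n = 0; n < P.Nf; ++n) {
      const std::vector<int> &f = fil[n];
      int tip = f.back();
      tr_j[n].push_back(static_cast<int>(f.size()));
      tr_X[n].push_back(x[tip] - hn[n]);
      double dy = y[tip] - sy[n], dz = z[tip] - sz[n];
      tr_R[n].push_back(std::sqrt(dy * dy + dz * dz));
    }
  }

  void record_xhist() {
    int N = n_slots();
    int nb = static_cast<int>(xhist.size());
    for (int i = 0; i < N; ++i) {
      if (nidx[i] != 0) continue;
      int b = static_cast<int>(std::floor(x[i] / xhist_bin));
      if (b >= 0 && b < nb) xhist[b] += 1.0;
    }
    xhist_samples += 1.0;
  }
};

// ---- state import/export ----

static void import_state(Engine &E, const List &state) {
  NumericMatrix pos = state["pos"], vel = state["vel"];
  IntegerVector nn = state["n_idx"], kk = state["k_idx"];
  int N = pos.nrow();
  E.x.assign(N, 0.0); E.y.assign(N, 0.0); E.z.assign(N, 0.0);
  E.vx.assign(N, 0.0); E.vy.assign(N, 0.0); E.vz.assign(N, 0.0);
  E.nidx.assign(N, 0); E.kidx.assign(N, 0);
  for (int i = 0; i < N; ++i) {
    E.x[i] = pos(i, 0); E.y[i] = pos(i, 1); E.z[i] = pos(i, 2);
    E.vx[i] = vel(i, 0); E.vy[i] = vel(i, 1); E.vz[i] = vel(i, 2);
    E.nidx[i] = nn[i]; E.kidx[i] = kk[i];
  }
  E.hn = as<std::vector<double> >(state["hn"]);
  E.sy = as<std::vector<double> >(state["seed_y"]);
  E.sz = as<std::vector<double> >(state["seed_z"]);
  E.L = as<double>(state["L"]);
  E.Ldot = as<double>(state["L_dot"]);
  E.t = as<double>(state["t"]);

  // rebuild filament rank lists from the topological indices
  E.fil.assign(E.P.Nf, std::vector<int>());
  std::vector<int> jn(E.P.Nf, 0);
  for (int i = 0; i < N; ++i)
    if (E.nidx[i] > 0) {
      if (E.nidx[i] > E.P.Nf) stop("monomer with filament index > Nf");
      jn[E.nidx[i] - 1] = std::max(jn[E.nidx[i] - 1], E.kidx[i]);
    }
  for (int n = 0; n < E.P.Nf; ++n) {
    if (jn[n] < 2) stop("filament %d has fewer than 2 monomers", n + 1);
    E.fil[n].assign(jn[n], -1);
  }
  E.n_free = 0;
  for (int i = 0; i < N; ++i) {
    if (E.nidx[i] > 0) {
      int n = E.nidx[i] - 1, k = E.kidx[i] - 1;
      if (E.fil[n][k] != -1) stop("duplicate topological index (%d,%d)",
                                  E.nidx[i], E.kidx[i]);
      E.fil[n][k] = i;
    } else {
      E.n_free++;
    }
  }
  for (int n = 0; n < E.P.Nf; ++n)
    for (int k = 0; k < jn[n]; ++k)
      if (E.fil[n][k] < 0) stop("missing rank %d in filament %d", k + 1, n + 1);

  RawVector rr = state["rng"];
  if (rr.size() != 128) stop("rng state must be 128 raw bytes");
  E.rng.load(RAW(rr));

  NumericVector nr = state["next_reaction"];
  double ngc = as<double>(state["next_gc"]);
  E.clock.assign(2 * E.P.Nf + 1, std::numeric_limits<double>::quiet_NaN());
  for (int c = 0; c < 2 * E.P.Nf && c < nr.size(); ++c) E.clock[c] = nr[c];
  E.clock[2 * E.P.Nf] = ngc;
}

static List export_state(const Engine &E) {
  int N = E.n_slots();
  NumericMatrix pos(N, 3), vel(N, 3);
  IntegerVector nn(N), kk(N);
  for (int i = 0; i < N; ++i) {
    pos(i, 0) = E.x[i]; pos(i, 1) = E.y[i]; pos(i, 2) = E.z[i];
    vel(i, 0) = E.vx[i]; vel(i, 1) = E.vy[i]; vel(i, 2) = E.vz[i];
    nn[i] = E.nidx[i]; kk[i] = E.kidx[i];
  }
  RawVector rr(128);
  E.rng.save(RAW(rr));
  NumericVector nreact(2 * E.P.Nf);
  for (int c = 0; c < 2 * E.P.Nf; ++c) nreact[c] = E.clock[c];
  return List::create(
      _["pos"] = pos, _["vel"] = vel, _["n_idx"] = nn, _["k_idx"] = kk,
      _["hn"] = E.hn, _["seed_y"] = E.sy, _["seed_z"] = E.sz, _["L"] = E.L,
      _["L_dot"] = E.Ldot, _["t"] = E.t, _["rng"] = rr,
      _["next_reaction"] = nreact, _["next_gc"] = E.clock[2 * E.P.Nf]);
}

static void setup_engine(Engine &E, const List &state, const List &params,
                         const List &control) {
  E.P = read_params(params);
  E.Lp2 = std::sqrt(E.P.A);
  E.mobile_wall = as<bool>(control["mobile_wall"]);
  E.react_on = as<bool>(control["reactions"]);
  E.gc_on = as<bool>(control["reservoir"]);
  E.include_pA = as<bool>(control["include_pA"]);
  E.do_counters = as<bool>(control["counters"]);
  E.trace_stride = as<int>(control["trace_stride"]);
  E.max_size = as<int>(control["max_size"]);
  E.log_attempts = control.containsElementNamed("log_attempts") ?
      as<bool>(control["log_attempts"]) : false;
  E.xhist_bin = as<double>(control["xhist_bin"]);
  E.xhist_stride = as<int>(control["xhist_stride"]);
  E.pA = E.P.kBT * E.P.rho1 * E.P.A;
  import_state(E, state);
  E.q_m.assign(MSZ, 0.0);
  E.u_att.assign(MSZ, 0.0);
  E.u_succ.assign(MSZ, 0.0);
  E.w_att.assign(MSZ, 0.0);
  E.w_succ.assign(MSZ, 0.0);
  E.ins_att = E.ins_acc = E.del_att = E.del_acc = E.refuse_reactive = 0.0;
  E.tr_j.assign(E.P.Nf, std::vector<int>());
  E.tr_X.assign(E.P.Nf, std::vector<double>());
  E.tr_R.assign(E.P.Nf, std::vector<double>());
  if (E.xhist_stride > 0) {
    int nb = static_cast<int>(std::ceil(E.L / E.xhist_bin)) + 1;
    E.xhist.assign(nb, 0.0);
  }
  E.xhist_samples = 0.0;
  E.stop_flag = false;
  E.force_dirty = true;
  E.ensure_clocks();
}

// [[Rcpp::export]]
List cpp_run_segment(List state, List params, List control, double duration) {
  Engine E;
  setup_engine(E, state, params, control);
  long nsteps = static_cast<long>(std::llround(duration / E.P.h));
  E.compute_forces();
  long step;
  for (step = 1; step <= nsteps; ++step) {
    E.vec_step();
    if (E.react_on || E.gc_on) E.process_events();
    if (E.do_counters) E.accumulate_q();
    if (E.trace_stride > 0 && step % E.trace_stride == 0) E.record_trace();
    if (E.xhist_stride > 0 && step % E.xhist_stride == 0) E.record_xhist();
    if (E.stop_flag) break;
    if (step % 500000 == 0) Rcpp::checkUserInterrupt();
  }
  long steps_done = std::min(step, nsteps);

  // compress counters to the m range actually visited
  std::vector<int> ms;
  for (int k = 0; k < MSZ; ++k)
    if (E.q_m[k] > 0 || E.u_att[k] > 0 || E.w_att[k] > 0) ms.push_back(k);
  int nm = static_cast<int>(ms.size());
  IntegerVector cm(nm);
  NumericVector cq(nm), cua(nm), cus(nm), cwa(nm), cws(nm);
  for (int i = 0; i < nm; ++i) {
    cm[i] = ms[i] - MOFF;
    cq[i] = E.q_m[ms[i]];
    cua[i] = E.u_att[ms[i]];
    cus[i] = E.u_succ[ms[i]];
    cwa[i] = E.w_att[ms[i]];
    cws[i] = E.w_succ[ms[i]];
  }

  List trace = List::create(
      _["t"] = E.tr_t, _["L"] = E.tr_L, _["L_dot"] = E.tr_Ldot,
      _["N1"] = E.tr_N1, _["U_bond"] = E.tr_Ub, _["U_bend"] = E.tr_Ubend,
      _["U_wall"] = E.tr_Uw, _["F_bun"] = E.tr_Fbun, _["F_wm"] = E.tr_Fwm);
  List perfil = List::create(_["j"] = wrap(E.tr_j), _["X"] = wrap(E.tr_X),
                             _["R_perp"] = wrap(E.tr_R));
  List counters = List::create(
      _["m"] = cm, _["Q"] = cq, _["U_att"] = cua, _["U_succ"] = cus,
      _["W_att"] = cwa, _["W_succ"] = cws);
  List gc = List::create(
      _["ins_att"] = E.ins_att, _["ins_acc"] = E.ins_acc,
      _["del_att"] = E.del_att, _["del_acc"] = E.del_acc,
      _["refuse_reactive"] = E.refuse_reactive);
  List events = List::create(
      _["t"] = E.ev_t, _["n"] = E.ev_n, _["dir"] = E.ev_dir, _["m"] = E.ev_m,
      _["dU"] = E.ev_dU, _["N_r"] = E.ev_Nr, _["accepted"] = E.ev_acc);
  List xh = R_NilValue;
  if (E.xhist_stride > 0)
    xh = List::create(_["bin"] = E.xhist_bin, _["counts"] = E.xhist,
                      _["samples"] = E.xhist_samples);

  return List::create(
      _["state"] = export_state(E), _["trace"] = trace, _["per_fil"] = perfil,
      _["counters"] = counters, _["gc"] = gc, _["events"] = events,
      _["xhist"] = xh, _["steps"] = static_cast<double>(steps_done),
      _["stopped_early"] = E.stop_flag);
}

// Forces, energies and the wall force decomposition for a static
// configuration (used by tests and by the energy bookkeeping).
// [[Rcpp::export]]
List cpp_forces(List state, List params, bool include_pA) {
  Engine E;
  List control = List::create(
      _["mobile_wall"] = false, _["reactions"] = false, _["reservoir"] = false,
      _["include_pA"] = include_pA, _["counters"] = false,
      _["trace_stride"] = 0, _["max_size"] = 0, _["xhist_bin"] = 0.1,
      _["xhist_stride"] = 0);
  setup_engine(E, state, params, control);
  E.include_pA = include_pA;
  E.compute_forces();
  int N = E.n_slots();
  NumericMatrix F(N, 3);
  for (int i = 0; i < N; ++i) {
    F(i, 0) = E.fx[i]; F(i, 1) = E.fy[i]; F(i, 2) = E.fz[i];
  }
  return List::create(
      _["forces"] = F, _["F_wall"] = E.wall_force_total(),
      _["F_w_bun"] = E.Fw_bun, _["F_w_m"] = E.Fw_m, _["U_bond"] = E.U_bond,
      _["U_bend"] = E.U_bend, _["U_wall"] = E.U_wall);
}

// ---- RNG plumbing exposed to R ----

// [[Rcpp::export]]
RawVector cpp_rng_new(double seed) {
  atrng::RngSet rs;
  rs.seed(static_cast<uint64_t>(seed));
  RawVector out(128);
  rs.save(RAW(out));
  return out;
}

// [[Rcpp::export]]
List cpp_rng_draw(RawVector rng, int stream, int n, std::string type) {
  if (rng.size() != 128) stop("rng state must be 128 raw bytes");
  if (stream < 0 || stream > 3) stop("stream must be in 0..3");
  atrng::RngSet rs;
  rs.load(RAW(rng));
  NumericVector v(n);
  if (type == "uniform") {
    for (int i = 0; i < n; ++i) v[i] = rs.st[stream].unif();
  } else if (type == "normal") {
    for (int i = 0; i < n; ++i) v[i] = rs.st[stream].normal();
  } else {
    stop("unknown draw type '%s'", type.c_str());
  }
  RawVector out(128);
  rs.save(RAW(out));
  return List::create(_["values"] = v, _["rng"] = out);
}
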