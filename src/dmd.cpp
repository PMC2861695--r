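// Event-driven discrete molecular dynamics over square-well pair potentials.
//
// Units: length Angstrom, energy kcal/mol, temperature kcal/mol/k_B (k_B = 1),
// time in simulation time units (tu); mass such that v is A/tu.
//
// A potential is a set of strictly ascending boundaries b[0] < ... < b[B-1]
// with shell energies e[s] for the shell (b[s], b[s+1]); the region inside
// b[0] is a hard core and the region outside b[B-1] has energy 0 unless the
// potential is "bounded", in which case b[B-1] is an infinite outer wall
// (used for bond and 1-3 pseudo-angle constraints).
//
// Beads travel ballistically between events; at a boundary the radial
// relative velocity component is updated by the conservation laws for a
// square-well step (transmit with sqrt(vr^2 - 2*dU/mu) or reflect), which
// conserves linear momentum, angular momentum about the pair midpoint and
// total energy exactly (to round-off).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Potential {
  std::vector<double> b;  // boundaries, ascending
  std::vector<double> e;  // shell energies, size B-1
  bool bounded;           // outermost boundary is an infinite wall
  double shell_energy(int s) const {
    int B = (int)b.size();
    if (s >= 0 && s < B - 1) return e[s];
    return 0.0;  // outermost (unbounded) shell
  }
};

enum EvType { EV_PAIR = 0, EV_THERMO = 1, EV_SAVE = 2, EV_END = 3 };

struct Event {
  double t;
  uint64_t seq;      // deterministic tie-break: queue-insertion order
  int type;
  int i, j;          // pair beads (EV_PAIR)
  int bidx;          // boundary index being hit
  int dir;           // -1 inward, +1 outward
  uint64_t ci, cj;   // collision counters at scheduling time
};

struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seq > b.seq;
  }
};

class DmdSystem {
public:
  int n;
  double L;                 // periodic box edge
  std::vector<double> x, y, z, vx, vy, vz, m, tb;  // tb = last-update time per bead
  std::vector<int> itype;   // n*n interaction type (0 = none), row-major
  std::vector<int> shell;   // current shell per pair
  std::vector<uint64_t> cc; // per-bead collision counter
  std::vector<Potential> pots;
  double epot;              // tracked potential energy
  double tnow;
  uint64_t seq;
  std::priority_queue<Event, std::vector<Event>, EventCmp> q;

  double mimg(double d) const {
    // minimum image of one coordinate difference
    if (L <= 0) return d;
    return d - L * std::round(d / L);
  }

  void rel(int i, int j, double t, double* r, double* v) const {
    double dtI = t - tb[i], dtJ = t - tb[j];
    r[0] = mimg((x[i] + vx[i] * dtI) - (x[j] + vx[j] * dtJ));
    r[1] = mimg((y[i] + vy[i] * dtI) - (y[j] + vy[j] * dtJ));
    r[2] = mimg((z[i] + vz[i] * dtI) - (z[j] + vz[j] * dtJ));
    v[0] = vx[i] - vx[j]; v[1] = vy[i] - vy[j]; v[2] = vz[i] - vz[j];
  }

  void advance_bead(int i, double t) {
    double dt = t - tb[i];
    x[i] += vx[i] * dt; y[i] += vy[i] * dt; z[i] += vz[i] * dt;
    tb[i] = t;
  }

  int pair_shell(double d2, const Potential& p) const {
    int B = (int)p.b.size();
    int s = B - 1;  // outermost
    for (int k = 0; k < B; ++k) {
      if (d2 < p.b[k] * p.b[k]) { s = k - 1; break; }
    }
    return s;  // -1 would mean inside hard core (invalid)
  }

  // earliest positive root of |r + v t|^2 = d^2; which = -1 -> smaller root
  // (approach from outside), +1 -> larger root (escape from inside)
  static double quad_root(const double* r, const double* v, double d, int which) {
    double a = v[0]*v[0] + v[1]*v[1] + v[2]*v[2];
    if (a == 0.0) return -1.0;
    double b = r[0]*v[0] + r[1]*v[1] + r[2]*v[2];
    double c = r[0]*r[0] + r[1]*r[1] + r[2]*r[2] - d * d;
    double disc = b * b - a * c;
    if (disc < 0.0) return -1.0;
    double sq = std::sqrt(disc);
    double t = (which < 0) ? (-b - sq) / a : (-b + sq) / a;
    return t;
  }

  // schedule the next event for pair (i, j), if any
  void schedule_pair(int i, int j, double t) {
    int ty = itype[(size_t)i * n + j];
    if (ty == 0) return;
    const Potential& p = pots[ty - 1];
    int s = shell[(size_t)i * n + j];
    double r[3], v[3];
    rel(i, j, t, r, v);
    const double teps = 1e-12;
    double best = -1.0; int bb = -1, bd = 0;
    int B = (int)p.b.size();
    // inner boundary of current shell: b[s] (hard core when s == 0)
    if (s >= 0) {
      double tin = quad_root(r, v, p.b[s], -1);
      if (tin > teps && (best < 0 || tin < best)) { best = tin; bb = s; bd = -1; }
    }
    // outer boundary: b[s+1] when it exists
    if (s + 1 <= B - 1) {
      double tout = quad_root(r, v, p.b[s + 1], +1);
      if (tout > teps && (best < 0 || tout < best)) { best = tout; bb = s + 1; bd = +1; }
    }
    if (best > 0) {
      Event ev; ev.t = t + best; ev.seq = seq++; ev.type = EV_PAIR;
      ev.i = i; ev.j = j; ev.bidx = bb; ev.dir = bd; ev.ci = cc[i]; ev.cj = cc[j];
      q.push(ev);
    }
  }

  void reschedule_bead(int i, double t) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      int a = std::min(i, j), b = std::max(i, j);
      if (itype[(size_t)a * n + b] != 0) schedule_pair(a, b, t);
    }
  }

  // resolve a pair event; returns true if velocities changed
  bool resolve_pair(const Event& ev) {
    int i = ev.i, j = ev.j;
    advance_bead(i, ev.t);
    advance_bead(j, ev.t);
    const Potential& p = pots[itype[(size_t)i * n + j] - 1];
    size_t key = (size_t)i * n + j;
    int s = shell[key];
    int B = (int)p.b.size();

    double r[3], v[3];
    rel(i, j, ev.t, r, v);
    double d = std::sqrt(r[0]*r[0] + r[1]*r[1] + r[2]*r[2]);
    if (d <= 0) return false;
    double nx = r[0] / d, ny = r[1] / d, nz = r[2] / d;
    double vr = v[0]*nx + v[1]*ny + v[2]*nz;
    double mu = m[i] * m[j] / (m[i] + m[j]);

    bool infinite_wall = false;
    double dU = 0.0;
    int snew = s;
    if (ev.dir < 0) {               // inward through b[s]
      if (s == 0) infinite_wall = true;  // hard core
      else { dU = p.shell_energy(s - 1) - p.shell_energy(s); snew = s - 1; }
    } else {                         // outward through b[s+1]
      if (p.bounded && ev.bidx == B - 1) infinite_wall = true;  // bond wall
      else { dU = p.shell_energy(s + 1) - p.shell_energy(s); snew = s + 1; }
    }

    double vrp;
    bool transmit = false;
    if (infinite_wall) {
      vrp = -vr;
    } else if (vr * vr > 2.0 * dU / mu) {
      double s2 = vr * vr - 2.0 * dU / mu;
      vrp = (vr >= 0 ? 1.0 : -1.0) * std::sqrt(s2);
      transmit = true;
    } else {
      vrp = -vr;  // reflected off an uphill step it cannot climb
    }

    double J = mu * (vrp - vr);  // impulse along n applied to bead i
    vx[i] += (J / m[i]) * nx; vy[i] += (J / m[i]) * ny; vz[i] += (J / m[i]) * nz;
    vx[j] -= (J / m[j]) * nx; vy[j] -= (J / m[j]) * ny; vz[j] -= (J / m[j]) * nz;
    if (transmit) { shell[key] = snew; epot += dU; }
    cc[i]++; cc[j]++;
    return true;
  }

  double ekin() const {
    double k = 0.0;
    for (int i = 0; i < n; ++i)
      k += 0.5 * m[i] * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
    return k;
  }

  double epot_scratch() const {
    double u = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        int ty = itype[(size_t)i * n + j];
        if (ty == 0) continue;
        u += pots[ty - 1].shell_energy(shell[(size_t)i * n + j]);
      }
    return u;
  }

  // mass-weighted radius of gyration at time t (beads advanced beforehand)
  double rgyr() const {
    double M = 0, cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < n; ++i) { M += m[i]; cx += m[i]*x[i]; cy += m[i]*y[i]; cz += m[i]*z[i]; }
    cx /= M; cy /= M; cz /= M;
    double s = 0;
    for (int i = 0; i < n; ++i) {
      double dx = x[i]-cx, dy = y[i]-cy, dz = z[i]-cz;
      s += m[i] * (dx*dx + dy*dy + dz*dz);
    }
    return std::sqrt(s / M);
  }
};

}  // namespace

// Earliest event for one pair: r, v relative (min-image applied by caller),
// boundaries of the square-well potential, current shell, bounded flag.
// Returns list(time, boundary, dir) or NULL when no boundary is reachable.
// [[Rcpp::export]]
SEXP pair_event_time_cpp(NumericVector r, NumericVector v,
                         NumericVector boundaries, int shell, bool bounded) {
  double rr[3] = { r[0], r[1], r[2] };
  double vv[3] = { v[0], v[1], v[2] };
  int B = boundaries.size();
  const double teps = 1e-12;
  double best = -1.0; int bb = -1, bd = 0;
  if (shell >= 0) {
    double t = DmdSystem::quad_root(rr, vv, boundaries[shell], -1);
    if (t > teps && (best < 0 || t < best)) { best = t; bb = shell; bd = -1; }
  }
  if (shell + 1 <= B - 1) {
    double t = DmdSystem::quad_root(rr, vv, boundaries[shell + 1], +1);
    if (t > teps && (best < 0 || t < best)) { best = t; bb = shell + 1; bd = +1; }
  }
  (void)bounded;
  if (best < 0) return R_NilValue;
  return List::create(_["time"] = best, _["boundary"] = bb + 1, _["dir"] = bd);
}

// Square-well collision rule for one pair exactly at a boundary.
// dU is the energy step for crossing in the current direction of radial
// motion; infinite_wall forces reflection (hard core / bond wall).
// [[Rcpp::export]]
List resolve_collision_cpp(NumericVector xi, NumericVector xj,
                           NumericVector vi, NumericVector vj,
                           double mi, double mj, double dU, bool infinite_wall) {
  double r[3] = { xi[0]-xj[0], xi[1]-xj[1], xi[2]-xj[2] };
  double d = std::sqrt(r[0]*r[0] + r[1]*r[1] + r[2]*r[2]);
  if (d <= 0) stop("coincident beads");
  double nx = r[0]/d, ny = r[1]/d, nz = r[2]/d;
  double vr = (vi[0]-vj[0])*nx + (vi[1]-vj[1])*ny + (vi[2]-vj[2])*nz;
  double mu = mi * mj / (mi + mj);
  double vrp; bool transmit = false;
  if (infinite_wall) vrp = -vr;
  else if (vr * vr > 2.0 * dU / mu) {
    vrp = (vr >= 0 ? 1.0 : -1.0) * std::sqrt(vr*vr - 2.0*dU/mu);
    transmit = true;
  } else vrp = -vr;
  double J = mu * (vrp - vr);
  NumericVector vio = clone(vi), vjo = clone(vj);
  vio[0] += (J/mi)*nx; vio[1] += (J/mi)*ny; vio[2] += (J/mi)*nz;
  vjo[0] -= (J/mj)*nx; vjo[1] -= (J/mj)*ny; vjo[2] -= (J/mj)*nz;
  return List::create(_["v_i"] = vio, _["v_j"] = vjo, _["transmitted"] = transmit);
}

// Full event loop. itype: n x n integer matrix, 0 = no interaction, k > 0
// indexes `potentials` (list of list(boundaries, energies, bounded)).
// thermo_rate: Andersen ghost-collision rate (events per tu); 0 disables.
// Uses R's RNG (set.seed on the R side controls everything).
// [[Rcpp::export]]
List dmd_engine_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                    IntegerMatrix itype, List potentials,
                    double L, double temperature, double duration,
                    double save_interval, double thermo_rate, double t0) {
  RNGScope rngs;
  DmdSystem S;
  S.n = pos0.nrow();
  S.L = L;
  S.tnow = t0;
  S.seq = 0;
  S.epot = 0.0;
  int n = S.n;
  S.x.resize(n); S.y.resize(n); S.z.resize(n);
  S.vx.resize(n); S.vy.resize(n); S.vz.resize(n);
  S.m.resize(n); S.tb.assign(n, t0); S.cc.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    S.x[i] = pos0(i,0); S.y[i] = pos0(i,1); S.z[i] = pos0(i,2);
    S.vx[i] = vel0(i,0); S.vy[i] = vel0(i,1); S.vz[i] = vel0(i,2);
    S.m[i] = mass[i];
    if (S.m[i] <= 0) stop("non-positive mass");
  }
  for (int k = 0; k < potentials.size(); ++k) {
    List pk = potentials[k];
    Potential p;
    p.b = as<std::vector<double>>(pk["boundaries"]);
    p.e = as<std::vector<double>>(pk["energies"]);
    p.bounded = as<bool>(pk["bounded"]);
    for (size_t q = 1; q < p.b.size(); ++q)
      if (p.b[q] <= p.b[q-1]) stop("potential boundaries must be strictly ascending");
    if (p.e.size() != p.b.size() - 1) stop("need one shell energy per inter-boundary shell");
    S.pots.push_back(p);
  }
  S.itype.assign((size_t)n * n, 0);
  S.shell.assign((size_t)n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int ty = itype(i, j);
      S.itype[(size_t)i * n + j] = ty;
      if (ty == 0) continue;
      if (ty < 1 || ty > (int)S.pots.size()) stop("interaction type out of range");
      double r[3], v[3];
      S.rel(i, j, t0, r, v);
      double d2 = r[0]*r[0] + r[1]*r[1] + r[2]*r[2];
      int s = S.pair_shell(d2, S.pots[ty - 1]);
      if (s < 0) stop("initial configuration violates a hard core (pair %d,%d)", i + 1, j + 1);
      if (S.pots[ty - 1].bounded && s > (int)S.pots[ty - 1].b.size() - 2)
        stop("initial configuration outside a bond wall (pair %d,%d)", i + 1, j + 1);
      S.shell[(size_t)i * n + j] = s;
      S.epot += S.pots[ty - 1].shell_energy(s);
    }

  double t_end = t0 + duration;
  int n_frames = (save_interval > 0 && duration > 0)
                   ? (int)std::floor(duration / save_interval + 1e-9) : 0;

  // seed the queue
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (S.itype[(size_t)i * n + j] != 0) S.schedule_pair(i, j, t0);
  if (thermo_rate > 0) {
    Event ev; ev.t = t0 + R::exp_rand() / thermo_rate; ev.seq = S.seq++;
    ev.type = EV_THERMO; ev.i = ev.j = ev.bidx = ev.dir = 0; ev.ci = ev.cj = 0;
    S.q.push(ev);
  }
  int next_save = 1;
  if (n_frames > 0) {
    Event ev; ev.t = t0 + save_interval; ev.seq = S.seq++;
    ev.type = EV_SAVE; ev.i = ev.j = ev.bidx = ev.dir = 0; ev.ci = ev.cj = 0;
    S.q.push(ev);
  }

  std::vector<double> f_time, f_epot, f_ekin, f_rg;
  List frames(n_frames);
  int fidx = 0;
  long long n_collisions = 0;
  double last_t = t0;

  while (!S.q.empty()) {
    Event ev = S.q.top(); S.q.pop();
    if (ev.type == EV_PAIR && (ev.ci != S.cc[ev.i] || ev.cj != S.cc[ev.j]))
      continue;  // stale
    if (ev.t > t_end) break;
    if (ev.t < last_t - 1e-9) stop("event time went backwards");
    last_t = ev.t;

    if (ev.type == EV_PAIR) {
      S.resolve_pair(ev);
      n_collisions++;
      S.reschedule_bead(ev.i, ev.t);
      S.reschedule_bead(ev.j, ev.t);
      if ((n_collisions & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    } else if (ev.type == EV_THERMO) {
      int i = (int)std::floor(unif_rand() * n);
      if (i >= n) i = n - 1;
      S.advance_bead(i, ev.t);
      double sd = std::sqrt(temperature / S.m[i]);
      S.vx[i] = norm_rand() * sd;
      S.vy[i] = norm_rand() * sd;
      S.vz[i] = norm_rand() * sd;
      S.cc[i]++;
      S.reschedule_bead(i, ev.t);
      Event nx; nx.t = ev.t + R::exp_rand() / thermo_rate; nx.seq = S.seq++;
      nx.type = EV_THERMO; nx.i = nx.j = nx.bidx = nx.dir = 0; nx.ci = nx.cj = 0;
      S.q.push(nx);
    } else if (ev.type == EV_SAVE) {
      for (int i = 0; i < n; ++i) S.advance_bead(i, ev.t);
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) { fr(i,0) = S.x[i]; fr(i,1) = S.y[i]; fr(i,2) = S.z[i]; }
      frames[fidx++] = fr;
      f_time.push_back(ev.t);
      f_epot.push_back(S.epot);
      f_ekin.push_back(S.ekin());
      f_rg.push_back(S.rgyr());
      next_save++;
      if (next_save <= n_frames) {
        Event nx; nx.t = t0 + next_save * save_interval; nx.seq = S.seq++;
        nx.type = EV_SAVE; nx.i = nx.j = nx.bidx = nx.dir = 0; nx.ci = nx.cj = 0;
        S.q.push(nx);
      }
    }
  }

  for (int i = 0; i < n; ++i) S.advance_bead(i, t_end);
  NumericMatrix posf(n, 3), velf(n, 3);
  for (int i = 0; i < n; ++i) {
    posf(i,0) = S.x[i]; posf(i,1) = S.y[i]; posf(i,2) = S.z[i];
    velf(i,0) = S.vx[i]; velf(i,1) = S.vy[i]; velf(i,2) = S.vz[i];
  }

  return List::create(
    _["time"] = f_time, _["epot"] = f_epot, _["ekin"] = f_ekin, _["rg"] = f_rg,
    _["frames"] = frames,
    _["pos"] = posf, _["vel"] = velf,
    _["n_collisions"] = (double)n_collisions,
    _["epot_tracked"] = S.epot,
    _["epot_scratch"] = S.epot_scratch(),
    _["t_end"] = t_end);
}
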