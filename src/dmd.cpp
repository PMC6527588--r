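// Event-driven discrete molecular dynamics core.
//
// Beads move ballistically between instantaneous events at the boundaries of
// piecewise-constant pair potentials (hard cores, square wells, infinite
// bond wells). Events are kept in a binary heap with lazy invalidation via
// per-bead event counters; pair predictions are restricted to beads in
// neighbouring cells of a linked-cell grid (cell edge >= the largest
// interaction radius), with cell-crossing events keeping the grid current.
// An Andersen-style ghost-collision thermostat resamples single-bead
// velocities from the Maxwell-Boltzmann distribution at rate nu per bead.
//
// Convention at shell boundaries is right-continuous: at exactly r = R the
// pair counts as outside shell R. The per-pair shell index is explicit
// bookkeeping (not re-derived from distances), so potential energy is
// tracked exactly; "healing" zero-time events re-synchronise bookkeeping
// with positions when floating round-off leaves a pair marginally on the
// wrong side of a boundary.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <random>
#include <limits>
using namespace Rcpp;

static const double DINF = std::numeric_limits<double>::infinity();

struct PType {
  int m;                   // number of radii
  bool bonded;
  std::vector<double> rad; // radii, increasing
  std::vector<double> r2;  // squared radii
  std::vector<double> E;   // m+1 shell energies; E[s] for r in (R[s-1], R[s]]
};

// Event kinds for the log (match R side): 1 core bounce, 2 well capture,
// 3 well escape, 4 well bounce, 5 bond reflection, 6 thermostat.
enum { K_CORE = 1, K_CAPT = 2, K_ESC = 3, K_WBOUNCE = 4, K_BONDR = 5, K_THERMO = 6 };

struct Ev {
  double t;
  int i, j;        // beads (j = -1 for non-pair events)
  int kind;        // 0 pair, 1 cell crossing, 2 thermostat
  int bnd, dir;    // pair: boundary index and +1 out / -1 in; cell: axis, dir
  unsigned ci, cj;
};
struct EvCmp { bool operator()(const Ev& a, const Ev& b) const { return a.t > b.t; } };

class Engine {
public:
  int N;
  double box, tnow;
  std::vector<double> x, v, mass;   // N*3, N*3, N
  std::vector<double> tloc;
  std::vector<int> itab;            // N*N type ids (1-based, 0 = none)
  std::vector<PType> types;
  std::vector<signed char> pst;     // per-pair shell index (i<j), -1 = none
  std::vector<unsigned> ctr, cellctr;
  double Upot;
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> heap;
  // cells
  bool use_cells;
  int nc; double cellsz;
  std::vector<int> cellof, head, nxt, prv;
  // thermostat
  double nu, temp;
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;
  // bookkeeping
  std::vector<long> counts;         // by log kind 1..6
  long n_events, n_cell = 0, n_steps = 0, stall_n = 0;
  double stall_t = -1.0;
  int last_cell_bead = -1, last_cell_axis = -1, last_cell_dir = 0;
  bool logging; int max_log;
  std::vector<double> log_t;
  std::vector<int> log_i, log_j, log_kind, log_bnd, log_dir;

  Engine(NumericMatrix X, NumericMatrix V, NumericVector M, double box_,
         IntegerMatrix IT, List TY, double nu_, double temp_,
         unsigned seed, bool logging_, int max_log_)
    : N(X.nrow()), box(box_), tnow(0.0), Upot(0.0), nu(nu_), temp(temp_),
      rng(seed), gauss(0.0, 1.0), counts(7, 0), n_events(0),
      logging(logging_), max_log(max_log_) {
    x.resize(3 * N); v.resize(3 * N); mass.resize(N); tloc.assign(N, 0.0);
    for (int i = 0; i < N; ++i) {
      mass[i] = M[i];
      for (int k = 0; k < 3; ++k) { x[3 * i + k] = X(i, k); v[3 * i + k] = V(i, k); }
    }
    itab.resize((size_t)N * N);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j) itab[(size_t)i * N + j] = IT(i, j);
    types.resize(TY.size());
    double rmax = 0.0;
    for (int t = 0; t < TY.size(); ++t) {
      List rec = TY[t];
      NumericVector rad = rec["radii"], en = rec["energies"];
      PType& P = types[t];
      P.m = rad.size(); P.bonded = as<bool>(rec["bonded"]);
      P.rad.resize(P.m); P.r2.resize(P.m); P.E.resize(P.m + 1);
      for (int k = 0; k < P.m; ++k) {
        P.rad[k] = rad[k];
        P.r2[k] = rad[k] * rad[k];
        if (rad[P.m - 1] > rmax) rmax = rad[P.m - 1];
      }
      for (int k = 0; k <= P.m; ++k) P.E[k] = en[k];
    }
    ctr.assign(N, 0u); cellctr.assign(N, 0u);
    // cells
    nc = (int)std::floor(box / rmax);
    use_cells = nc >= 4;
    if (use_cells) {
      cellsz = box / nc;
      cellof.assign(N, 0);
      head.assign((size_t)nc * nc * nc, -1);
      nxt.assign(N, -1); prv.assign(N, -1);
      for (int i = 0; i < N; ++i) cell_insert(i, cell_of_pos(i));
    }
    init_pair_states();
  }

  inline double wrapc(double a) const { return a - box * std::floor(a / box); }
  inline double mic(double d) const { return d - box * std::nearbyint(d / box); }
  inline double posat(int i, int k, double t) const {
    return x[3 * i + k] + v[3 * i + k] * (t - tloc[i]);
  }
  inline void advance_bead(int i, double t) {
    for (int k = 0; k < 3; ++k) x[3 * i + k] = posat(i, k, t);
    tloc[i] = t;
  }
  inline signed char& state(int i, int j) {
    return (i < j) ? pst[(size_t)i * N + j] : pst[(size_t)j * N + i];
  }

  int cell_of_pos(int i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      int ck = (int)(wrapc(posat(i, k, tnow)) / cellsz);
      if (ck >= nc) ck = nc - 1; if (ck < 0) ck = 0;
      c[k] = ck;
    }
    return (c[2] * nc + c[1]) * nc + c[0];
  }
  void cell_insert(int i, int c) {
    cellof[i] = c;
    nxt[i] = head[c]; prv[i] = -1;
    if (head[c] >= 0) prv[head[c]] = i;
    head[c] = i;
  }
  void cell_remove(int i) {
    int c = cellof[i];
    if (prv[i] >= 0) nxt[prv[i]] = nxt[i]; else head[c] = nxt[i];
    if (nxt[i] >= 0) prv[nxt[i]] = prv[i];
  }

  void init_pair_states() {
    pst.assign((size_t)N * N, (signed char)-1);
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        int t = itab[(size_t)i * N + j];
        if (t <= 0) continue;
        const PType& P = types[t - 1];
        double r2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double d = mic(x[3 * j + k] - x[3 * i + k]);
          r2 += d * d;
        }
        int s = 0;
        while (s < P.m && P.r2[s] <= r2) ++s;
        if (!std::isfinite(P.E[s]))
          stop("invalid initial state: pair (%d,%d) at r=%f nm violates its potential",
               i + 1, j + 1, std::sqrt(r2));
        pst[(size_t)i * N + j] = (signed char)s;
        Upot += P.E[s];
      }
    }
  }

  double kinetic() const {
    double ke = 0.0;
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += v[3 * i + k] * v[3 * i + k];
      ke += 0.5 * mass[i] * s;
    }
    return ke;
  }

  // ---- predictions -------------------------------------------------------
  void predict_pair(int a, int b) {
    int i = (a < b) ? a : b, j = (a < b) ? b : a;
    int t = itab[(size_t)i * N + j];
    if (t <= 0) return;
    const PType& P = types[t - 1];
    int s = pst[(size_t)i * N + j];
    double dx[3], dv[3];
    for (int k = 0; k < 3; ++k) {
      dx[k] = mic(posat(j, k, tnow) - posat(i, k, tnow));
      dv[k] = v[3 * j + k] - v[3 * i + k];
    }
    double r2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
    double b2 = dx[0] * dv[0] + dx[1] * dv[1] + dx[2] * dv[2];
    double v2 = dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2];
    double tbest = DINF; int bbest = -1, dbest = 0;
    if (s >= 1) {                       // inward boundary R[s-1]
      double c = r2 - P.r2[s - 1];
      if (c <= 0.0) {                   // at or (by round-off) below it
        if (b2 < 0.0) { tbest = 0.0; bbest = s - 1; dbest = -1; }
      } else if (b2 < 0.0 && v2 > 0.0) {
        double disc = b2 * b2 - v2 * c;
        if (disc > 0.0) {
          double tt = (-b2 - std::sqrt(disc)) / v2;
          if (tt < tbest) { tbest = tt; bbest = s - 1; dbest = -1; }
        }
      }
    }
    if (s < P.m && v2 > 0.0) {          // outward boundary R[s]
      double c = r2 - P.r2[s];
      double tt;
      if (c > 0.0 && b2 >= 0.0) tt = 0.0;   // outside moving out: immediate
      else {
        double disc = b2 * b2 - v2 * c;     // >= b2^2 when c <= 0
        // c > 0, b < 0, disc <= 0 would strand the pair outside its
        // bookkept shell forever (a grazing-bounce round-off artefact);
        // resolve immediately -- the resolution snaps it back onto the
        // boundary
        tt = (disc > 0.0) ? (-b2 + std::sqrt(disc)) / v2 : 0.0;
      }
      if (tt < tbest) { tbest = tt; bbest = s; dbest = +1; }
    }
    // Without cell lists nothing re-examines a receding pair, yet on the
    // torus it re-approaches through a neighbouring image: the prediction
    // is only valid while the minimal-image frame holds, so cap it there
    // and schedule a re-prediction. (In cells mode the cell-crossing
    // events already refresh predictions before the image can change.)
    if (!use_cells) {
      double timg = DINF;
      // the lower clamp is relative to the clock so tnow + timg always
      // advances past tnow (an absolute epsilon freezes time once it is
      // below one ulp of tnow)
      double tmin_adv = 1e-12 + 1e-14 * tnow;
      for (int k = 0; k < 3; ++k) {
        if (dv[k] == 0.0) continue;
        double tt = ((dv[k] > 0.0 ? box / 2.0 : -box / 2.0) - dx[k]) / dv[k];
        if (tt < tmin_adv) tt = tmin_adv;
        if (tt < timg) timg = tt;
      }
      if (!(bbest >= 0 && tbest <= timg)) {
        if (timg < DINF)
          push_ev(Ev{tnow + timg, i, j, 3, 0, 0, ctr[i], ctr[j]});
        return;
      }
    }
    if (bbest >= 0)
      push_ev(Ev{tnow + tbest, i, j, 0, bbest, dbest, ctr[i], ctr[j]});
  }

  void predict_cell_cross(int i) {
    if (!use_cells) return;
    int c = cellof[i];
    int cx = c % nc, cy = (c / nc) % nc, cz = c / (nc * nc);
    int cc[3] = {cx, cy, cz};
    double tbest = DINF; int axis = -1, dir = 0;
    for (int k = 0; k < 3; ++k) {
      double vk = v[3 * i + k];
      if (vk == 0.0) continue;
      // displacement from the cell's lower bound, reduced to (-box/2, box/2]
      // so that a bead sitting exactly on a periodic image of a boundary is
      // still referred to its own cell (a naive wrapped coordinate makes a
      // bead at the box edge appear below every cell and cycles forever)
      double w = wrapc(posat(i, k, tnow));
      double d = w - cc[k] * cellsz;
      d -= box * std::floor(d / box + 0.5);
      double tt;
      int dd;
      if (vk > 0.0) {
        double rem = cellsz - d;
        if (rem < 0.0) rem = 0.0;
        tt = rem / vk; dd = +1;
      } else {
        double rem = d;
        if (rem < 0.0) rem = 0.0;
        tt = rem / (-vk); dd = -1;
      }
      if (tt < tbest) { tbest = tt; axis = k; dir = dd; }
    }
    if (axis >= 0)
      push_ev(Ev{tnow + tbest, i, -1, 1, axis, dir, ctr[i], cellctr[i]});
  }

  void scan_bead(int i) {              // all partners of i (after velocity change)
    if (use_cells) {
      int c = cellof[i];
      int cx = c % nc, cy = (c / nc) % nc, cz = c / (nc * nc);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dxk = -1; dxk <= 1; ++dxk) {
            int ux = (cx + dxk + nc) % nc, uy = (cy + dy + nc) % nc,
                uz = (cz + dz + nc) % nc;
            for (int j = head[(uz * nc + uy) * nc + ux]; j >= 0; j = nxt[j])
              if (j != i) predict_pair(i, j);
          }
    } else {
      for (int j = 0; j < N; ++j) if (j != i) predict_pair(i, j);
    }
    predict_cell_cross(i);
  }

  void init_predictions() {
    if (use_cells) {
      for (int i = 0; i < N; ++i) {
        int c = cellof[i];
        int cx = c % nc, cy = (c / nc) % nc, cz = c / (nc * nc);
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dxk = -1; dxk <= 1; ++dxk) {
              int ux = (cx + dxk + nc) % nc, uy = (cy + dy + nc) % nc,
                  uz = (cz + dz + nc) % nc;
              for (int j = head[(uz * nc + uy) * nc + ux]; j >= 0; j = nxt[j])
                if (j > i) predict_pair(i, j);
            }
        predict_cell_cross(i);
      }
    } else {
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) predict_pair(i, j);
    }
  }

  // ---- resolutions -------------------------------------------------------
  inline void push_ev(const Ev& e) {
    if (!(e.t >= tnow - 1e-9) || e.t != e.t)
      stop("internal error: bad event time %g (now %g) kind %d pair %d,%d",
           e.t, tnow, e.kind, e.i + 1, e.j + 1);
    heap.push(e);
  }

  void log_event(double t, int i, int j, int kind, int bnd) {
    ++counts[kind];
    ++n_events;
    if (logging && (int)log_t.size() < max_log) {
      log_t.push_back(t); log_i.push_back(i + 1); log_j.push_back(j + 1);
      log_kind.push_back(kind); log_bnd.push_back(bnd);
    }
  }

  void resolve_pair(const Ev& e) {
    int i = e.i, j = e.j;
    advance_bead(i, e.t); advance_bead(j, e.t);
    const PType& P = types[itab[(size_t)i * N + j] - 1];
    double dx[3], dv[3];
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      dx[k] = mic(x[3 * j + k] - x[3 * i + k]);
      dv[k] = v[3 * j + k] - v[3 * i + k];
      r2 += dx[k] * dx[k];
    }
    double rr = std::sqrt(r2);
    // snap the separation exactly onto the boundary radius: removes the
    // round-off drift that would otherwise leave the pair marginally on the
    // wrong side of the shell it just touched
    double Rb = P.rad[e.bnd];
    double factor = Rb / rr;
    for (int k = 0; k < 3; ++k) {
      x[3 * j + k] += dx[k] * (factor - 1.0);
      dx[k] = dx[k] * factor;
    }
    rr = Rb;
    double nv[3] = {dx[0] / rr, dx[1] / rr, dx[2] / rr};
    double vr = dv[0] * nv[0] + dv[1] * nv[1] + dv[2] * nv[2];
    double mi = mass[i], mj = mass[j], mu = mi * mj / (mi + mj);
    int from = (e.dir > 0) ? e.bnd : e.bnd + 1;
    int to   = (e.dir > 0) ? e.bnd + 1 : e.bnd;
    double vrp; int kindlog;
    if (!std::isfinite(P.E[to])) {            // infinite wall: reflect
      vrp = -vr;
      kindlog = P.bonded ? K_BONDR : K_CORE;
    } else {
      double dU = P.E[to] - P.E[from];
      double q = vr * vr - 2.0 * dU / mu;
      if (q > 0.0) {                          // cross the boundary
        vrp = (e.dir > 0 ? 1.0 : -1.0) * std::sqrt(q);
        state(i, j) = (signed char)to;
        Upot += dU;
        kindlog = (e.dir > 0) ? K_ESC : K_CAPT;
      } else {                                // insufficient radial KE
        vrp = -vr;
        kindlog = K_WBOUNCE;
      }
    }
    double dvr = vrp - vr;
    for (int k = 0; k < 3; ++k) {
      v[3 * i + k] -= (mu / mi) * dvr * nv[k];
      v[3 * j + k] += (mu / mj) * dvr * nv[k];
    }
    ++ctr[i]; ++ctr[j];
    log_event(e.t, i, j, kindlog, e.bnd);
    scan_bead(i); scan_bead(j);
  }

  void resolve_cell(const Ev& e) {
    int i = e.i;
    last_cell_bead = i; last_cell_axis = e.bnd; last_cell_dir = e.dir;
    advance_bead(i, e.t);
    int c = cellof[i];
    int cc[3] = {c % nc, (c / nc) % nc, c / (nc * nc)};
    cc[e.bnd] = (cc[e.bnd] + e.dir + nc) % nc;
    cell_remove(i);
    cell_insert(i, (cc[2] * nc + cc[1]) * nc + cc[0]);
    ++cellctr[i];
    // newly adjacent layer: coordinate along the crossing axis
    int la = (cc[e.bnd] + e.dir + nc) % nc;
    int a1 = (e.bnd + 1) % 3, a2 = (e.bnd + 2) % 3;
    for (int d1 = -1; d1 <= 1; ++d1)
      for (int d2 = -1; d2 <= 1; ++d2) {
        int u[3];
        u[e.bnd] = la;
        u[a1] = (cc[a1] + d1 + nc) % nc;
        u[a2] = (cc[a2] + d2 + nc) % nc;
        for (int j = head[(u[2] * nc + u[1]) * nc + u[0]]; j >= 0; j = nxt[j])
          if (j != i) predict_pair(i, j);
      }
    predict_cell_cross(i);
  }

  void resolve_thermo(const Ev& e) {
    std::uniform_int_distribution<int> pick(0, N - 1);
    int i = pick(rng);
    advance_bead(i, e.t);
    double sd = std::sqrt(temp / mass[i]);
    for (int k = 0; k < 3; ++k) v[3 * i + k] = sd * gauss(rng);
    ++ctr[i];
    log_event(e.t, i, -1, K_THERMO, -1);
    scan_bead(i);
    schedule_thermo();
  }

  void schedule_thermo() {
    if (nu <= 0.0) return;
    std::exponential_distribution<double> ex(nu * N);
    push_ev(Ev{tnow + ex(rng), -1, -1, 2, 0, 0, 0u, 0u});
  }

  void compact_heap() {
    std::vector<Ev> keep;
    keep.reserve(heap.size() / 4 + 64);
    while (!heap.empty()) {
      const Ev& e = heap.top();
      bool ok = (e.kind == 2) ||
        ((e.kind == 0 || e.kind == 3) && e.ci == ctr[e.i] && e.cj == ctr[e.j]) ||
        (e.kind == 1 && e.ci == ctr[e.i] && e.cj == cellctr[e.i]);
      if (ok) keep.push_back(e);
      heap.pop();
    }
    for (const Ev& e : keep) heap.push(e);
  }

  // ---- main loop ---------------------------------------------------------
  List run(double t_end, double dt_sample) {
    init_predictions();
    schedule_thermo();
    int nframes = (dt_sample > 0.0) ? (int)std::floor(t_end / dt_sample + 1e-9) : 0;
    NumericVector f_t(nframes), f_pot(nframes), f_kin(nframes);
    NumericVector frames((size_t)nframes * N * 3);
    int fidx = 0;
    double next_sample = (nframes > 0) ? dt_sample : DINF;
    size_t heap_cap = std::max((size_t)40 * N + 4096, (size_t)1 << 20);
    while (true) {
      if (heap.size() > heap_cap) { compact_heap(); heap_cap = std::max(heap.size() * 4, heap_cap); }
      double tev = heap.empty() ? DINF : heap.top().t;
      double tstop = std::min(next_sample, t_end);
      if (tev > tstop) {
        if (tstop >= t_end && next_sample > t_end) break;
        // record a frame at next_sample (virtual propagation)
        tnow = next_sample;
        f_t[fidx] = next_sample;
        f_pot[fidx] = Upot;
        double ke = kinetic();
        f_kin[fidx] = ke;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < 3; ++k)
            frames[(size_t)fidx * N * 3 + (size_t)k * N + i] = posat(i, k, next_sample);
        ++fidx;
        next_sample = (fidx < nframes) ? dt_sample * (fidx + 1) : DINF;
        if (fidx >= nframes && next_sample > t_end && t_end <= tnow) break;
        continue;
      }
      Ev e = heap.top(); heap.pop();
      if (e.kind != 2 && (e.i < 0 || e.i >= N || (e.kind != 1 && (e.j < 0 || e.j >= N))))
        stop("internal error: malformed event kind %d i %d j %d at t=%g",
             e.kind, e.i, e.j, e.t);
      bool ok = (e.kind == 2) ||
        ((e.kind == 0 || e.kind == 3) && e.ci == ctr[e.i] && e.cj == ctr[e.j]) ||
        (e.kind == 1 && e.ci == ctr[e.i] && e.cj == cellctr[e.i]);
      if (!ok) continue;
      tnow = e.t;
      if (e.kind == 0) resolve_pair(e);
      else if (e.kind == 1) { ++n_cell; resolve_cell(e); }
      else if (e.kind == 3) predict_pair(e.i, e.j);   // minimal-image refresh
      else resolve_thermo(e);
      ++n_steps;
      if ((n_steps & 0xFFFF) == 0) {
        Rcpp::checkUserInterrupt();
        if (tnow <= stall_t && n_steps - stall_n > 2000000L)
          stop("engine stalled: %ld steps without time advancing past %.9g "
               "(events %ld, cell crossings %ld, last cell bead %d)",
               (long)(n_steps - stall_n), stall_t, n_events, n_cell,
               last_cell_bead + 1);
        if (tnow > stall_t) { stall_t = tnow; stall_n = n_steps; }
      }
    }
    tnow = t_end;
    for (int i = 0; i < N; ++i) advance_bead(i, t_end);
    NumericMatrix Xo(N, 3), Vo(N, 3);
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) { Xo(i, k) = x[3 * i + k]; Vo(i, k) = v[3 * i + k]; }
    frames.attr("dim") = IntegerVector::create(N, 3, nframes);
    List lg = R_NilValue;
    if (logging)
      lg = List::create(_["t"] = log_t, _["i"] = log_i, _["j"] = log_j,
                        _["kind"] = log_kind, _["bnd"] = log_bnd);
    return List::create(
      _["x"] = Xo, _["v"] = Vo, _["time"] = t_end,
      _["potential"] = Upot, _["kinetic"] = kinetic(),
      _["frames"] = frames, _["frame_times"] = f_t,
      _["frame_potential"] = f_pot, _["frame_kinetic"] = f_kin,
      _["counts"] = NumericVector::create(
        _["core_bounce"] = counts[K_CORE], _["well_capture"] = counts[K_CAPT],
        _["well_escape"] = counts[K_ESC], _["well_bounce"] = counts[K_WBOUNCE],
        _["bond_reflection"] = counts[K_BONDR], _["thermostat"] = counts[K_THERMO]),
      _["n_events"] = (double)n_events, _["n_cell"] = (double)n_cell,
      _["log"] = lg);
  }
};

// [[Rcpp::export]]
List dmd_advance_cpp(NumericMatrix x, NumericMatrix v, NumericVector mass,
                     double box, IntegerMatrix itab, List types,
                     double t_end, double dt_sample,
                     double thermo_rate, double temperature,
                     double seed, bool log_events, int max_log) {
  Engine eng(x, v, mass, box, itab, types, thermo_rate, temperature,
             (unsigned)seed, log_events, max_log);
  return eng.run(t_end, dt_sample);
}
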