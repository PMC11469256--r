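// Discrete-element core: 2D soft frictional discs under Lees-Edwards shear.
// Nondimensional units: L0 = small-element diameter, M0 = small-element mass,
// T0 = sqrt(M0 / kn_ref).
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Mat {
  double kn;    // effective normal stiffness (includes E multiplier)
  double kt;    // effective tangential stiffness
  double mu;    // Coulomb friction coefficient
  double eta;   // normal dashpot [M0/T0]
  double drag;  // background drag toward the affine field [M0/T0]
  int law;      // 0 = linear, 1 = stiffening
  double dmax;  // overlap scale of the stiffening law
};

static Mat mat_from_list(const List& par) {
  Mat M;
  M.kn   = as<double>(par["kn"]);
  M.kt   = as<double>(par["kt"]);
  M.mu   = as<double>(par["mu"]);
  M.eta  = as<double>(par["eta"]);
  M.drag = as<double>(par["drag"]);
  M.law  = as<int>(par["law"]);
  M.dmax = as<double>(par["dmax"]);
  return M;
}

// Minimum image under Lees-Edwards offset; returns the y-image count applied
// to j (branch b = r_i - r_j on input).
static inline int miwrap(double& bx, double& by, double Lx, double Ly, double gLy) {
  int ny = (int) std::nearbyint(by / Ly);
  if (ny != 0) { by -= ny * Ly; bx -= ny * gLy; }
  bx -= Lx * std::nearbyint(bx / Lx);
  return ny;
}

// Elastic normal force; stiffening law diverges as delta -> dmax and is
// clamped near the pole as an integrator guard.
static inline double f_elastic(double delta, const Mat& M, int& warn) {
  if (M.law == 0) return M.kn * delta;
  double xf = delta / M.dmax;
  if (xf >= 0.99) { warn++; return 99.0 * M.kn * M.dmax; }
  return M.kn * delta / (1.0 - xf);
}

struct PairOut {
  double fjx, fjy;  // force on j exerted by i
  double fn, ft, delta, nx, ny, ai, aj, bx, by;
  int nyim;
};

// Frictional contact between unbonded elements. Updates the tangential
// spring xi in place; returns false (and resets xi) when the contact is open.
static inline bool contact_pair(int i, int j,
                                const double* x, const double* y,
                                const double* vx, const double* vy,
                                const double* om, const double* r,
                                double Lx, double Ly, double gamma, double gdot,
                                const Mat& M, double dt, bool upd,
                                double& xi, PairOut& o, int& warn, double& capex) {
  double bx = x[i] - x[j], by = y[i] - y[j];
  int nyim = miwrap(bx, by, Lx, Ly, gamma * Ly);
  double rsum = r[i] + r[j];
  double d2 = bx * bx + by * by;
  if (d2 >= rsum * rsum) { xi = 0.0; return false; }
  double d = std::sqrt(d2);
  double delta = rsum - d;
  double nx = -bx / d, ny = -by / d;     // unit normal, i -> j
  double tx = -ny,     ty = nx;          // tangent (z-hat cross n)
  double vrx = vx[j] + nyim * gdot * Ly - vx[i];
  double vry = vy[j] - vy[i];
  double vn = -(vrx * nx + vry * ny);    // approach speed > 0
  double ai = r[i] - 0.5 * delta, aj = r[j] - 0.5 * delta;
  double vt = vrx * tx + vry * ty - (om[i] * ai + om[j] * aj);
  double Fn = f_elastic(delta, M, warn) + M.eta * vn;
  if (Fn < 0.0) Fn = 0.0;                // no tensile contact force
  double ft = 0.0;
  if (M.mu > 0.0 && M.kt > 0.0) {
    if (upd) xi += vt * dt;
    double ftr = M.kt * xi, fc = M.mu * Fn;
    if (std::fabs(ftr) > fc) { ft = (ftr > 0.0 ? fc : -fc); xi = ft / M.kt; }
    else ft = ftr;
    double ex = std::fabs(ft) - M.mu * Fn;
    if (ex > capex) capex = ex;
  } else {
    xi = 0.0;
  }
  o.fjx = Fn * nx - ft * tx;
  o.fjy = Fn * ny - ft * ty;
  o.fn = Fn; o.ft = ft; o.delta = delta;
  o.nx = nx; o.ny = ny; o.ai = ai; o.aj = aj;
  o.bx = bx; o.by = by; o.nyim = nyim;
  return true;
}

// Permanent bond: central spring active in tension and compression plus the
// pair dashpot. The cross-link also binds the interface tangentially: an
// uncapped tangential spring (no Coulomb slip) models the polymer bridges
// that prevent interfacial sliding at cross-linked contacts.
static inline void bond_pair(int i, int j, double rest, double kb,
                             const double* x, const double* y,
                             const double* vx, const double* vy,
                             const double* om, const double* r,
                             double Lx, double Ly, double gamma, double gdot,
                             const Mat& M, double dt, bool upd,
                             double& xi, PairOut& o) {
  double bx = x[i] - x[j], by = y[i] - y[j];
  int nyim = miwrap(bx, by, Lx, Ly, gamma * Ly);
  double d = std::sqrt(bx * bx + by * by);
  double nx = -bx / d, ny = -by / d;
  double tx = -ny, ty = nx;
  double vrx = vx[j] + nyim * gdot * Ly - vx[i];
  double vry = vy[j] - vy[i];
  double vn = -(vrx * nx + vry * ny);
  double Fb = kb * (rest - d) + M.eta * vn;   // signed, both branches
  double delta = r[i] + r[j] - d;
  double ft = 0.0;
  double ai = r[i] - 0.5 * delta, aj = r[j] - 0.5 * delta;
  if (M.kt > 0.0) {
    double vt = vrx * tx + vry * ty - (om[i] * ai + om[j] * aj);
    if (upd) xi += vt * dt;
    ft = M.kt * xi;
  }
  o.fjx = Fb * nx - ft * tx;
  o.fjy = Fb * ny - ft * ty;
  o.fn = Fb; o.ft = ft; o.delta = delta;
  o.nx = nx; o.ny = ny; o.ai = ai; o.aj = aj;
  o.bx = bx; o.by = by; o.nyim = nyim;
}

// ---------------------------------------------------------------------------
// Simulation container with Verlet neighbor list.
// ---------------------------------------------------------------------------
struct Sim {
  int n;
  std::vector<double> x, y, vx, vy, om, r, m, I;
  double Lx, Ly, gamma;
  Mat M;
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> brest, bk, bxi;
  std::unordered_set<long long> bonded;
  // neighbor list (non-bonded candidates)
  std::vector<int> pi, pj;
  std::vector<double> pxi;
  double skin, rmax;
  std::vector<double> ux0, y0;  // co-deforming reference coords at last build
  double gamma_nl;
  // force output
  std::vector<double> fx, fy, tq;
  double sxx, sxy, syy;  // pairwise virial sums (not yet divided by area)
  double capex;
  int warn;

  long long key(int i, int j) const {
    int a = i < j ? i : j, b = i < j ? j : i;
    return (long long) a * (long long) n + b;
  }

  void init(const NumericMatrix& elem, const NumericMatrix& bondm,
            const List& par, double Lx_, double Ly_, double gamma_) {
    n = elem.nrow();
    x.resize(n); y.resize(n); vx.resize(n); vy.resize(n);
    om.resize(n); r.resize(n); m.resize(n); I.resize(n);
    for (int i = 0; i < n; i++) {
      x[i] = elem(i, 0); y[i] = elem(i, 1);
      vx[i] = elem(i, 2); vy[i] = elem(i, 3);
      om[i] = elem(i, 4); r[i] = elem(i, 5);
      m[i] = elem(i, 6); I[i] = elem(i, 7);
    }
    Lx = Lx_; Ly = Ly_; gamma = gamma_;
    M = mat_from_list(par);
    int nb = bondm.nrow();
    bi.resize(nb); bj.resize(nb); brest.resize(nb); bk.resize(nb);
    bxi.assign(nb, 0.0);
    for (int b = 0; b < nb; b++) {
      bi[b] = (int) bondm(b, 0) - 1;
      bj[b] = (int) bondm(b, 1) - 1;
      brest[b] = bondm(b, 2);
      bk[b] = bondm(b, 3);
      if (bondm.ncol() > 4) bxi[b] = bondm(b, 4);
      bonded.insert(key(bi[b], bj[b]));
    }
    rmax = 0.0;
    for (int i = 0; i < n; i++) if (r[i] > rmax) rmax = r[i];
    skin = 0.6;
    fx.resize(n); fy.resize(n); tq.resize(n);
    ux0.resize(n); y0.resize(n);
    build_nl();
  }

  void build_nl() {
    std::unordered_map<long long, double> old;
    for (size_t k = 0; k < pi.size(); k++)
      if (pxi[k] != 0.0) old[key(pi[k], pj[k])] = pxi[k];
    pi.clear(); pj.clear(); pxi.clear();
    double gLy = gamma * Ly;
    for (int i = 0; i < n; i++) {
      for (int j = i + 1; j < n; j++) {
        if (!bonded.empty() && bonded.count(key(i, j))) continue;
        double bx = x[i] - x[j], by = y[i] - y[j];
        miwrap(bx, by, Lx, Ly, gLy);
        double rc = r[i] + r[j] + skin;
        if (bx * bx + by * by < rc * rc) {
          pi.push_back(i); pj.push_back(j);
          std::unordered_map<long long, double>::iterator it = old.find(key(i, j));
          pxi.push_back(it == old.end() ? 0.0 : it->second);
        }
      }
    }
    for (int i = 0; i < n; i++) { ux0[i] = x[i] - gamma * y[i]; y0[i] = y[i]; }
    gamma_nl = gamma;
  }

  bool need_rebuild() const {
    double cutoff = 2.0 * rmax + skin;
    double dg = std::fabs(gamma - gamma_nl);
    double half = 0.5 * (skin * 0.9 - dg * cutoff);
    if (half <= 0.0) return true;
    double h2 = half * half;
    for (int i = 0; i < n; i++) {
      double du = x[i] - gamma * y[i] - ux0[i];
      double dy = y[i] - y0[i];
      if (du * du + dy * dy > h2) return true;
    }
    return false;
  }

  // One force evaluation; updates tangential springs when upd is true.
  void eval(double gdot, double dt, bool upd, bool with_drag) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(tq.begin(), tq.end(), 0.0);
    sxx = sxy = syy = 0.0;
    capex = -1e300;
    PairOut o;
    const double* X = x.data(); const double* Y = y.data();
    const double* VX = vx.data(); const double* VY = vy.data();
    const double* OM = om.data(); const double* R = r.data();
    for (size_t k = 0; k < pi.size(); k++) {
      int i = pi[k], j = pj[k];
      if (!contact_pair(i, j, X, Y, VX, VY, OM, R, Lx, Ly, gamma, gdot,
                        M, dt, upd, pxi[k], o, warn, capex)) continue;
      fx[j] += o.fjx; fy[j] += o.fjy;
      fx[i] -= o.fjx; fy[i] -= o.fjy;
      tq[i] += o.ai * o.ft; tq[j] += o.aj * o.ft;
      sxx += o.bx * o.fjx;
      syy += o.by * o.fjy;
      sxy += 0.5 * (o.bx * o.fjy + o.by * o.fjx);
    }
    for (size_t b = 0; b < bi.size(); b++) {
      int i = bi[b], j = bj[b];
      bond_pair(i, j, brest[b], bk[b], X, Y, VX, VY, OM, R,
                Lx, Ly, gamma, gdot, M, dt, upd, bxi[b], o);
      fx[j] += o.fjx; fy[j] += o.fjy;
      fx[i] -= o.fjx; fy[i] -= o.fjy;
      tq[i] += o.ai * o.ft; tq[j] += o.aj * o.ft;
      sxx += o.bx * o.fjx;
      syy += o.by * o.fjy;
      sxy += 0.5 * (o.bx * o.fjy + o.by * o.fjx);
    }
    if (with_drag && M.drag > 0.0) {
      for (int i = 0; i < n; i++) {
        fx[i] -= M.drag * (vx[i] - gdot * (y[i] - 0.5 * Ly));
        fy[i] -= M.drag * vy[i];
        tq[i] -= M.drag * r[i] * r[i] * om[i];
      }
    }
  }

  void wrap(double gdot) {
    for (int i = 0; i < n; i++) {
      if (y[i] >= Ly)      { y[i] -= Ly; x[i] -= gamma * Ly; vx[i] -= gdot * Ly; }
      else if (y[i] < 0.0) { y[i] += Ly; x[i] += gamma * Ly; vx[i] += gdot * Ly; }
      x[i] -= Lx * std::floor(x[i] / Lx);
    }
  }

  bool finite_ok() const {
    double ke = 0.0;
    for (int i = 0; i < n; i++) {
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(vx[i]) || !std::isfinite(vy[i])) return false;
      ke += m[i] * (vx[i] * vx[i] + vy[i] * vy[i]);
    }
    return std::isfinite(ke) && ke < 1e8 * n;
  }

  NumericMatrix state() const {
    NumericMatrix out(n, 8);
    for (int i = 0; i < n; i++) {
      out(i, 0) = x[i]; out(i, 1) = y[i];
      out(i, 2) = vx[i]; out(i, 3) = vy[i];
      out(i, 4) = om[i]; out(i, 5) = r[i];
      out(i, 6) = m[i]; out(i, 7) = I[i];
    }
    return out;
  }

  // Elastic + kinetic energy (linear contact law); used by conservation tests.
  double energy(double gdot) const {
    double e = 0.0;
    for (int i = 0; i < n; i++)
      e += 0.5 * m[i] * (vx[i] * vx[i] + vy[i] * vy[i]) + 0.5 * I[i] * om[i] * om[i];
    double gLy = gamma * Ly;
    for (size_t k = 0; k < pi.size(); k++) {
      int i = pi[k], j = pj[k];
      double bx = x[i] - x[j], by = y[i] - y[j];
      miwrap(bx, by, Lx, Ly, gLy);
      double d = std::sqrt(bx * bx + by * by);
      double delta = r[i] + r[j] - d;
      if (delta > 0.0) e += 0.5 * M.kn * delta * delta;
      e += 0.5 * M.kt * pxi[k] * pxi[k];
    }
    for (size_t b = 0; b < bi.size(); b++) {
      double bx = x[bi[b]] - x[bj[b]], by = y[bi[b]] - y[bj[b]];
      miwrap(bx, by, Lx, Ly, gLy);
      double d = std::sqrt(bx * bx + by * by);
      double s = brest[b] - d;
      e += 0.5 * bk[b] * s * s + 0.5 * M.kt * bxi[b] * bxi[b];
    }
    return e;
  }
};

// ---------------------------------------------------------------------------
// Oscillatory shear run: gamma(t) = gamma_init + gamma0 * sin(w t).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List dem_run(NumericMatrix elem, NumericMatrix bondm, List par,
             double Lx, double Ly, double gamma_init,
             double gamma0, double w, double dt_target,
             int n_cycles, int samples_per_cycle) {
  Sim s;
  s.warn = 0;
  s.init(elem, bondm, par, Lx, Ly, gamma_init);
  int spc = samples_per_cycle *
    (int) std::ceil(2.0 * M_PI / (w * dt_target * samples_per_cycle));
  double dt = 2.0 * M_PI / (w * spc);
  int rec_every = spc / samples_per_cycle;
  int nsteps = n_cycles * spc;
  int nsamp = n_cycles * samples_per_cycle + 1;
  NumericMatrix samples(nsamp, 5);
  double A = Lx * Ly;

  double gdot = gamma0 * w;  // affine initialization at t = 0
  for (int i = 0; i < s.n; i++) s.vx[i] += gdot * (s.y[i] - 0.5 * Ly);

  s.eval(gdot, dt, false, true);
  double cap_max = s.capex;
  int isamp = 0;
  bool ok = true;

  // record helper values
  {
    double kxx = 0, kxy = 0, kyy = 0;
    for (int i = 0; i < s.n; i++) {
      double vpx = s.vx[i] - gdot * (s.y[i] - 0.5 * Ly), vpy = s.vy[i];
      kxx += s.m[i] * vpx * vpx; kxy += s.m[i] * vpx * vpy; kyy += s.m[i] * vpy * vpy;
    }
    samples(0, 0) = 0.0; samples(0, 1) = 0.0;
    samples(0, 2) = (s.sxx + kxx) / A;
    samples(0, 3) = (s.sxy + kxy) / A;
    samples(0, 4) = (s.syy + kyy) / A;
    isamp = 1;
  }

  for (int step = 1; step <= nsteps; step++) {
    double t = step * dt;
    for (int i = 0; i < s.n; i++) {
      s.vx[i] += 0.5 * dt * s.fx[i] / s.m[i];
      s.vy[i] += 0.5 * dt * s.fy[i] / s.m[i];
      s.om[i] += 0.5 * dt * s.tq[i] / s.I[i];
      s.x[i] += s.vx[i] * dt;
      s.y[i] += s.vy[i] * dt;
    }
    double gdot_new = gamma0 * w * std::cos(w * t);
    s.gamma = gamma_init + gamma0 * std::sin(w * t);
    for (int i = 0; i < s.n; i++)
      s.vx[i] += (gdot_new - gdot) * (s.y[i] - 0.5 * Ly);
    gdot = gdot_new;
    s.wrap(gdot);
    if (s.need_rebuild()) s.build_nl();
    s.eval(gdot, dt, true, true);
    if (s.capex > cap_max) cap_max = s.capex;
    for (int i = 0; i < s.n; i++) {
      s.vx[i] += 0.5 * dt * s.fx[i] / s.m[i];
      s.vy[i] += 0.5 * dt * s.fy[i] / s.m[i];
      s.om[i] += 0.5 * dt * s.tq[i] / s.I[i];
    }
    if (step % 32 == 0 && !s.finite_ok()) { ok = false; break; }
    if (step % rec_every == 0) {
      double kxx = 0, kxy = 0, kyy = 0;
      for (int i = 0; i < s.n; i++) {
        double vpx = s.vx[i] - gdot * (s.y[i] - 0.5 * Ly), vpy = s.vy[i];
        kxx += s.m[i] * vpx * vpx; kxy += s.m[i] * vpx * vpy; kyy += s.m[i] * vpy * vpy;
      }
      samples(isamp, 0) = t;
      samples(isamp, 1) = gamma0 * std::sin(w * t);
      samples(isamp, 2) = (s.sxx + kxx) / A;
      samples(isamp, 3) = (s.sxy + kxy) / A;
      samples(isamp, 4) = (s.syy + kyy) / A;
      isamp++;
    }
  }
  if (!ok) {
    NumericMatrix trunc(isamp, 5);
    for (int a = 0; a < isamp; a++)
      for (int b = 0; b < 5; b++) trunc(a, b) = samples(a, b);
    samples = trunc;
  }
  NumericMatrix bxi_out(s.bxi.size(), 1);
  for (size_t b = 0; b < s.bxi.size(); b++) bxi_out(b, 0) = s.bxi[b];
  return List::create(
    _["samples"] = samples,
    _["elem"] = s.state(),
    _["gamma"] = s.gamma,
    _["dt"] = dt,
    _["steps_per_cycle"] = spc,
    _["cap_excess"] = (cap_max == -1e300 ? R_NegInf : cap_max),
    _["stiff_warnings"] = s.warn,
    _["ok"] = ok);
}

// ---------------------------------------------------------------------------
// Free integration (no drive) with optional trajectory/energy recording.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List dem_steps(NumericMatrix elem, NumericMatrix bondm, List par,
               double Lx, double Ly, double gamma,
               int n_steps, double dt, int record_every) {
  Sim s;
  s.warn = 0;
  s.init(elem, bondm, par, Lx, Ly, gamma);
  int nrec = n_steps / record_every + 1;
  NumericMatrix T(nrec, 1), E(nrec, 1);
  NumericMatrix X(nrec, s.n), Y(nrec, s.n), VX(nrec, s.n), VY(nrec, s.n), OMr(nrec, s.n);
  s.eval(0.0, dt, false, true);
  double cap_max = s.capex;
  int ir = 0;
  T(0, 0) = 0.0; E(0, 0) = s.energy(0.0);
  for (int i = 0; i < s.n; i++) {
    X(0, i) = s.x[i]; Y(0, i) = s.y[i];
    VX(0, i) = s.vx[i]; VY(0, i) = s.vy[i]; OMr(0, i) = s.om[i];
  }
  ir = 1;
  bool ok = true;
  for (int step = 1; step <= n_steps; step++) {
    for (int i = 0; i < s.n; i++) {
      s.vx[i] += 0.5 * dt * s.fx[i] / s.m[i];
      s.vy[i] += 0.5 * dt * s.fy[i] / s.m[i];
      s.om[i] += 0.5 * dt * s.tq[i] / s.I[i];
      s.x[i] += s.vx[i] * dt;
      s.y[i] += s.vy[i] * dt;
    }
    s.wrap(0.0);
    if (s.need_rebuild()) s.build_nl();
    s.eval(0.0, dt, true, true);
    if (s.capex > cap_max) cap_max = s.capex;
    for (int i = 0; i < s.n; i++) {
      s.vx[i] += 0.5 * dt * s.fx[i] / s.m[i];
      s.vy[i] += 0.5 * dt * s.fy[i] / s.m[i];
      s.om[i] += 0.5 * dt * s.tq[i] / s.I[i];
    }
    if (step % 64 == 0 && !s.finite_ok()) { ok = false; break; }
    if (step % record_every == 0 && ir < nrec) {
      T(ir, 0) = step * dt; E(ir, 0) = s.energy(0.0);
      for (int i = 0; i < s.n; i++) {
        X(ir, i) = s.x[i]; Y(ir, i) = s.y[i];
        VX(ir, i) = s.vx[i]; VY(ir, i) = s.vy[i]; OMr(ir, i) = s.om[i];
      }
      ir++;
    }
  }
  return List::create(
    _["time"] = T, _["energy"] = E,
    _["X"] = X, _["Y"] = Y, _["VX"] = VX, _["VY"] = VY, _["OM"] = OMr,
    _["elem"] = s.state(),
    _["cap_excess"] = (cap_max == -1e300 ? R_NegInf : cap_max),
    _["ok"] = ok);
}

// ---------------------------------------------------------------------------
// Single force evaluation over exact contacts (brute-force pair search).
// states: matrix (i, j, xi) of tangential springs carried into this call.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List dem_forces(NumericMatrix elem, NumericMatrix bondm, List par,
                double Lx, double Ly, double gamma,
                NumericMatrix states, double dt, double gdot) {
  int n = elem.nrow();
  std::vector<double> x(n), y(n), vx(n), vy(n), om(n), r(n);
  for (int i = 0; i < n; i++) {
    x[i] = elem(i, 0); y[i] = elem(i, 1);
    vx[i] = elem(i, 2); vy[i] = elem(i, 3);
    om[i] = elem(i, 4); r[i] = elem(i, 5);
  }
  Mat M = mat_from_list(par);
  std::unordered_set<long long> bonded;
  for (int b = 0; b < bondm.nrow(); b++) {
    int a = (int) bondm(b, 0) - 1, c = (int) bondm(b, 1) - 1;
    int lo = a < c ? a : c, hi = a < c ? c : a;
    bonded.insert((long long) lo * n + hi);
  }
  std::unordered_map<long long, double> xi_in;
  for (int k = 0; k < states.nrow(); k++) {
    int a = (int) states(k, 0) - 1, c = (int) states(k, 1) - 1;
    int lo = a < c ? a : c, hi = a < c ? c : a;
    xi_in[(long long) lo * n + hi] = states(k, 2);
  }
  std::vector<double> fx(n, 0.0), fy(n, 0.0), tq(n, 0.0);
  double sxx = 0, sxy = 0, syy = 0, capex = -1e300;
  int warn = 0;
  std::vector<int> Pi, Pj;
  std::vector<double> Pfn, Pft, Pd, Pnx, Pny, Pfjx, Pfjy, Pxi;
  std::vector<int> Pbond;
  PairOut o;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      if (bonded.count((long long) i * n + j)) continue;
      double xi = 0.0;
      std::unordered_map<long long, double>::iterator it =
        xi_in.find((long long) i * n + j);
      if (it != xi_in.end()) xi = it->second;
      if (!contact_pair(i, j, x.data(), y.data(), vx.data(), vy.data(),
                        om.data(), r.data(), Lx, Ly, gamma, gdot,
                        M, dt, true, xi, o, warn, capex)) continue;
      fx[j] += o.fjx; fy[j] += o.fjy; fx[i] -= o.fjx; fy[i] -= o.fjy;
      tq[i] += o.ai * o.ft; tq[j] += o.aj * o.ft;
      sxx += o.bx * o.fjx; syy += o.by * o.fjy;
      sxy += 0.5 * (o.bx * o.fjy + o.by * o.fjx);
      Pi.push_back(i + 1); Pj.push_back(j + 1);
      Pfn.push_back(o.fn); Pft.push_back(o.ft); Pd.push_back(o.delta);
      Pnx.push_back(o.nx); Pny.push_back(o.ny);
      Pfjx.push_back(o.fjx); Pfjy.push_back(o.fjy);
      Pxi.push_back(xi); Pbond.push_back(0);
    }
  }
  for (int b = 0; b < bondm.nrow(); b++) {
    int i = (int) bondm(b, 0) - 1, j = (int) bondm(b, 1) - 1;
    double xi = bondm.ncol() > 4 ? bondm(b, 4) : 0.0;
    bond_pair(i, j, bondm(b, 2), bondm(b, 3), x.data(), y.data(),
              vx.data(), vy.data(), om.data(), r.data(),
              Lx, Ly, gamma, gdot, M, dt, true, xi, o);
    fx[j] += o.fjx; fy[j] += o.fjy; fx[i] -= o.fjx; fy[i] -= o.fjy;
    tq[i] += o.ai * o.ft; tq[j] += o.aj * o.ft;
    sxx += o.bx * o.fjx; syy += o.by * o.fjy;
    sxy += 0.5 * (o.bx * o.fjy + o.by * o.fjx);
    Pi.push_back(i + 1); Pj.push_back(j + 1);
    Pfn.push_back(o.fn); Pft.push_back(o.ft); Pd.push_back(o.delta);
    Pnx.push_back(o.nx); Pny.push_back(o.ny);
    Pfjx.push_back(o.fjx); Pfjy.push_back(o.fjy);
    Pxi.push_back(xi); Pbond.push_back(1);
  }
  int np = Pi.size();
  NumericMatrix pairs(np, 11);
  for (int k = 0; k < np; k++) {
    pairs(k, 0) = Pi[k]; pairs(k, 1) = Pj[k]; pairs(k, 2) = Pd[k];
    pairs(k, 3) = Pnx[k]; pairs(k, 4) = Pny[k]; pairs(k, 5) = Pfn[k];
    pairs(k, 6) = Pft[k]; pairs(k, 7) = Pfjx[k]; pairs(k, 8) = Pfjy[k];
    pairs(k, 9) = Pxi[k]; pairs(k, 10) = Pbond[k];
  }
  NumericMatrix F(n, 2);
  NumericVector TQ(n);
  for (int i = 0; i < n; i++) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; TQ[i] = tq[i]; }
  double A = Lx * Ly;
  NumericMatrix sig(2, 2);
  sig(0, 0) = sxx / A; sig(1, 1) = syy / A;
  sig(0, 1) = sxy / A; sig(1, 0) = sxy / A;
  return List::create(
    _["force"] = F, _["torque"] = TQ, _["pairs"] = pairs,
    _["sigma_pairs"] = sig,
    _["cap_excess"] = (capex == -1e300 ? R_NegInf : capex),
    _["stiff_warnings"] = warn);
}

// ---------------------------------------------------------------------------
// Exact contact list (brute force, min image under shear).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix dem_contacts(NumericVector x, NumericVector y, NumericVector r,
                           double Lx, double Ly, double gamma) {
  int n = x.size();
  std::vector<double> ci, cj, cd, cnx, cny, cdist;
  double gLy = gamma * Ly;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double bx = x[i] - x[j], by = y[i] - y[j];
      miwrap(bx, by, Lx, Ly, gLy);
      double rsum = r[i] + r[j];
      double d2 = bx * bx + by * by;
      if (d2 >= rsum * rsum) continue;
      double d = std::sqrt(d2);
      ci.push_back(i + 1); cj.push_back(j + 1);
      cd.push_back(rsum - d);
      cnx.push_back(-bx / d); cny.push_back(-by / d);
      cdist.push_back(d);
    }
  }
  NumericMatrix out(ci.size(), 6);
  for (size_t k = 0; k < ci.size(); k++) {
    out(k, 0) = ci[k]; out(k, 1) = cj[k]; out(k, 2) = cd[k];
    out(k, 3) = cnx[k]; out(k, 4) = cny[k]; out(k, 5) = cdist[k];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Packing protocol: isotropic shrink in stages with FIRE relaxation
// (frictionless linear contacts, unit masses). Deterministic.
// ---------------------------------------------------------------------------
struct PackNL {
  std::vector<int> pi, pj;
  std::vector<double> x0, y0;
};

static void pack_build(PackNL& nl, const std::vector<double>& x,
                       const std::vector<double>& y, const std::vector<double>& r,
                       double Lx, double Ly, double skin) {
  int n = x.size();
  nl.pi.clear(); nl.pj.clear();
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double bx = x[i] - x[j], by = y[i] - y[j];
      miwrap(bx, by, Lx, Ly, 0.0);
      double rc = r[i] + r[j] + skin;
      if (bx * bx + by * by < rc * rc) { nl.pi.push_back(i); nl.pj.push_back(j); }
    }
  }
  nl.x0 = x; nl.y0 = y;
}

static double pack_forces(const PackNL& nl, const std::vector<double>& x,
                          const std::vector<double>& y, const std::vector<double>& r,
                          double Lx, double Ly, double kn,
                          std::vector<double>& fx, std::vector<double>& fy) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  for (size_t k = 0; k < nl.pi.size(); k++) {
    int i = nl.pi[k], j = nl.pj[k];
    double bx = x[i] - x[j], by = y[i] - y[j];
    miwrap(bx, by, Lx, Ly, 0.0);
    double rsum = r[i] + r[j];
    double d2 = bx * bx + by * by;
    if (d2 >= rsum * rsum) continue;
    double d = std::sqrt(d2);
    double f = kn * (rsum - d) / d;  // along b, pushes i away from j
    fx[i] += f * bx; fy[i] += f * by;
    fx[j] -= f * bx; fy[j] -= f * by;
  }
  double fmax2 = 0.0;
  for (size_t i = 0; i < fx.size(); i++) {
    double f2 = fx[i] * fx[i] + fy[i] * fy[i];
    if (f2 > fmax2) fmax2 = f2;
  }
  return std::sqrt(fmax2);
}

// [[Rcpp::export]]
List dem_pack(NumericVector x0, NumericVector y0, NumericVector rad,
              double Lx0, double Ly0, double phi_target,
              double kn, double stage_ratio, int max_iter_stage,
              int max_iter_final, double tol_stage, double tol_final) {
  int n = x0.size();
  std::vector<double> x(n), y(n), r(n);
  double area_el = 0.0;
  for (int i = 0; i < n; i++) {
    x[i] = x0[i]; y[i] = y0[i]; r[i] = rad[i];
    area_el += M_PI * r[i] * r[i];
  }
  double Lx = Lx0, Ly = Ly0;
  double skin = 0.5;
  std::vector<double> vx(n, 0.0), vy(n, 0.0), fx(n), fy(n);
  PackNL nl;
  double dt0 = 0.1 / std::sqrt(kn), dtmax = 10.0 * dt0;

  bool done_shrink = false;
  long total_iters = 0;
  double fmax = 0.0;
  while (true) {
    double phi = area_el / (Lx * Ly);
    bool final_stage = false;
    if (!done_shrink) {
      double phi_next = phi * stage_ratio;
      if (phi_next >= phi_target) { phi_next = phi_target; done_shrink = true; }
      double sc = std::sqrt(phi / phi_next);
      Lx *= sc; Ly *= sc;
      for (int i = 0; i < n; i++) { x[i] *= sc; y[i] *= sc; }
      final_stage = done_shrink;
    } else {
      break;
    }
    // FIRE relaxation
    pack_build(nl, x, y, r, Lx, Ly, skin);
    std::fill(vx.begin(), vx.end(), 0.0);
    std::fill(vy.begin(), vy.end(), 0.0);
    double dt = dt0, alpha = 0.1;
    int npos = 0;
    int maxit = final_stage ? max_iter_final : max_iter_stage;
    double tol = final_stage ? tol_final : tol_stage;
    fmax = pack_forces(nl, x, y, r, Lx, Ly, kn, fx, fy);
    for (int it = 0; it < maxit && fmax > tol; it++) {
      double P = 0.0, vnorm = 0.0, fnorm = 0.0;
      for (int i = 0; i < n; i++) {
        P += fx[i] * vx[i] + fy[i] * vy[i];
        vnorm += vx[i] * vx[i] + vy[i] * vy[i];
        fnorm += fx[i] * fx[i] + fy[i] * fy[i];
      }
      vnorm = std::sqrt(vnorm); fnorm = std::sqrt(fnorm);
      if (P > 0.0) {
        npos++;
        if (npos > 5) { dt = std::min(dt * 1.1, dtmax); alpha *= 0.99; }
      } else {
        npos = 0; dt *= 0.5; alpha = 0.1;
        std::fill(vx.begin(), vx.end(), 0.0);
        std::fill(vy.begin(), vy.end(), 0.0);
      }
      double mix = (fnorm > 0.0 ? alpha * vnorm / fnorm : 0.0);
      double v2max = 0.0;
      for (int i = 0; i < n; i++) {
        vx[i] += fx[i] * dt;
        vy[i] += fy[i] * dt;
        vx[i] = (1.0 - alpha) * vx[i] + mix * fx[i];
        vy[i] = (1.0 - alpha) * vy[i] + mix * fy[i];
        double v2 = vx[i] * vx[i] + vy[i] * vy[i];
        if (v2 > v2max) v2max = v2;
      }
      // cap per-iteration displacement at a fraction of the skin
      double step_cap = 0.12, fcap2 = 1.0;
      double dmaxstep = std::sqrt(v2max) * dt;
      if (dmaxstep > step_cap) fcap2 = step_cap / dmaxstep;
      for (int i = 0; i < n; i++) {
        x[i] += vx[i] * dt * fcap2;
        y[i] += vy[i] * dt * fcap2;
        y[i] -= Ly * std::floor(y[i] / Ly);
        x[i] -= Lx * std::floor(x[i] / Lx);
      }
      // rebuild when accumulated motion could invalidate the list
      double dmax2 = 0.0;
      for (int i = 0; i < n; i++) {
        double du = x[i] - nl.x0[i], dv = y[i] - nl.y0[i];
        du -= Lx * std::nearbyint(du / Lx);
        dv -= Ly * std::nearbyint(dv / Ly);
        double d2 = du * du + dv * dv;
        if (d2 > dmax2) dmax2 = d2;
      }
      if (2.0 * std::sqrt(dmax2) > 0.85 * skin)
        pack_build(nl, x, y, r, Lx, Ly, skin);
      fmax = pack_forces(nl, x, y, r, Lx, Ly, kn, fx, fy);
      total_iters++;
    }
  }
  NumericVector xo(n), yo(n);
  for (int i = 0; i < n; i++) { xo[i] = x[i]; yo[i] = y[i]; }
  return List::create(
    _["x"] = xo, _["y"] = yo, _["Lx"] = Lx, _["Ly"] = Ly,
    _["fmax"] = fmax, _["iterations"] = (double) total_iters);
}
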