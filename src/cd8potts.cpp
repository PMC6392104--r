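// Compiled core of the cd8potts simulator.
//
// Layout:
//   - molecular network RHS + RK4 stepper (per-cell ODE system)
//   - IL2 reaction-diffusion field (FTCS, periodic, subcycled)
//   - Cellular Potts lattice: Hamiltonian, incremental copy attempts, MCS
//   - cell rules: cycle, partitioning, differentiation, apoptosis
//   - the full coupled simulation loop (cpp_run_simulation)
//
// All randomness goes through R's RNG (unif_rand) so set.seed() gives
// bit-exact reproducibility across the whole engine.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// cell type codes (shared with R/params.R)
// ---------------------------------------------------------------------------
enum CellType { MEDIUM = 0, APC = 1, NAIVE = 2, PREACT = 3, ACT = 4, EFF = 5, MEM = 6 };
static const int NTYPES = 7;

// ---------------------------------------------------------------------------
// molecular network
// ---------------------------------------------------------------------------
struct MolParams {
  double lam_R1, lam_R2, lam_E1, k_R, mu_IL2_plus, mu_IL2_minus, k_e;
  double lam_T1, lam_T2, lam_T3, n, k_T;
  double mu_F_plus, mu_F_minus, lam_F, k_F;
  double lam_c1, lam_c2, lam_c3, lam_c4, lam_E2, k_c;
  double lam_E3, lam_E4, lam_E5, lam_E6, lam_E7, k_E;
  int fas_cap_product; // 0: cap = lam_F / k_F (default); 1: cap = lam_F * k_F
};

static double getp(const List& p, const char* nm) {
  if (!p.containsElementNamed(nm)) stop("missing molecular parameter '%s'", nm);
  return as<double>(p[nm]);
}

static MolParams read_mol_params(const List& p) {
  MolParams m;
  m.lam_R1 = getp(p, "lam_R1"); m.lam_R2 = getp(p, "lam_R2");
  m.lam_E1 = getp(p, "lam_E1"); m.k_R = getp(p, "k_R");
  m.mu_IL2_plus = getp(p, "mu_IL2_plus"); m.mu_IL2_minus = getp(p, "mu_IL2_minus");
  m.k_e = getp(p, "k_e");
  m.lam_T1 = getp(p, "lam_T1"); m.lam_T2 = getp(p, "lam_T2");
  m.lam_T3 = getp(p, "lam_T3"); m.n = getp(p, "n"); m.k_T = getp(p, "k_T");
  m.mu_F_plus = getp(p, "mu_F_plus"); m.mu_F_minus = getp(p, "mu_F_minus");
  m.lam_F = getp(p, "lam_F"); m.k_F = getp(p, "k_F");
  m.lam_c1 = getp(p, "lam_c1"); m.lam_c2 = getp(p, "lam_c2");
  m.lam_c3 = getp(p, "lam_c3"); m.lam_c4 = getp(p, "lam_c4");
  m.lam_E2 = getp(p, "lam_E2"); m.k_c = getp(p, "k_c");
  m.lam_E3 = getp(p, "lam_E3"); m.lam_E4 = getp(p, "lam_E4");
  m.lam_E5 = getp(p, "lam_E5"); m.lam_E6 = getp(p, "lam_E6");
  m.lam_E7 = getp(p, "lam_E7"); m.k_E = getp(p, "k_E");
  m.fas_cap_product = p.containsElementNamed("fas_cap_mode") &&
    as<std::string>(p["fas_cap_mode"]) == "product" ? 1 : 0;
  return m;
}

struct Env {
  double fAPC, G, H, IL2cm, Tbcm;
};

// d/dt of (R, LR, Tb, Fs, Cas, E)
static void mol_rhs(const double* x, const Env& e, const MolParams& p, double* dx) {
  const double R = x[0], LR = x[1], Tb = x[2], Fs = x[3], Cas = x[4], E = x[5];
  dx[0] = p.lam_R1 * e.fAPC + (p.mu_IL2_minus + p.lam_R2) * LR + p.lam_E1 * E -
          (p.mu_IL2_plus * e.IL2cm + p.k_R) * R;
  dx[1] = p.mu_IL2_plus * e.IL2cm * R - p.mu_IL2_minus * LR - p.k_e * LR;
  const double Tbn = (Tb > 0.0) ? std::pow(Tb, p.n) : 0.0;
  dx[2] = p.lam_T1 * e.fAPC + p.lam_T2 * Tbn / (std::pow(p.lam_T3, p.n) + Tbn) -
          p.k_T * Tb;
  const double fcap = p.fas_cap_product ? p.lam_F * p.k_F : p.lam_F / p.k_F;
  dx[3] = e.H * p.mu_F_plus * e.Tbcm * (fcap - Fs) - p.mu_F_minus * Fs - p.k_F * Fs;
  dx[4] = e.G * p.lam_c1 / ((1.0 + p.lam_c2 * LR) * (1.0 + p.lam_c3 * e.fAPC) *
                            (1.0 + p.lam_E2 * E)) +
          p.lam_c4 * Fs - p.k_c * Cas;
  dx[5] = 1.0 / (1.0 + p.lam_E5 * e.fAPC) *
          (p.lam_E3 * LR / (p.lam_E6 + LR) + e.G * p.lam_E4 / (1.0 + p.lam_E7 * Tb)) -
          p.k_E * E;
}

// one classical RK4 step of size h (no clipping)
static void rk4_once(double* x, const Env& e, const MolParams& p, double h) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  mol_rhs(x, e, p, k1);
  for (int i = 0; i < 6; ++i) tmp[i] = x[i] + 0.5 * h * k1[i];
  mol_rhs(tmp, e, p, k2);
  for (int i = 0; i < 6; ++i) tmp[i] = x[i] + 0.5 * h * k2[i];
  mol_rhs(tmp, e, p, k3);
  for (int i = 0; i < 6; ++i) tmp[i] = x[i] + h * k3[i];
  mol_rhs(tmp, e, p, k4);
  for (int i = 0; i < 6; ++i)
    x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// RK4 over dt; if any variable moves by >20% of max(|x|, 1) in the single
// step, redo with 10 substeps. Negative undershoots clipped to 0 (counted).
static void step_mol(double* x, const Env& e, const MolParams& p, double dt,
                     long& clipped, long& steps) {
  double trial[6];
  for (int i = 0; i < 6; ++i) trial[i] = x[i];
  rk4_once(trial, e, p, dt);
  bool big = false;
  for (int i = 0; i < 6; ++i) {
    double ref = std::max(std::fabs(x[i]), 1.0);
    if (std::fabs(trial[i] - x[i]) > 0.2 * ref) { big = true; break; }
  }
  if (big) {
    for (int i = 0; i < 6; ++i) trial[i] = x[i];
    for (int s = 0; s < 10; ++s) rk4_once(trial, e, p, dt / 10.0);
  }
  ++steps;
  for (int i = 0; i < 6; ++i) {
    if (!R_finite(trial[i]))
      stop("numerical blow-up in molecular variable %d (value %g)", i + 1, trial[i]);
    if (trial[i] < 0.0) { trial[i] = 0.0; ++clipped; }
    x[i] = trial[i];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_molecular_rhs(NumericMatrix state, NumericMatrix env, List params) {
  MolParams p = read_mol_params(params);
  int nr = state.nrow();
  NumericMatrix out(nr, 6);
  for (int r = 0; r < nr; ++r) {
    double x[6], dx[6];
    for (int i = 0; i < 6; ++i) x[i] = state(r, i);
    Env e{env(r, 0), env(r, 1), env(r, 2), env(r, 3), env(r, 4)};
    mol_rhs(x, e, p, dx);
    for (int i = 0; i < 6; ++i) out(r, i) = dx[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_step_molecular(NumericMatrix state, NumericMatrix env, List params,
                        double dt, int n_steps) {
  MolParams p = read_mol_params(params);
  int nr = state.nrow();
  NumericMatrix out(nr, 6);
  long clipped = 0, steps = 0;
  for (int r = 0; r < nr; ++r) {
    double x[6];
    for (int i = 0; i < 6; ++i) x[i] = state(r, i);
    Env e{env(r, 0), env(r, 1), env(r, 2), env(r, 3), env(r, 4)};
    for (int s = 0; s < n_steps; ++s) step_mol(x, e, p, dt, clipped, steps);
    for (int i = 0; i < 6; ++i) out(r, i) = x[i];
  }
  return List::create(_["state"] = out, _["clipped"] = (double)clipped,
                      _["steps"] = (double)steps);
}

// ---------------------------------------------------------------------------
// IL2 field: FTCS with 4-neighbour Laplacian, periodic wrap, subcycled so
// that D * dt_sub / dx^2 <= 1/4 (dx = 1 node).
// ---------------------------------------------------------------------------
static void field_step(std::vector<double>& f, const std::vector<double>& src,
                       int L, double D, double delta, double dt) {
  int nsub = (int)std::ceil(std::max(1.0, 4.0 * D * dt));
  double h = dt / nsub;
  // decay handled by an exact exponential factor per substep (operator
  // splitting), so pure decay follows exp(-delta t) to rounding
  double shrink = std::exp(-delta * h);
  int S = L * L;
  std::vector<double> g(S);
  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < L; ++j) {
      int jl = (j == 0) ? L - 1 : j - 1, jr = (j == L - 1) ? 0 : j + 1;
      for (int i = 0; i < L; ++i) {
        int iu = (i == 0) ? L - 1 : i - 1, id = (i == L - 1) ? 0 : i + 1;
        int n = j * L + i;
        double lap = f[jl * L + i] + f[jr * L + i] + f[j * L + iu] + f[j * L + id] -
                     4.0 * f[n];
        g[n] = (f[n] + h * (D * lap + src[n])) * shrink;
      }
    }
    f.swap(g);
  }
  for (int n = 0; n < S; ++n) {
    if (!R_finite(f[n]) || f[n] < -1e-12)
      stop("IL2 field update unstable (D = %g, dt = %g)", D, dt);
    if (f[n] < 0.0) f[n] = 0.0;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_field_step(NumericMatrix grid, NumericMatrix sources, double D,
                             double delta, double dt) {
  int L = grid.nrow();
  if (grid.ncol() != L || sources.nrow() != L || sources.ncol() != L)
    stop("grid and sources must be square matrices of the same size");
  int S = L * L;
  std::vector<double> f(S), src(S);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) { f[j * L + i] = grid(i, j); src[j * L + i] = sources(i, j); }
  field_step(f, src, L, D, delta, dt);
  NumericMatrix out(L, L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) out(i, j) = f[j * L + i];
  return out;
}

// ---------------------------------------------------------------------------
// Potts lattice helpers
// ---------------------------------------------------------------------------
struct PottsConf {
  std::vector<double> J;      // NTYPES x NTYPES
  double lam_area, lam_pm, temperature;
  std::vector<double> A;      // target area (nodes), NaN = unconstrained
  std::vector<double> P;      // target perimeter (um), NaN = unconstrained
  std::vector<double> v;      // motility weight per type
  int theta_interval;
  double Jat(int t1, int t2) const { return J[t1 * NTYPES + t2]; }
};

static PottsConf read_potts_conf(const List& pc) {
  PottsConf c;
  NumericMatrix J = pc["J"];
  if (J.nrow() != NTYPES || J.ncol() != NTYPES) stop("J must be 7 x 7");
  c.J.resize(NTYPES * NTYPES);
  for (int a = 0; a < NTYPES; ++a)
    for (int b = 0; b < NTYPES; ++b) c.J[a * NTYPES + b] = J(a, b);
  c.lam_area = as<double>(pc["lam_area"]);
  c.lam_pm = as<double>(pc["lam_pm"]);
  c.temperature = as<double>(pc["temperature"]);
  c.A = as<std::vector<double>>(pc["A"]);
  c.P = as<std::vector<double>>(pc["P"]);
  c.v = as<std::vector<double>>(pc["v"]);
  c.theta_interval = as<int>(pc["theta_interval"]);
  if ((int)c.A.size() != NTYPES || (int)c.P.size() != NTYPES || (int)c.v.size() != NTYPES)
    stop("A, P and v must have length 7");
  return c;
}

// lattice stored column-major as std::vector<int>, node n = j*L + i
struct Grid {
  int L, S;
  std::vector<int> sigma; // cell id per node, 0 = medium
  int up(int n) const { int i = n % L; return (i == 0) ? n + L - 1 : n - 1; }
  int dn(int n) const { int i = n % L; return (i == L - 1) ? n - L + 1 : n + 1; }
  int lf(int n) const { return (n < L) ? n + S - L : n - L; }
  int rt(int n) const { return (n >= S - L) ? n - S + L : n + L; }
  void nbrs(int n, int* out) const { out[0] = up(n); out[1] = dn(n); out[2] = lf(n); out[3] = rt(n); }
};

// full Hamiltonian from scratch; type_of maps cell id -> type (0 for medium)
static double full_hamiltonian(const Grid& g, const std::vector<int>& type_of,
                               const PottsConf& c) {
  // per-cell area and boundary-edge counts
  int maxid = (int)type_of.size() - 1;
  std::vector<double> area(maxid + 1, 0.0), edges(maxid + 1, 0.0);
  double contact = 0.0;
  for (int n = 0; n < g.S; ++n) {
    int id = g.sigma[n];
    if (id > 0) area[id] += 1.0;
    int nb[4];
    g.nbrs(n, nb);
    for (int d = 0; d < 4; ++d) {
      int id2 = g.sigma[nb[d]];
      if (id2 != id && id > 0) edges[id] += 1.0;
    }
    // contact: count each unordered pair once via down and right neighbours
    int pair[2] = {g.dn(n), g.rt(n)};
    for (int d = 0; d < 2; ++d) {
      int id2 = g.sigma[pair[d]];
      if (id2 != id) contact += c.Jat(type_of[id], type_of[id2]);
    }
  }
  double H = contact;
  for (int id = 1; id <= maxid; ++id) {
    if (area[id] == 0.0 && edges[id] == 0.0) continue;
    int t = type_of[id];
    if (!ISNAN(c.A[t])) H += c.lam_area * std::pow(area[id] - c.A[t], 2.0);
    if (!ISNAN(c.P[t])) H += c.lam_pm * std::pow(4.0 * edges[id] - c.P[t], 2.0);
  }
  return H;
}

// [[Rcpp::export]]
double cpp_hamiltonian(IntegerMatrix sigma, IntegerVector cell_ids,
                       IntegerVector cell_types, List pconf) {
  PottsConf c = read_potts_conf(pconf);
  Grid g;
  g.L = sigma.nrow(); g.S = g.L * g.L;
  if (sigma.ncol() != g.L) stop("sigma must be square");
  g.sigma.resize(g.S);
  int maxid = 0;
  for (int j = 0; j < g.L; ++j)
    for (int i = 0; i < g.L; ++i) {
      g.sigma[j * g.L + i] = sigma(i, j);
      maxid = std::max(maxid, sigma(i, j));
    }
  std::vector<int> type_of(maxid + 1, 0);
  for (int k = 0; k < cell_ids.size(); ++k) {
    if (cell_ids[k] < 1 || cell_ids[k] > maxid) continue;
    if (cell_types[k] < 0 || cell_types[k] >= NTYPES) stop("unknown cell type code");
    type_of[cell_ids[k]] = cell_types[k];
  }
  return full_hamiltonian(g, type_of, c);
}

// [[Rcpp::export]]
LogicalVector cpp_metropolis_accept(NumericVector dE, double temperature) {
  int n = dE.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (dE[i] <= 0.0) || (unif_rand() < std::exp(-dE[i] / temperature));
  return out;
}

// engine-level cell bookkeeping shared between the MCS wrapper and the run loop
struct CellBook {
  std::vector<int> type_of;     // id -> type
  std::vector<double> area, edges, theta, vmot;
};

// one copy attempt; updates grid + book incrementally. Returns ΔH on acceptance
// (energy terms only, no motility), NAN when rejected.
static double attempt_copy(Grid& g, CellBook& bk, const PottsConf& c,
                           long& attempts, long& accepted) {
  ++attempts;
  int ns = (int)(unif_rand() * g.S);
  if (ns >= g.S) ns = g.S - 1;
  int dir = (int)(unif_rand() * 4.0);
  if (dir >= 4) dir = 3;
  int nb[4];
  g.nbrs(ns, nb);
  int ng = nb[dir];
  int s = g.sigma[ns], gid = g.sigma[ng];
  if (s == gid) return NA_REAL;
  if (gid > 0 && bk.area[gid] <= 1.0) return NA_REAL; // don't annihilate a cell
  int ts = (s > 0) ? bk.type_of[s] : 0;
  int tg = (gid > 0) ? bk.type_of[gid] : 0;

  int gnb[4];
  g.nbrs(ng, gnb);
  int n_s = 0, n_g = 0;
  double dcontact = 0.0;
  for (int d = 0; d < 4; ++d) {
    int idn = g.sigma[gnb[d]];
    int tn = (idn > 0) ? bk.type_of[idn] : 0;
    if (idn == s) ++n_s;
    if (idn == gid) ++n_g;
    if (idn != gid) dcontact -= c.Jat(tg, tn);
    if (idn != s) dcontact += c.Jat(ts, tn);
  }
  double dH = dcontact;
  if (s > 0) {
    if (!ISNAN(c.A[ts]))
      dH += c.lam_area * (std::pow(bk.area[s] + 1.0 - c.A[ts], 2.0) -
                          std::pow(bk.area[s] - c.A[ts], 2.0));
    if (!ISNAN(c.P[ts])) {
      double de = 4.0 - 2.0 * n_s;
      dH += c.lam_pm * (std::pow(4.0 * (bk.edges[s] + de) - c.P[ts], 2.0) -
                        std::pow(4.0 * bk.edges[s] - c.P[ts], 2.0));
    }
  }
  if (gid > 0) {
    if (!ISNAN(c.A[tg]))
      dH += c.lam_area * (std::pow(bk.area[gid] - 1.0 - c.A[tg], 2.0) -
                          std::pow(bk.area[gid] - c.A[tg], 2.0));
    if (!ISNAN(c.P[tg])) {
      double de = 2.0 * n_g - 4.0;
      dH += c.lam_pm * (std::pow(4.0 * (bk.edges[gid] + de) - c.P[tg], 2.0) -
                        std::pow(4.0 * bk.edges[gid] - c.P[tg], 2.0));
    }
  }
  // motility bias: dot of the source cell's heading with the copy direction
  double dmot = 0.0;
  if (s > 0 && bk.vmot[s] != 0.0) {
    // directions: 0 up (i-1), 1 down (i+1), 2 left (j-1), 3 right (j+1)
    // x = column j, y = row i with y increasing downward
    double dx = (dir == 3) ? 1.0 : (dir == 2) ? -1.0 : 0.0;
    double dy = (dir == 1) ? 1.0 : (dir == 0) ? -1.0 : 0.0;
    dmot = bk.vmot[s] * (std::cos(bk.theta[s]) * dx + std::sin(bk.theta[s]) * dy);
  }
  double cost = dH - dmot;
  bool ok = (cost <= 0.0) || (unif_rand() < std::exp(-cost / c.temperature));
  if (!ok) return NA_REAL;
  // commit
  g.sigma[ng] = s;
  if (s > 0) { bk.area[s] += 1.0; bk.edges[s] += 4.0 - 2.0 * n_s; }
  if (gid > 0) { bk.area[gid] -= 1.0; bk.edges[gid] += 2.0 * n_g - 4.0; }
  ++accepted;
  return dH;
}

static void init_book(const Grid& g, CellBook& bk) {
  int maxid = (int)bk.type_of.size() - 1;
  bk.area.assign(maxid + 1, 0.0);
  bk.edges.assign(maxid + 1, 0.0);
  for (int n = 0; n < g.S; ++n) {
    int id = g.sigma[n];
    if (id > 0) {
      bk.area[id] += 1.0;
      int nb[4];
      g.nbrs(n, nb);
      for (int d = 0; d < 4; ++d)
        if (g.sigma[nb[d]] != id) bk.edges[id] += 1.0;
    }
  }
}

// [[Rcpp::export]]
List cpp_monte_carlo_step(IntegerMatrix sigma, IntegerVector cell_ids,
                          IntegerVector cell_types, NumericVector theta,
                          NumericVector v, List pconf, int n_mcs) {
  PottsConf c = read_potts_conf(pconf);
  Grid g;
  g.L = sigma.nrow(); g.S = g.L * g.L;
  g.sigma.resize(g.S);
  int maxid = 0;
  for (int j = 0; j < g.L; ++j)
    for (int i = 0; i < g.L; ++i) {
      g.sigma[j * g.L + i] = sigma(i, j);
      maxid = std::max(maxid, sigma(i, j));
    }
  CellBook bk;
  bk.type_of.assign(maxid + 1, 0);
  bk.theta.assign(maxid + 1, 0.0);
  bk.vmot.assign(maxid + 1, 0.0);
  for (int k = 0; k < cell_ids.size(); ++k) {
    int id = cell_ids[k];
    if (id < 1 || id > maxid) continue;
    bk.type_of[id] = cell_types[k];
    bk.theta[id] = theta[k];
    bk.vmot[id] = v[k];
  }
  init_book(g, bk);
  double H = full_hamiltonian(g, bk.type_of, c);
  long attempts = 0, accepted = 0;
  long N = 3L * g.S;
  for (int m = 0; m < n_mcs; ++m)
    for (long a = 0; a < N; ++a) {
      double dH = attempt_copy(g, bk, c, attempts, accepted);
      if (!ISNAN(dH)) H += dH;
    }
  IntegerMatrix out(g.L, g.L);
  for (int j = 0; j < g.L; ++j)
    for (int i = 0; i < g.L; ++i) out(i, j) = g.sigma[j * g.L + i];
  return List::create(_["sigma"] = out, _["attempts"] = (double)attempts,
                      _["accepted"] = (double)accepted, _["hamiltonian"] = H);
}

// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(IntegerMatrix sigma) {
  int L = sigma.nrow(), S = L * L;
  Grid g;
  g.L = L; g.S = S;
  g.sigma.resize(S);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) g.sigma[j * L + i] = sigma(i, j);
  std::vector<std::pair<int, int>> pairs;
  for (int n = 0; n < S; ++n) {
    int a = g.sigma[n];
    int two[2] = {g.dn(n), g.rt(n)};
    for (int d = 0; d < 2; ++d) {
      int b = g.sigma[two[d]];
      if (a > 0 && b > 0 && a != b)
        pairs.emplace_back(std::min(a, b), std::max(a, b));
    }
  }
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  IntegerMatrix out(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first;
    out(k, 1) = pairs[k].second;
  }
  return out;
}

// boundary nodes of one cell (>= 1 first-order neighbour outside the cell)
// [[Rcpp::export]]
IntegerMatrix cpp_boundary_nodes(IntegerMatrix sigma, int id) {
  int L = sigma.nrow();
  Grid g;
  g.L = L; g.S = L * L;
  g.sigma.resize(g.S);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) g.sigma[j * L + i] = sigma(i, j);
  std::vector<std::pair<int, int>> rows;
  for (int n = 0; n < g.S; ++n) {
    if (g.sigma[n] != id) continue;
    int nb[4];
    g.nbrs(n, nb);
    for (int d = 0; d < 4; ++d)
      if (g.sigma[nb[d]] != id) {
        rows.emplace_back(n % L + 1, n / L + 1); // 1-based (row, col)
        break;
      }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t k = 0; k < rows.size(); ++k) {
    out(k, 0) = rows[k].first;
    out(k, 1) = rows[k].second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// division geometry: bisect a cell perpendicular to its principal axis into
// two connected node sets of near-equal size (alternating BFS region growth
// from the two extreme nodes along the principal axis).
// ---------------------------------------------------------------------------
static void split_nodes(const Grid& g, const std::vector<int>& nodes,
                        std::vector<int>& half1, std::vector<int>& half2) {
  int m = (int)nodes.size();
  // unwrap coordinates around the first node (cells are small vs the lattice)
  std::vector<double> x(m), y(m);
  std::vector<int> idx_of(g.S, -1);
  for (int k = 0; k < m; ++k) idx_of[nodes[k]] = k;
  std::vector<char> seen(m, 0);
  std::queue<int> q;
  q.push(0);
  seen[0] = 1;
  x[0] = 0; y[0] = 0;
  const double dxs[4] = {0, 0, -1, 1}, dys[4] = {-1, 1, 0, 0};
  while (!q.empty()) {
    int k = q.front(); q.pop();
    int nb[4];
    g.nbrs(nodes[k], nb);
    for (int d = 0; d < 4; ++d) {
      int k2 = idx_of[nb[d]];
      if (k2 >= 0 && !seen[k2]) {
        seen[k2] = 1;
        x[k2] = x[k] + dxs[d];
        y[k2] = y[k] + dys[d];
        q.push(k2);
      }
    }
  }
  // principal axis of the node cloud (2x2 covariance eigenvector)
  double mx = 0, my = 0;
  for (int k = 0; k < m; ++k) { mx += x[k]; my += y[k]; }
  mx /= m; my /= m;
  double sxx = 0, syy = 0, sxy = 0;
  for (int k = 0; k < m; ++k) {
    sxx += (x[k] - mx) * (x[k] - mx);
    syy += (y[k] - my) * (y[k] - my);
    sxy += (x[k] - mx) * (y[k] - my);
  }
  double ax, ay;
  double tr = sxx + syy, det = sxx * syy - sxy * sxy;
  double lam = 0.5 * tr + std::sqrt(std::max(0.0, 0.25 * tr * tr - det));
  if (std::fabs(sxy) > 1e-12) { ax = lam - syy; ay = sxy; }
  else if (sxx >= syy) { ax = 1; ay = 0; }
  else { ax = 0; ay = 1; }
  // seeds: extreme projections along the axis (ties broken by node order)
  int kmin = 0, kmax = 0;
  double pmin = 1e300, pmax = -1e300;
  for (int k = 0; k < m; ++k) {
    double pr = ax * x[k] + ay * y[k];
    if (pr < pmin) { pmin = pr; kmin = k; }
    if (pr > pmax) { pmax = pr; kmax = k; }
  }
  if (kmin == kmax) kmax = (kmin + 1) % m;
  // alternating BFS growth keeps both halves connected
  std::vector<int> owner(m, 0);
  std::queue<int> q1, q2;
  owner[kmin] = 1; q1.push(kmin);
  owner[kmax] = 2; q2.push(kmax);
  int c1 = 1, c2 = 1, assigned = 2;
  while (assigned < m) {
    bool grow1 = (c1 <= c2 && !q1.empty()) || q2.empty();
    std::queue<int>& q = grow1 ? q1 : q2;
    int who = grow1 ? 1 : 2;
    if (q.empty()) { // stranded nodes (fragmented mother): assign arbitrarily
      for (int k = 0; k < m; ++k)
        if (!owner[k]) { owner[k] = who; q.push(k); ++assigned; (grow1 ? c1 : c2)++; break; }
      continue;
    }
    int k = q.front(); q.pop();
    int nb[4];
    g.nbrs(nodes[k], nb);
    bool claimed = false;
    for (int d = 0; d < 4; ++d) {
      int k2 = idx_of[nb[d]];
      if (k2 >= 0 && !owner[k2]) {
        owner[k2] = who;
        (who == 1 ? c1 : c2)++;
        ++assigned;
        q.push(k);  // requeue parent: it may have more free neighbours
        q.push(k2);
        claimed = true;
        break;
      }
    }
    (void)claimed;
  }
  half1.clear(); half2.clear();
  for (int k = 0; k < m; ++k)
    (owner[k] == 1 ? half1 : half2).push_back(nodes[k]);
}

// [[Rcpp::export]]
List cpp_split_cell(IntegerMatrix sigma, int id, int new_id) {
  int L = sigma.nrow();
  Grid g;
  g.L = L; g.S = L * L;
  g.sigma.resize(g.S);
  std::vector<int> nodes;
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      g.sigma[j * L + i] = sigma(i, j);
      if (sigma(i, j) == id) nodes.push_back(j * L + i);
    }
  if (nodes.size() < 2) stop("cell area must be >= 2 nodes to divide");
  std::vector<int> h1, h2;
  split_nodes(g, nodes, h1, h2);
  IntegerMatrix out = clone(sigma);
  for (int n : h2) out(n % L, n / L) = new_id;
  return List::create(_["sigma"] = out, _["n1"] = (int)h1.size(),
                      _["n2"] = (int)h2.size());
}

// ---------------------------------------------------------------------------
// full coupled simulation
// ---------------------------------------------------------------------------
struct SimCell {
  int id = 0, type = MEDIUM;
  int k = 0;
  double cyc_len = 0, cyc_elapsed = 0;
  bool first_div = false;
  double mol[6] = {0, 0, 0, 0, 0, 0};
  double theta = 0;
  double apc_death = 0;
  bool G = false, alive = false;
  // per-MCS environment
  int fAPC = 0;
  bool H = false;
  double Tbcm = 0, IL2cm = 0;
  std::vector<int> contacts;
};

struct FieldParams {
  double D, delta, lam_R3, lam_R4, lam_1, lam_T4;
};

static double secretion(const double* mol, double fAPC, const FieldParams& fp) {
  return (fp.lam_R3 * mol[1] / (fp.lam_R4 + mol[1]) + fp.lam_1 * fAPC) /
         (1.0 + fp.lam_T4 * mol[2]);
}

// [[Rcpp::export]]
double cpp_secretion_rate(NumericVector state, double f_APC, List field_params) {
  FieldParams fp{as<double>(field_params["D"]), as<double>(field_params["delta"]),
                 as<double>(field_params["lam_R3"]), as<double>(field_params["lam_R4"]),
                 as<double>(field_params["lam_1"]), as<double>(field_params["lam_T4"])};
  double mol[6];
  for (int i = 0; i < 6; ++i) mol[i] = state[i];
  return secretion(mol, f_APC, fp);
}

struct World {
  Grid g;
  std::vector<double> field;
  std::vector<SimCell> cells;   // indexed by slot
  std::vector<int> slot_of;     // id -> slot (or -1)
  int next_id = 1;
  CellBook bk;                  // id-indexed caches for the Potts step

  int new_cell(int type) {
    SimCell c;
    c.id = next_id++;
    c.type = type;
    c.alive = true;
    cells.push_back(c);
    slot_of.push_back((int)cells.size() - 1);
    // grow book
    bk.type_of.push_back(type);
    bk.area.push_back(0.0);
    bk.edges.push_back(0.0);
    bk.theta.push_back(0.0);
    bk.vmot.push_back(0.0);
    return c.id;
  }
  SimCell& by_id(int id) { return cells[slot_of[id]]; }
};

// place a w x h block of fresh cell `id` at a random free spot; true on success
static bool place_block(World& w, int id, int wdt, int hgt) {
  for (int tries = 0; tries < 20000; ++tries) {
    int i0 = (int)(unif_rand() * w.g.L), j0 = (int)(unif_rand() * w.g.L);
    bool free = true;
    for (int dj = 0; dj < wdt && free; ++dj)
      for (int di = 0; di < hgt && free; ++di) {
        int i = (i0 + di) % w.g.L, j = (j0 + dj) % w.g.L;
        if (w.g.sigma[j * w.g.L + i] != 0) free = false;
      }
    if (!free) continue;
    for (int dj = 0; dj < wdt; ++dj)
      for (int di = 0; di < hgt; ++di) {
        int i = (i0 + di) % w.g.L, j = (j0 + dj) % w.g.L;
        w.g.sigma[j * w.g.L + i] = id;
      }
    return true;
  }
  return false;
}

struct EventLog {
  std::vector<double> mcs;
  std::vector<int> id;
  std::vector<int> code;   // 1 pre-activation, 2 activation, 3 division,
                           // 4 birth, 5 memory conversion, 6 apoptosis, 7 APC death
  std::vector<double> value;
  void add(int m, int cid, int cd, double val) {
    mcs.push_back(m); id.push_back(cid); code.push_back(cd); value.push_back(val);
  }
};

// [[Rcpp::export]]
List cpp_run_simulation(List config) {
  // --- unpack ----------------------------------------------------------------
  const int L = as<int>(config["L"]);
  const int n_mcs = as<int>(config["n_mcs"]);
  const double min_per_mcs = as<double>(config["minutes_per_mcs"]);
  const double dt = min_per_mcs / 60.0; // hours per MCS
  const int n_naive = as<int>(config["n_naive"]);
  const int n_apc = as<int>(config["n_apc"]);
  const int n_memory = as<int>(config["n_memory"]);
  const int snap_every = as<int>(config["snapshot_every"]);
  const int cell_snap_every = as<int>(config["cell_snapshot_every"]);
  const double start_day = as<double>(config["start_day"]);
  MolParams mp = read_mol_params(config["molecular"]);
  List fpl = config["field"];
  FieldParams fp{as<double>(fpl["D"]), as<double>(fpl["delta"]),
                 as<double>(fpl["lam_R3"]), as<double>(fpl["lam_R4"]),
                 as<double>(fpl["lam_1"]), as<double>(fpl["lam_T4"])};
  PottsConf pc = read_potts_conf(config["potts"]);
  List rl = config["rules"];
  const double IL2R_th = as<double>(rl["IL2R_th"]);
  const double Tbet_th = as<double>(rl["Tbet_th"]);
  const double Eomes_th = as<double>(rl["Eomes_th"]);
  const double Cas_th = as<double>(rl["Caspases_th"]);
  const double m_unev = as<double>(rl["m"]);
  const bool memory_divides = as<bool>(rl["memory_divides"]); // alternative rule
  NumericVector mem_state = config["memory_state"];

  World w;
  w.g.L = L;
  w.g.S = L * L;
  w.g.sigma.assign(w.g.S, 0);
  w.slot_of.assign(1, -1); // id 0 = medium
  w.bk.type_of.assign(1, 0);
  w.bk.area.assign(1, 0.0);
  w.bk.edges.assign(1, 0.0);
  w.bk.theta.assign(1, 0.0);
  w.bk.vmot.assign(1, 0.0);
  w.field.assign(w.g.S, 0.0);

  // --- initial population ----------------------------------------------------
  for (int a = 0; a < n_apc; ++a) {
    int id = w.new_cell(APC);
    if (!place_block(w, id, 12, 12)) stop("could not place APC %d", a + 1);
    w.by_id(id).apc_death = 48.0 + 48.0 * unif_rand();
  }
  for (int a = 0; a < n_naive; ++a) {
    int id = w.new_cell(NAIVE);
    if (!place_block(w, id, 3, 3)) stop("could not place naive cell %d", a + 1);
  }
  for (int a = 0; a < n_memory; ++a) {
    int id = w.new_cell(MEM);
    if (!place_block(w, id, 3, 3)) stop("could not place memory cell %d", a + 1);
    SimCell& c = w.by_id(id);
    for (int i = 0; i < 6; ++i) c.mol[i] = mem_state[i];
    c.G = true;
  }
  // sync book with initial lattice
  init_book(w.g, w.bk);
  for (auto& c : w.cells) {
    c.theta = 2.0 * M_PI * unif_rand();
    w.bk.theta[c.id] = c.theta;
    w.bk.type_of[c.id] = c.type;
    w.bk.vmot[c.id] = pc.v[c.type];
  }

  // --- outputs ---------------------------------------------------------------
  std::vector<double> snap_mcs;
  std::vector<int> cnt_naive, cnt_pre, cnt_act, cnt_eff, cnt_mem, cnt_apc;
  std::vector<double> cs_mcs;
  std::vector<int> cs_id, cs_type, cs_k;
  std::vector<double> cs_mol[6];
  EventLog ev;
  long attempts = 0, accepted = 0, clipped = 0, mol_steps = 0;
  bool extinct = false;

  auto snapshot = [&](int mcs) {
    int nn = 0, np = 0, na = 0, ne = 0, nm = 0, nA = 0;
    for (auto& c : w.cells) {
      if (!c.alive) continue;
      switch (c.type) {
        case NAIVE: ++nn; break;
        case PREACT: ++np; break;
        case ACT: ++na; break;
        case EFF: ++ne; break;
        case MEM: ++nm; break;
        case APC: ++nA; break;
      }
    }
    snap_mcs.push_back(mcs);
    cnt_naive.push_back(nn); cnt_pre.push_back(np); cnt_act.push_back(na);
    cnt_eff.push_back(ne); cnt_mem.push_back(nm); cnt_apc.push_back(nA);
  };
  auto cell_snapshot = [&](int mcs) {
    for (auto& c : w.cells) {
      if (!c.alive || c.type == APC) continue;
      cs_mcs.push_back(mcs);
      cs_id.push_back(c.id);
      cs_type.push_back(c.type);
      cs_k.push_back(c.k);
      for (int i = 0; i < 6; ++i) cs_mol[i].push_back(c.mol[i]);
    }
  };
  snapshot(0);
  cell_snapshot(0);

  std::vector<double> src(w.g.S);
  std::vector<int> dividing, dying;

  // --- main loop -------------------------------------------------------------
  for (int mcs = 1; mcs <= n_mcs; ++mcs) {
    double t_hours = mcs * dt;

    // (0) refresh privileged angles
    if (pc.theta_interval > 0 && mcs % pc.theta_interval == 0)
      for (auto& c : w.cells)
        if (c.alive) {
          c.theta = 2.0 * M_PI * unif_rand();
          w.bk.theta[c.id] = c.theta;
        }

    // (1) Potts Monte Carlo step: N = 3 * S copy attempts
    long N = 3L * w.g.S;
    for (long a = 0; a < N; ++a) attempt_copy(w.g, w.bk, pc, attempts, accepted);

    // (2) contacts and environment inputs
    for (auto& c : w.cells)
      if (c.alive) { c.contacts.clear(); c.fAPC = 0; c.H = false; c.Tbcm = 0; c.IL2cm = 0; }
    for (int n = 0; n < w.g.S; ++n) {
      int a = w.g.sigma[n];
      int two[2] = {w.g.dn(n), w.g.rt(n)};
      for (int d = 0; d < 2; ++d) {
        int b = w.g.sigma[two[d]];
        if (a > 0 && b > 0 && a != b) {
          w.by_id(a).contacts.push_back(b);
          w.by_id(b).contacts.push_back(a);
        }
      }
      // membrane IL2: boundary nodes of each CD8 cell
      if (a > 0) {
        SimCell& c = w.by_id(a);
        if (c.type >= NAIVE) {
          int nb[4];
          w.g.nbrs(n, nb);
          for (int d = 0; d < 4; ++d)
            if (w.g.sigma[nb[d]] != a) { c.IL2cm += w.field[n]; break; }
        }
      }
    }
    for (auto& c : w.cells) {
      if (!c.alive || c.type < NAIVE) continue;
      std::sort(c.contacts.begin(), c.contacts.end());
      c.contacts.erase(std::unique(c.contacts.begin(), c.contacts.end()),
                       c.contacts.end());
      for (int other : c.contacts) {
        SimCell& o = w.by_id(other);
        if (o.type == APC && (c.type == NAIVE || c.type == PREACT || c.type == MEM))
          ++c.fAPC;
        if ((o.type == EFF || o.type == MEM) && c.type != NAIVE) {
          c.H = true;
          c.Tbcm += o.mol[2];
        }
      }
    }

    // (3) molecular step per CD8 T-cell (naive cells stay at the zero state)
    for (auto& c : w.cells) {
      if (!c.alive || c.type < PREACT) continue;
      Env e;
      e.fAPC = (c.type == PREACT) ? (double)c.fAPC : 0.0;
      e.G = c.G ? 1.0 : 0.0;
      e.H = c.H ? 1.0 : 0.0;
      e.IL2cm = c.IL2cm;
      e.Tbcm = c.Tbcm;
      step_mol(c.mol, e, mp, dt, clipped, mol_steps);
    }

    // (4) IL2 field: secretion sources (pre-activated and later; not naive/APC),
    // each cell's rate deposited equally over its nodes in one lattice pass
    std::fill(src.begin(), src.end(), 0.0);
    for (int n = 0; n < w.g.S; ++n) {
      int id = w.g.sigma[n];
      if (id == 0) continue;
      SimCell& c = w.by_id(id);
      if (c.type < PREACT) continue;
      double rate = secretion(c.mol, (c.type == PREACT) ? c.fAPC : 0.0, fp);
      if (rate > 0.0) src[n] = rate / w.bk.area[id];
    }
    field_step(w.field, src, L, fp.D, fp.delta, dt);

    // (5) rules ---------------------------------------------------------------
    // (5a) naive or memory cell binding an APC becomes pre-activated
    for (auto& c : w.cells) {
      if (!c.alive) continue;
      if ((c.type == NAIVE || c.type == MEM) && c.fAPC > 0) {
        c.type = PREACT;
        c.G = true;
        w.bk.type_of[c.id] = PREACT;
        w.bk.vmot[c.id] = pc.v[PREACT];
        ev.add(mcs, c.id, 1, 0);
      }
    }
    // (5b) pre-activated reaching IL2R_th becomes activated, starts cycling
    for (auto& c : w.cells) {
      if (!c.alive || c.type != PREACT) continue;
      if (c.mol[1] >= IL2R_th) {
        c.type = ACT;
        c.k = 0;
        double ck = 6.0; // c_0
        c.cyc_len = ck - 4.0 + 8.0 * unif_rand();
        c.cyc_elapsed = 0.0;
        c.first_div = true;
        w.bk.type_of[c.id] = ACT;
        w.bk.vmot[c.id] = pc.v[ACT];
        ev.add(mcs, c.id, 2, 0);
      }
    }
    // (5c) cycle advance + division / memory conversion
    dividing.clear();
    for (auto& c : w.cells) {
      if (!c.alive || (c.type != ACT && c.type != EFF)) continue;
      c.cyc_elapsed += dt;
      if (c.cyc_elapsed < c.cyc_len) continue;
      if (c.mol[5] > Eomes_th && !memory_divides) {
        c.type = MEM;
        w.bk.type_of[c.id] = MEM;
        w.bk.vmot[c.id] = pc.v[MEM];
        ev.add(mcs, c.id, 5, c.mol[5]);
        continue;
      }
      if (w.bk.area[c.id] < 2.0) continue; // defer until the cell regains area
      dividing.push_back(c.id);
    }
    if (!dividing.empty()) {
      // collect node lists in one lattice pass
      std::vector<std::vector<int>> nodes(dividing.size());
      std::vector<int> which(w.bk.type_of.size(), -1);
      for (size_t k = 0; k < dividing.size(); ++k) which[dividing[k]] = (int)k;
      for (int n = 0; n < w.g.S; ++n) {
        int id = w.g.sigma[n];
        if (id > 0 && which[id] >= 0) nodes[which[id]].push_back(n);
      }
      for (size_t k = 0; k < dividing.size(); ++k) {
        int mid = dividing[k];
        SimCell& mother = w.by_id(mid);
        std::vector<int> h1, h2;
        split_nodes(w.g, nodes[k], h1, h2);
        bool to_memory = memory_divides && mother.mol[5] > Eomes_th;
        // molecular partitioning
        double d1[6], d2[6];
        if (mother.first_div) {
          // Tbet: proximal daughter gets (2-K)*Tb, distal K*Tb, K ~ U[0.5, 1]
          double K = 0.5 + 0.5 * unif_rand();
          bool d1_proximal = unif_rand() < 0.5;
          double tb = mother.mol[2];
          d1[2] = d1_proximal ? (2.0 - K) * tb : K * tb;
          d2[2] = d1_proximal ? K * tb : (2.0 - K) * tb;
          for (int i = 0; i < 6; ++i) {
            if (i == 2) continue;
            double ki = 1.0 - m_unev / 100.0 * unif_rand();
            bool d1_gets = unif_rand() < 0.5;
            d1[i] = (d1_gets ? ki : 2.0 - ki) * mother.mol[i];
            d2[i] = (d1_gets ? 2.0 - ki : ki) * mother.mol[i];
          }
        } else {
          for (int i = 0; i < 6; ++i) {
            double ki = 1.0 - m_unev / 100.0 * unif_rand();
            bool d1_gets = unif_rand() < 0.5;
            d1[i] = (d1_gets ? ki : 2.0 - ki) * mother.mol[i];
            d2[i] = (d1_gets ? 2.0 - ki : ki) * mother.mol[i];
          }
        }
        int kd = mother.k + 1;
        bool momG = mother.G;
        // retire mother, create two daughters
        mother.alive = false;
        ev.add(mcs, mid, 3, 0);
        int id1 = w.new_cell(ACT), id2 = w.new_cell(ACT);
        for (int n : nodes[k]) w.g.sigma[n] = 0; // cleared below by reassignment
        for (int n : h1) w.g.sigma[n] = id1;
        for (int n : h2) w.g.sigma[n] = id2;
        int pair_ids[2] = {id1, id2};
        double* dmol[2] = {d1, d2};
        for (int dd = 0; dd < 2; ++dd) {
          SimCell& dc = w.by_id(pair_ids[dd]);
          for (int i = 0; i < 6; ++i) dc.mol[i] = dmol[dd][i];
          dc.G = momG;
          dc.k = kd;
          dc.first_div = false;
          dc.type = to_memory ? MEM
                    : (dc.mol[2] >= Tbet_th ? EFF : ACT);
          if (dc.type != MEM) {
            double ck = 6.0 + 28.0 * (double)kd * kd / ((double)kd * kd + 100.0);
            dc.cyc_len = ck - 4.0 + 8.0 * unif_rand();
            dc.cyc_elapsed = 0.0;
          }
          dc.theta = 2.0 * M_PI * unif_rand();
          w.bk.type_of[dc.id] = dc.type;
          w.bk.theta[dc.id] = dc.theta;
          w.bk.vmot[dc.id] = pc.v[dc.type];
          ev.add(mcs, dc.id, 4, mid);
          if (dc.type == MEM) ev.add(mcs, dc.id, 5, dc.mol[5]);
        }
        // rebuild area/edge caches for the two daughters
        for (int dd = 0; dd < 2; ++dd) {
          int id = pair_ids[dd];
          w.bk.area[id] = 0;
          w.bk.edges[id] = 0;
        }
        for (int n : nodes[k]) {
          int id = w.g.sigma[n];
          w.bk.area[id] += 1.0;
        }
        for (int n : nodes[k]) {
          int id = w.g.sigma[n];
          int nb[4];
          w.g.nbrs(n, nb);
          for (int d = 0; d < 4; ++d)
            if (w.g.sigma[nb[d]] != id) w.bk.edges[id] += 1.0;
        }
        // mother's cached area/edges now refer to a dead id
        w.bk.area[mid] = 0;
        w.bk.edges[mid] = 0;
      }
    }
    // (5d) apoptosis: Caspases threshold (never naive); APC lifetime
    dying.clear();
    for (auto& c : w.cells) {
      if (!c.alive) continue;
      if (c.type == APC) {
        if (t_hours >= c.apc_death) { dying.push_back(c.id); ev.add(mcs, c.id, 7, 0); }
      } else if (c.type >= PREACT && c.mol[4] >= Cas_th) {
        dying.push_back(c.id);
        ev.add(mcs, c.id, 6, c.mol[4]);
      }
    }
    if (!dying.empty()) {
      std::vector<char> is_dying(w.bk.type_of.size(), 0);
      for (int id : dying) {
        is_dying[id] = 1;
        w.by_id(id).alive = false;
        w.bk.area[id] = 0;
        w.bk.edges[id] = 0;
      }
      for (int n = 0; n < w.g.S; ++n)
        if (w.g.sigma[n] > 0 && is_dying[w.g.sigma[n]]) w.g.sigma[n] = 0;
      // neighbours' edge counts changed: rebuild caches
      init_book(w.g, w.bk);
      for (auto& c : w.cells)
        if (!c.alive) { w.bk.area[c.id] = 0; w.bk.edges[c.id] = 0; }
    }

    // (6) snapshots
    if (mcs % snap_every == 0 || mcs == n_mcs) snapshot(mcs);
    if (mcs % cell_snap_every == 0 || mcs == n_mcs) cell_snapshot(mcs);

    // extinction check (no live CD8 cell at all)
    bool any_cd8 = false;
    for (auto& c : w.cells)
      if (c.alive && c.type >= NAIVE) { any_cd8 = true; break; }
    if (!any_cd8) { extinct = true; snapshot(mcs); break; }
    if (mcs % 500 == 0) Rcpp::checkUserInterrupt();
  }

  // --- pack outputs ----------------------------------------------------------
  IntegerMatrix sig_out(L, L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) sig_out(i, j) = w.g.sigma[j * L + i];
  NumericMatrix field_out(L, L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) field_out(i, j) = w.field[j * L + i];

  int n_final = 0;
  for (auto& c : w.cells) if (c.alive) ++n_final;
  IntegerVector fid(n_final), ftype(n_final), fk(n_final);
  NumericVector farea(n_final);
  NumericMatrix fmol(n_final, 6);
  int r = 0;
  for (auto& c : w.cells) {
    if (!c.alive) continue;
    fid[r] = c.id; ftype[r] = c.type; fk[r] = c.k;
    farea[r] = w.bk.area[c.id];
    for (int i = 0; i < 6; ++i) fmol(r, i) = c.mol[i];
    ++r;
  }

  List pop = List::create(
      _["mcs"] = wrap(snap_mcs), _["naive"] = wrap(cnt_naive),
      _["pre_activated"] = wrap(cnt_pre), _["activated"] = wrap(cnt_act),
      _["effector"] = wrap(cnt_eff), _["memory"] = wrap(cnt_mem),
      _["apc"] = wrap(cnt_apc));
  List cellsnap = List::create(
      _["mcs"] = wrap(cs_mcs), _["id"] = wrap(cs_id), _["type"] = wrap(cs_type),
      _["k"] = wrap(cs_k), _["R"] = wrap(cs_mol[0]), _["LR"] = wrap(cs_mol[1]),
      _["Tb"] = wrap(cs_mol[2]), _["Fs"] = wrap(cs_mol[3]),
      _["Cas"] = wrap(cs_mol[4]), _["E"] = wrap(cs_mol[5]));
  List events = List::create(
      _["mcs"] = wrap(ev.mcs), _["id"] = wrap(ev.id), _["code"] = wrap(ev.code),
      _["value"] = wrap(ev.value));
  List final_cells = List::create(
      _["id"] = fid, _["type"] = ftype, _["k"] = fk, _["area"] = farea,
      _["mol"] = fmol);
  return List::create(
      _["population"] = pop, _["cells"] = cellsnap, _["events"] = events,
      _["final_sigma"] = sig_out, _["final_field"] = field_out,
      _["final_cells"] = final_cells,
      _["stats"] = List::create(_["attempts"] = (double)attempts,
                                _["accepted"] = (double)accepted,
                                _["clipped"] = (double)clipped,
                                _["mol_steps"] = (double)mol_steps,
                                _["extinct"] = extinct),
      _["start_day"] = start_day, _["minutes_per_mcs"] = min_per_mcs);
}
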