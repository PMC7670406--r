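// Event-driven exact stochastic simulation of the weighted network model.
//
// Between damage events the deficit vector is frozen, so every hazard is a
// hinged polynomial in age: f_i(t) = max(Wd_i + mu_i(t), 0) with mu_i monotone
// non-decreasing, Gamma_i^+ = max(poly(f_i), 0), and likewise the mortality
// hazard through x(t). Each hazard therefore has at most two hinge kinks per
// inter-event interval (inner argument crossing zero, outer series crossing
// zero), and between kinks the total hazard is exactly polynomial. Waiting
// times are drawn by hazard inversion: u ~ Exp(1), solve
// int_t^{T} Gamma_tot(s) ds = u, integrating each kink-free segment with
// Gauss-Legendre quadrature of sufficient order (exact for the polynomial
// degree) and locating the crossing by bisection to 1e-9 years.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---- RNG: splitmix64-seeded xoshiro-free mt19937_64, manual transforms ----

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  Rng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0x632BE59BD9B4E019ULL * (stream + 1));
    for (int k = 0; k < 4; ++k) s[k] = splitmix64(x);
  }
  // xoshiro256++
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double rexp() { return -std::log(unif()); }
};

// ---- Gauss-Legendre nodes on [-1, 1] by Newton iteration -------------------

static void gauss_legendre(int n, std::vector<double> &x,
                           std::vector<double> &w) {
  x.assign(n, 0.0);
  w.assign(n, 0.0);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double pp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2;
        p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      double z1 = z;
      z = z1 - p1 / pp;
      if (std::fabs(z - z1) < 1e-15) break;
    }
    x[i] = -z;
    x[n - 1 - i] = z;
    w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    w[n - 1 - i] = w[i];
  }
}

// ---- model ------------------------------------------------------------------

struct Model {
  int N, nf, np, nd1, nd2;
  std::vector<double> W;      // N*N row-major: W[i*N+j]
  std::vector<double> mu;     // N*nf row-major, orders 1..nf
  std::vector<double> gam;    // N*(np+1) row-major, orders 0..np
  std::vector<double> beta;   // N
  std::vector<double> alpha;  // nd1+1
  std::vector<double> eta;    // nd2+1
  std::vector<double> glx, glw;

  void init_quadrature() {
    // between hinge kinks the total hazard is polynomial of this degree, so
    // n-point Gauss-Legendre (exact to degree 2n-1) integrates it exactly
    int maxdeg = std::max(std::max(np * std::max(nf, 1), nd1 * std::max(nd2, 1)),
                          std::max(nf, nd2));
    int npts = std::max(2, (maxdeg + 2) / 2);
    gauss_legendre(npts, glx, glw);
  }

  inline double mu_i(int i, double t) const {
    if (nf == 0) return 0.0;
    double acc = 0.0;
    for (int n = nf; n >= 1; --n) acc = acc * t + mu[i * nf + (n - 1)];
    return acc * t;
  }
  // inner argument of f_i given cached weighted deficit sum Wd_i
  inline double inner_i(int i, double Wdi, double t) const {
    return Wdi + mu_i(i, t);
  }
  // damage-rate series evaluated at f (before the outer hinge)
  inline double gseries_i(int i, double f) const {
    double acc = 0.0;
    for (int n = np; n >= 0; --n) acc = acc * f + gam[i * (np + 1) + n];
    return acc;
  }
  inline double rate_i(int i, double Wdi, double t) const {
    double a = inner_i(i, Wdi, t);
    double f = a > 0.0 ? a : 0.0;
    double g = gseries_i(i, f);
    return g > 0.0 ? g : 0.0;
  }
  inline double eta_t(double t) const {
    double acc = 0.0;
    for (int n = nd2; n >= 0; --n) acc = acc * t + eta[n];
    return acc;
  }
  inline double mort_inner(double Bd, double t) const { return Bd + eta_t(t); }
  inline double dseries(double x) const {
    double acc = 0.0;
    for (int n = nd1; n >= 0; --n) acc = acc * x + alpha[n];
    return acc;
  }
  inline double mort_rate(double Bd, double t) const {
    double a = mort_inner(Bd, t);
    double x = a > 0.0 ? a : 0.0;
    double g = dseries(x);
    return g > 0.0 ? g : 0.0;
  }
};

static Model unpack_model(const List &pl) {
  Model m;
  m.N = as<int>(pl["N"]);
  m.nf = as<int>(pl["nf"]);
  m.np = as<int>(pl["np"]);
  m.nd1 = as<int>(pl["nd1"]);
  m.nd2 = as<int>(pl["nd2"]);
  NumericMatrix W = pl["W"], mu = pl["mu"], gam = pl["gamma"];
  m.W.resize(m.N * m.N);
  for (int i = 0; i < m.N; ++i)
    for (int j = 0; j < m.N; ++j) m.W[i * m.N + j] = W(i, j);
  m.mu.resize(m.N * m.nf);
  for (int i = 0; i < m.N; ++i)
    for (int n = 0; n < m.nf; ++n) m.mu[i * m.nf + n] = mu(i, n);
  m.gam.resize(m.N * (m.np + 1));
  for (int i = 0; i < m.N; ++i)
    for (int n = 0; n <= m.np; ++n) m.gam[i * (m.np + 1) + n] = gam(i, n);
  m.beta = as<std::vector<double>>(pl["beta"]);
  m.alpha = as<std::vector<double>>(pl["alpha"]);
  m.eta = as<std::vector<double>>(pl["eta"]);
  m.init_quadrature();
  return m;
}

// ---- simulation core --------------------------------------------------------

struct SimState {
  std::vector<int> d;
  std::vector<double> Wd;  // sum_j W[i][j] d_j for every i
  double Bd;               // sum_j beta_j d_j
  int n_undamaged;
};

static void init_state(const Model &m, const std::vector<int> &d0,
                       SimState &st) {
  st.d = d0;
  st.Wd.assign(m.N, 0.0);
  st.Bd = 0.0;
  st.n_undamaged = 0;
  for (int j = 0; j < m.N; ++j) {
    if (d0[j]) {
      for (int i = 0; i < m.N; ++i) st.Wd[i] += m.W[i * m.N + j];
      st.Bd += m.beta[j];
    } else {
      ++st.n_undamaged;
    }
  }
}

static inline void apply_damage(const Model &m, SimState &st, int j) {
  st.d[j] = 1;
  for (int i = 0; i < m.N; ++i) st.Wd[i] += m.W[i * m.N + j];
  st.Bd += m.beta[j];
  --st.n_undamaged;
}

static inline double total_rate(const Model &m, const SimState &st, double t) {
  double tot = 0.0;
  for (int i = 0; i < m.N; ++i)
    if (!st.d[i]) tot += m.rate_i(i, st.Wd[i], t);
  tot += m.mort_rate(st.Bd, t);
  return tot;
}

// root of a monotone non-decreasing function with g(lo) < 0 < g(hi), by the
// Illinois variant of regula falsi (guaranteed bracketing, superlinear on
// smooth functions), to an absolute tolerance in t
template <typename F>
static double bisect_root(F g, double lo, double hi, double tol = 1e-9) {
  double flo = g(lo), fhi = g(hi);
  if (flo >= 0.0) return lo;
  if (fhi <= 0.0) return hi;
  int side = 0;
  for (int it = 0; it < 100 && hi - lo > tol; ++it) {
    double mid = (flo == fhi) ? 0.5 * (lo + hi)
                              : lo + (hi - lo) * (-flo) / (fhi - flo);
    // keep the secant point strictly interior
    if (mid <= lo || mid >= hi) mid = 0.5 * (lo + hi);
    double fm = g(mid);
    if (fm < 0.0) {
      lo = mid; flo = fm;
      if (side == -1) fhi *= 0.5;  // Illinois weighting
      side = -1;
    } else {
      hi = mid; fhi = fm;
      if (side == 1) flo *= 0.5;
      side = 1;
    }
  }
  return 0.5 * (lo + hi);
}

// hinge-kink breakpoints of the total hazard in (t0, T), given frozen deficits
static void breakpoints(const Model &m, const SimState &st, double t0,
                        double T, std::vector<double> &bp) {
  bp.clear();
  for (int i = 0; i < m.N; ++i) {
    if (st.d[i]) continue;
    double a0 = m.inner_i(i, st.Wd[i], t0), aT = m.inner_i(i, st.Wd[i], T);
    if (a0 < 0.0 && aT > 0.0) {
      bp.push_back(bisect_root(
          [&](double t) { return m.inner_i(i, st.Wd[i], t); }, t0, T, 1e-7));
    }
    double g0 = m.gseries_i(i, std::max(a0, 0.0));
    double gT = m.gseries_i(i, std::max(aT, 0.0));
    if (g0 < 0.0 && gT > 0.0) {
      bp.push_back(bisect_root(
          [&](double t) {
            return m.gseries_i(i, std::max(m.inner_i(i, st.Wd[i], t), 0.0));
          }, t0, T, 1e-7));
    }
  }
  double a0 = m.mort_inner(st.Bd, t0), aT = m.mort_inner(st.Bd, T);
  if (a0 < 0.0 && aT > 0.0) {
    bp.push_back(bisect_root(
        [&](double t) { return m.mort_inner(st.Bd, t); }, t0, T, 1e-7));
  }
  double g0 = m.dseries(std::max(a0, 0.0)), gT = m.dseries(std::max(aT, 0.0));
  if (g0 < 0.0 && gT > 0.0) {
    bp.push_back(bisect_root(
        [&](double t) {
          return m.dseries(std::max(m.mort_inner(st.Bd, t), 0.0));
        }, t0, T, 1e-7));
  }
  std::sort(bp.begin(), bp.end());
}

static inline double gl_integral(const Model &m, const SimState &st, double a,
                                 double b) {
  double c = 0.5 * (a + b), h = 0.5 * (b - a), acc = 0.0;
  for (size_t k = 0; k < m.glx.size(); ++k)
    acc += m.glw[k] * total_rate(m, st, c + h * m.glx[k]);
  return h * acc;
}

// draw the next event time by hazard inversion; returns T if none by horizon
static double draw_event_time(const Model &m, const SimState &st, double t0,
                              double T, double u,
                              std::vector<double> &bp_scratch) {
  breakpoints(m, st, t0, T, bp_scratch);
  bp_scratch.push_back(T);
  double cum = 0.0, a = t0;
  for (double b : bp_scratch) {
    if (b <= a) continue;
    double I = gl_integral(m, st, a, b);
    if (cum + I < u) {
      cum += I;
      a = b;
      continue;
    }
    double target = u - cum;
    return bisect_root(
        [&](double tau) { return gl_integral(m, st, a, tau) - target; }, a, b,
        1e-9);
  }
  return T;
}

// Simulate one individual. Records damage events (age, 0-based node) and sets
// death_age (= +Inf if alive at the horizon).
static void simulate_core(const Model &m, double start_age,
                          const std::vector<int> &d0, double horizon, Rng &rng,
                          std::vector<double> &ev_age, std::vector<int> &ev_node,
                          double &death_age) {
  SimState st;
  init_state(m, d0, st);
  std::vector<double> bp;
  double t = start_age;
  death_age = R_PosInf;
  while (t < horizon) {
    double u = rng.rexp();
    double te = draw_event_time(m, st, t, horizon, u, bp);
    if (te >= horizon) return;  // alive at horizon
    // pick the event: undamaged nodes in index order, mortality last
    double tot = total_rate(m, st, te);
    if (tot <= 0.0) { t = te + 1e-9; continue; }  // float-edge guard
    double r = rng.unif() * tot, cum = 0.0;
    int picked = -1;  // -1 = mortality
    for (int i = 0; i < m.N; ++i) {
      if (st.d[i]) continue;
      cum += m.rate_i(i, st.Wd[i], te);
      if (r < cum) { picked = i; break; }
    }
    if (picked < 0) {
      death_age = te;
      return;
    }
    apply_damage(m, st, picked);
    ev_age.push_back(te);
    ev_node.push_back(picked);
    t = te;
  }
}

// ---- exported entry points --------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_one(List pl, double start_age, IntegerVector init_d,
                      double horizon, double seed, double stream) {
  Model m = unpack_model(pl);
  std::vector<int> d0(init_d.begin(), init_d.end());
  Rng rng((uint64_t)seed, (uint64_t)stream);
  std::vector<double> ev_age;
  std::vector<int> ev_node;
  double death_age;
  simulate_core(m, start_age, d0, horizon, rng, ev_age, ev_node, death_age);
  IntegerVector nodes(ev_node.size());
  for (size_t k = 0; k < ev_node.size(); ++k) nodes[k] = ev_node[k] + 1;
  return List::create(_["event_age"] = wrap(ev_age), _["event_node"] = nodes,
                      _["death_age"] = death_age);
}

// Death ages of n replicates from one baseline (Inf = alive at horizon).
// [[Rcpp::export]]
NumericVector cpp_sim_death_ages(List pl, double start_age,
                                 IntegerVector init_d, double horizon, int n,
                                 double seed, double stream0) {
  Model m = unpack_model(pl);
  std::vector<int> d0(init_d.begin(), init_d.end());
  NumericVector out(n);
  std::vector<double> ev_age;
  std::vector<int> ev_node;
  for (int k = 0; k < n; ++k) {
    Rng rng((uint64_t)seed, (uint64_t)(stream0 + k));
    ev_age.clear();
    ev_node.clear();
    double death_age;
    simulate_core(m, start_age, d0, horizon, rng, ev_age, ev_node, death_age);
    out[k] = death_age;
  }
  return out;
}

// Birth-cohort pool: n individuals from age 0, all-zero state. Returns the
// joint-state code (sum d_i 2^(i-1)) of each individual at each query age
// (-1 once dead) plus death ages. Query ages are typically bin midpoints.
// [[Rcpp::export]]
List cpp_sim_pool_codes(List pl, int n, double horizon,
                        NumericVector query_ages, double seed,
                        double stream0) {
  Model m = unpack_model(pl);
  if (m.N > 25) stop("joint-state tallies limited to N <= 25");
  int nq = query_ages.size();
  IntegerMatrix codes(n, nq);
  NumericVector death(n);
  std::vector<int> d0(m.N, 0);
  std::vector<double> ev_age;
  std::vector<int> ev_node;
  for (int k = 0; k < n; ++k) {
    Rng rng((uint64_t)seed, (uint64_t)(stream0 + k));
    ev_age.clear();
    ev_node.clear();
    double death_age;
    simulate_core(m, 0.0, d0, horizon, rng, ev_age, ev_node, death_age);
    death[k] = death_age;
    // right-continuous state reconstruction at each query age
    for (int q = 0; q < nq; ++q) {
      double tq = query_ages[q];
      if (!(death_age > tq)) { codes(k, q) = -1; continue; }
      int code = 0;
      for (size_t e = 0; e < ev_age.size(); ++e)
        if (ev_age[e] <= tq) code |= (1 << ev_node[e]);
      codes(k, q) = code;
    }
  }
  return List::create(_["codes"] = codes, _["death_age"] = death);
}

// Batched per-record survival fractions: for record m, simulate n forward
// trajectories from (base_age[m], d[m,]) and return the fraction with death
// age beyond eval_lo[m] and eval_hi[m] (1.0 when the eval age is at or below
// baseline). Stream block per record keeps random numbers common across
// parameter values.
// [[Rcpp::export]]
NumericMatrix cpp_record_survfrac(List pl, NumericVector base_age,
                                  IntegerMatrix dmat, NumericVector eval_lo,
                                  NumericVector eval_hi, double horizon, int n,
                                  double seed, NumericVector stream0) {
  Model m = unpack_model(pl);
  int M = base_age.size();
  NumericMatrix out(M, 2);
  std::vector<int> d0(m.N);
  std::vector<double> ev_age;
  std::vector<int> ev_node;
  for (int r = 0; r < M; ++r) {
    for (int j = 0; j < m.N; ++j) d0[j] = dmat(r, j);
    // only survival up to the evaluation ages is needed, so stop there
    double hz = std::min(horizon,
                         std::max(eval_lo[r], eval_hi[r]) + 1e-9);
    int nlo = 0, nhi = 0;
    for (int k = 0; k < n; ++k) {
      Rng rng((uint64_t)seed, (uint64_t)(stream0[r] + k));
      ev_age.clear();
      ev_node.clear();
      double death_age;
      simulate_core(m, base_age[r], d0, hz, rng, ev_age, ev_node,
                    death_age);
      if (death_age > eval_lo[r]) ++nlo;
      if (death_age > eval_hi[r]) ++nhi;
    }
    out(r, 0) = eval_lo[r] <= base_age[r] ? 1.0 : (double)nlo / n;
    out(r, 1) = eval_hi[r] <= base_age[r] ? 1.0 : (double)nhi / n;
  }
  return out;
}

// Cross-sectional sampler support: one life from birth per drawn baseline
// age; returns survival to baseline, the state code at baseline, the
// recorded survival age min(death, baseline + window) and the censor flag.
// [[Rcpp::export]]
List cpp_sample_records(List pl, NumericVector baseline_ages, double window,
                        double seed, double stream0) {
  Model m = unpack_model(pl);
  if (m.N > 25) stop("state codes limited to N <= 25");
  int n = baseline_ages.size();
  LogicalVector alive(n);
  IntegerVector code(n);
  NumericVector surv(n);
  IntegerVector cens(n);
  std::vector<int> d0(m.N, 0);
  std::vector<double> ev_age;
  std::vector<int> ev_node;
  for (int k = 0; k < n; ++k) {
    double t0 = baseline_ages[k], hz = t0 + window;
    Rng rng((uint64_t)seed, (uint64_t)(stream0 + k));
    ev_age.clear();
    ev_node.clear();
    double death_age;
    simulate_core(m, 0.0, d0, hz, rng, ev_age, ev_node, death_age);
    if (!(death_age > t0)) { alive[k] = false; continue; }
    alive[k] = true;
    int c = 0;
    for (size_t e = 0; e < ev_age.size(); ++e)
      if (ev_age[e] <= t0) c |= (1 << ev_node[e]);
    code[k] = c;
    if (death_age <= hz) {
      surv[k] = death_age;
      cens[k] = 0;
    } else {
      surv[k] = hz;
      cens[k] = 1;
    }
  }
  return List::create(_["alive"] = alive, _["code"] = code,
                      _["surv_age"] = surv, _["censored"] = cens);
}
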