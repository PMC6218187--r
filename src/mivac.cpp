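// Core accumulator engine: a race of four leaky, mutually inhibiting
// accumulators under a linearly collapsing bound, with value-dependent
// fixations, an additive boost for the fixated accumulator, and probabilistic
// identification of the unavailable distractor.  Simulation-based likelihoods
// need millions of trial simulations per fit, hence compiled code and a fast
// local RNG (xoshiro256++ with a ziggurat normal sampler) seeded explicitly so
// results are reproducible and independent of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- RNG -------

struct Rng {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  explicit Rng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
    // avoid the all-zero state
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 1;
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0,1)
  double unif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return u > 0.0 ? u : 0x1.0p-53;
  }

  int32_t i32() { return (int32_t)(next() >> 32); }
};

// ---------------------------------------------- ziggurat normal sampler -----
// Marsaglia & Tsang (2000), 128 layers.

static double   zig_wn[128], zig_fn[128];
static uint32_t zig_kn[128];
static bool     zig_ready = false;

void zig_init() {
  const double m1 = 2147483648.0;
  double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
  double q = vn / std::exp(-0.5 * dn * dn);
  zig_kn[0] = (uint32_t)((dn / q) * m1);
  zig_kn[1] = 0;
  zig_wn[0] = q / m1;
  zig_wn[127] = dn / m1;
  zig_fn[0] = 1.0;
  zig_fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; i--) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    zig_kn[i + 1] = (uint32_t)((dn / tn) * m1);
    tn = dn;
    zig_fn[i] = std::exp(-0.5 * dn * dn);
    zig_wn[i] = dn / m1;
  }
  zig_ready = true;
}

double znorm(Rng &rng) {
  const double r = 3.442619855899;
  int32_t hz = rng.i32();
  uint32_t iz = (uint32_t)hz & 127u;
  for (;;) {
    uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (ahz < zig_kn[iz]) return hz * zig_wn[iz];
    double x = hz * zig_wn[iz];
    if (iz == 0) {  // tail
      double y;
      do {
        x = -std::log(rng.unif()) * (1.0 / r);
        y = -std::log(rng.unif());
      } while (y + y < x * x);
      return hz > 0 ? r + x : -(r + x);
    }
    if (zig_fn[iz] + rng.unif() * (zig_fn[iz - 1] - zig_fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
    hz = rng.i32();
    iz = (uint32_t)hz & 127u;
  }
}

// -------------------------------------------------------------- engine ------

// dyn constants, packed by the R side:
// 0 leak, 1 inhibition, 2 theta0, 3 theta_end, 4 dt_ms, 5 fixation_period_ms,
// 6 detection_period_ms, 7 horizon_ms, 8 nondecision_ms
struct Dyn {
  double leak, inh, theta0, theta_end, dt, fix_ms, det_ms, horizon_ms, nondec;
  int n_steps, fix_steps, det_steps;
  explicit Dyn(const NumericVector &d) {
    leak = d[0]; inh = d[1]; theta0 = d[2]; theta_end = d[3]; dt = d[4];
    fix_ms = d[5]; det_ms = d[6]; horizon_ms = d[7]; nondec = d[8];
    n_steps = (int)std::lround(horizon_ms / dt);
    fix_steps = (int)std::lround(fix_ms / dt);
    det_steps = (int)std::lround(det_ms / dt);
  }
};

struct FixRecord {
  std::vector<int> target;
  std::vector<double> onset, duration;
};

// fixation target draw: softmax(gamma * value / sum(value)), D zeroed once
// identified; uniform when all values are zero
int draw_fixation(const double *fixval, bool d_ident, double gamma, Rng &rng) {
  double fv[4];
  for (int i = 0; i < 4; ++i) fv[i] = fixval[i];
  if (d_ident) fv[2] = 0.0;
  double s = fv[0] + fv[1] + fv[2] + fv[3];
  double p[4];
  if (s <= 0.0 || gamma == 0.0) {
    p[0] = p[1] = p[2] = p[3] = 0.25;
  } else {
    double mx = -1e300;
    for (int i = 0; i < 4; ++i) {
      p[i] = gamma * fv[i] / s;
      if (p[i] > mx) mx = p[i];
    }
    double tot = 0.0;
    for (int i = 0; i < 4; ++i) { p[i] = std::exp(p[i] - mx); tot += p[i]; }
    for (int i = 0; i < 4; ++i) p[i] /= tot;
  }
  double u = rng.unif(), c = 0.0;
  for (int i = 0; i < 3; ++i) { c += p[i]; if (u < c) return i; }
  return 3;
}

// one trial; returns outcome 0 HV, 1 LV, 2 D, 3 EMPTY, 4 MISS
// rt_ms set to crossing time + nondecision (or -1 for a miss)
// theta: precomputed bound per step (length n_steps), theta[k] at time (k+1)*dt
int run_trial(const double *input, const double *fixval, bool d_present,
              double sigma, double gamma, double beta, double pi_p,
              const Dyn &dyn, const double *theta, bool beta_on_empty,
              Rng &rng, double *rt_ms, FixRecord *rec,
              const double *fixdur /* 4x4 meanlog1, sdlog1, meanlogm, sdlogm
                                      by option row; NULL = fixed schedule */) {
  double A[4] = {0.0, 0.0, 0.0, 0.0};
  bool d_ident = false;
  int fixated = -1;
  int fix_change = 0;       // step index at which the next fixation is drawn
  int fix_count = 0;
  int next_det = dyn.det_steps;   // first identification check at 100 ms
  double fix_onset = 0.0;
  double I[4] = {input[0], input[1], input[2], input[3]};

  for (int k = 0; k < dyn.n_steps; ++k) {
    // (1) fixation update at its period boundary (first fixation at t = 0)
    if (k == fix_change) {
      if (rec && fixated >= 0) {
        rec->target.push_back(fixated);
        rec->onset.push_back(fix_onset);
        rec->duration.push_back(k * dyn.dt - fix_onset);
      }
      if (fixated >= 0) I[fixated] = d_ident && fixated == 2 ? 0.0 : input[fixated];
      fixated = draw_fixation(fixval, d_ident, gamma, rng);
      fix_onset = k * dyn.dt;
      if (fixdur) {
        int col = (fix_count == 0) ? 0 : 2;
        double ml = fixdur[fixated + 4 * col];
        double sl = fixdur[fixated + 4 * (col + 1)];
        double dur = std::exp(ml + sl * znorm(rng));
        int steps = (int)std::lround(dur / dyn.dt);
        if (steps < 1) steps = 1;
        fix_change = k + steps;
      } else {
        fix_change = k + dyn.fix_steps;
      }
      ++fix_count;
      bool empty_target = (fixated == 3) || (fixated == 2 && !d_present);
      if (beta_on_empty || !empty_target)
        I[fixated] = (d_ident && fixated == 2 ? 0.0 : input[fixated]) + beta;
    }
    // (2) distractor-identification check from the reveal time onward
    if (d_present && !d_ident && k == next_det) {
      next_det += dyn.det_steps;
      if (pi_p >= 1.0 || rng.unif() < pi_p) {
        d_ident = true;
        I[2] = fixated == 2 ? I[2] - input[2] : 0.0;
      }
    }
    // (3, 4) leak + mutual inhibition + input + noise
    double S = A[0] + A[1] + A[2] + A[3];
    double mx = -1e300;
    int arg = 0;
    for (int i = 0; i < 4; ++i) {
      double a = dyn.leak * A[i] + dyn.inh * (S - A[i]) + I[i];
      if (sigma > 0.0) a += sigma * znorm(rng);
      A[i] = a;
      if (a > mx) { mx = a; arg = i; }
    }
    // (5) bound check at the new time
    if (mx >= theta[k]) {
      int nmax = 0;
      for (int i = 0; i < 4; ++i) if (A[i] == mx) ++nmax;
      if (nmax > 1) {  // residual tie: uniform among the tied maxima
        int pick = (int)(rng.unif() * nmax);
        int seen = 0;
        for (int i = 0; i < 4; ++i)
          if (A[i] == mx && seen++ == pick) { arg = i; break; }
      }
      *rt_ms = (k + 1) * dyn.dt + dyn.nondec;
      if (rec && fixated >= 0) {
        rec->target.push_back(fixated);
        rec->onset.push_back(fix_onset);
        rec->duration.push_back((k + 1) * dyn.dt - fix_onset);
      }
      if (arg == 2 && !d_present) return 3;
      if (arg == 3) return 3;
      return arg;
    }
  }
  *rt_ms = -1.0;
  if (rec && fixated >= 0) {
    rec->target.push_back(fixated);
    rec->onset.push_back(fix_onset);
    rec->duration.push_back(dyn.n_steps * dyn.dt - fix_onset);
  }
  return 4;
}

std::vector<double> theta_schedule(const Dyn &dyn) {
  std::vector<double> theta(dyn.n_steps);
  for (int k = 0; k < dyn.n_steps; ++k)
    theta[k] = dyn.theta0 -
      (dyn.theta0 - dyn.theta_end) * ((k + 1) * dyn.dt) / dyn.horizon_ms;
  return theta;
}

}  // namespace

// ------------------------------------------------------------ exports -------

// Outcome-category counts per trial: n_trials x 5 matrix (HV, LV, D, EMPTY,
// MISS) from `nsims` simulations of each trial.
// [[Rcpp::export]]
IntegerMatrix cpp_outcome_counts(NumericMatrix inputs, NumericMatrix fixvals,
                                 LogicalVector d_present, NumericVector pars,
                                 NumericVector dyn_const, int nsims,
                                 double seed, bool beta_on_empty) {
  if (!zig_ready) zig_init();
  Dyn dyn(dyn_const);
  int n = inputs.nrow();
  IntegerMatrix counts(n, 5);
  std::vector<double> theta = theta_schedule(dyn);
  Rng rng((uint64_t)seed);
  double rt;
  for (int t = 0; t < n; ++t) {
    double in[4] = {inputs(t, 0), inputs(t, 1), inputs(t, 2), inputs(t, 3)};
    double fv[4] = {fixvals(t, 0), fixvals(t, 1), fixvals(t, 2), fixvals(t, 3)};
    bool dp = d_present[t];
    for (int s = 0; s < nsims; ++s) {
      int o = run_trial(in, fv, dp, pars[0], pars[1], pars[2], pars[3], dyn,
                        theta.data(), beta_on_empty, rng, &rt, nullptr,
                        nullptr);
      counts(t, o)++;
    }
  }
  return counts;
}

// Clipped simulation-based log-likelihood for a batch of parameter vectors
// (rows of par_mat: sigma, gamma, beta, pi).  The same seed is reused for
// every row (common random numbers), so the likelihood surface is
// deterministic given the seed.
// [[Rcpp::export]]
NumericVector cpp_loglik_batch(NumericMatrix par_mat, NumericMatrix inputs,
                               NumericMatrix fixvals, LogicalVector d_present,
                               IntegerVector observed, NumericVector dyn_const,
                               int nsims, double floor_p, double ceil_p,
                               double seed, bool beta_on_empty) {
  if (!zig_ready) zig_init();
  Dyn dyn(dyn_const);
  int n = inputs.nrow(), m = par_mat.nrow();
  NumericVector out(m);
  std::vector<double> theta = theta_schedule(dyn);
  double rt;
  for (int r = 0; r < m; ++r) {
    Rng rng((uint64_t)seed);
    double sg = par_mat(r, 0), gm = par_mat(r, 1), bt = par_mat(r, 2),
           pp = par_mat(r, 3);
    double ll = 0.0;
    for (int t = 0; t < n; ++t) {
      double in[4] = {inputs(t, 0), inputs(t, 1), inputs(t, 2), inputs(t, 3)};
      double fv[4] = {fixvals(t, 0), fixvals(t, 1), fixvals(t, 2),
                      fixvals(t, 3)};
      bool dp = d_present[t];
      int cnt = 0;
      for (int s = 0; s < nsims; ++s) {
        int o = run_trial(in, fv, dp, sg, gm, bt, pp, dyn, theta.data(),
                          beta_on_empty, rng, &rt, nullptr, nullptr);
        if (o == observed[t]) ++cnt;
      }
      double p = (double)cnt / nsims;
      if (p < floor_p) p = floor_p;
      if (p > ceil_p) p = ceil_p;
      ll += std::log(p);
    }
    out[r] = ll;
    if (m > 1 && r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Grid search with exact branch-and-bound pruning: a candidate whose partial
// log-likelihood plus the best attainable remainder (log ceiling per
// remaining trial) already falls below the worst member of the current
// top-`pool_size` set cannot enter the final pool, so it is abandoned.  The
// same seed per candidate (common random numbers) makes the retained values
// identical to brute force.  Pruned candidates report -Inf.
// [[Rcpp::export]]
NumericVector cpp_grid_search(NumericMatrix par_mat, NumericMatrix inputs,
                              NumericMatrix fixvals, LogicalVector d_present,
                              IntegerVector observed, NumericVector dyn_const,
                              int nsims, double floor_p, double ceil_p,
                              double seed, bool beta_on_empty,
                              int pool_size) {
  if (!zig_ready) zig_init();
  Dyn dyn(dyn_const);
  int n = inputs.nrow(), m = par_mat.nrow();
  NumericVector out(m);
  std::vector<double> theta = theta_schedule(dyn);
  std::vector<double> pool;  // smallest element = current cutoff
  const double log_ceil = std::log(ceil_p);
  double rt;
  for (int r = 0; r < m; ++r) {
    Rng rng((uint64_t)seed);
    double sg = par_mat(r, 0), gm = par_mat(r, 1), bt = par_mat(r, 2),
           pp = par_mat(r, 3);
    double cutoff = (int)pool.size() >= pool_size
      ? *std::min_element(pool.begin(), pool.end()) : -INFINITY;
    double ll = 0.0;
    bool pruned = false;
    for (int t = 0; t < n; ++t) {
      double in[4] = {inputs(t, 0), inputs(t, 1), inputs(t, 2), inputs(t, 3)};
      double fv[4] = {fixvals(t, 0), fixvals(t, 1), fixvals(t, 2),
                      fixvals(t, 3)};
      bool dp = d_present[t];
      int cnt = 0;
      for (int s = 0; s < nsims; ++s) {
        int o = run_trial(in, fv, dp, sg, gm, bt, pp, dyn, theta.data(),
                          beta_on_empty, rng, &rt, nullptr, nullptr);
        if (o == observed[t]) ++cnt;
      }
      double p = (double)cnt / nsims;
      if (p < floor_p) p = floor_p;
      if (p > ceil_p) p = ceil_p;
      ll += std::log(p);
      if (ll + (n - 1 - t) * log_ceil < cutoff) { pruned = true; break; }
    }
    if (pruned) {
      out[r] = -INFINITY;
    } else {
      out[r] = ll;
      if ((int)pool.size() < pool_size) {
        pool.push_back(ll);
      } else {
        auto mn = std::min_element(pool.begin(), pool.end());
        if (ll > *mn) *mn = ll;
      }
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full behavioral simulation: choices, RTs, and (optionally) fixation
// streams.  fixdur, when given, is a 4x4 matrix (rows HV, LV, D, EMPTY;
// columns meanlog/sdlog for first fixations then meanlog/sdlog for middle
// fixations) of log-normal fixation-duration parameters replacing the fixed
// schedule.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix inputs, NumericMatrix fixvals,
                  LogicalVector d_present, NumericVector pars,
                  NumericVector dyn_const, int nreps, double seed,
                  bool beta_on_empty, bool record_fix,
                  Nullable<NumericMatrix> fixdur) {
  if (!zig_ready) zig_init();
  Dyn dyn(dyn_const);
  int n = inputs.nrow();
  std::vector<int> trial, rep, resp;
  std::vector<double> rt_out;
  std::vector<int> f_trial, f_rep, f_index, f_target;
  std::vector<double> f_onset, f_dur;
  const double *fd = nullptr;
  NumericMatrix fdm;
  if (fixdur.isNotNull()) {
    fdm = NumericMatrix(fixdur);
    fd = fdm.begin();
  }
  Rng rng((uint64_t)seed);
  std::vector<double> theta = theta_schedule(dyn);
  double rt;
  for (int t = 0; t < n; ++t) {
    double in[4] = {inputs(t, 0), inputs(t, 1), inputs(t, 2), inputs(t, 3)};
    double fv[4] = {fixvals(t, 0), fixvals(t, 1), fixvals(t, 2), fixvals(t, 3)};
    bool dp = d_present[t];
    for (int r = 0; r < nreps; ++r) {
      FixRecord rec;
      int o = run_trial(in, fv, dp, pars[0], pars[1], pars[2], pars[3], dyn,
                        theta.data(), beta_on_empty, rng, &rt,
                        record_fix ? &rec : nullptr, fd);
      trial.push_back(t + 1);
      rep.push_back(r + 1);
      resp.push_back(o);
      rt_out.push_back(rt < 0 ? NA_REAL : rt);
      if (record_fix) {
        for (size_t i = 0; i < rec.target.size(); ++i) {
          f_trial.push_back(t + 1);
          f_rep.push_back(r + 1);
          f_index.push_back((int)i + 1);
          f_target.push_back(rec.target[i]);
          f_onset.push_back(rec.onset[i]);
          f_dur.push_back(rec.duration[i]);
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  List out = List::create(
      _["trial"] = wrap(trial), _["rep"] = wrap(rep),
      _["response"] = wrap(resp), _["rt_ms"] = wrap(rt_out));
  if (record_fix)
    out["fixations"] = List::create(
        _["trial"] = wrap(f_trial), _["rep"] = wrap(f_rep),
        _["fix_index"] = wrap(f_index), _["target"] = wrap(f_target),
        _["onset_ms"] = wrap(f_onset), _["duration_ms"] = wrap(f_dur));
  return out;
}
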