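// Core numerics for the drift-diffusion model:
//  - first-passage-time density of the Wiener process between two absorbing
//    boundaries (small-time / large-time series with an accuracy-based switch)
//  - likelihood of the full DDM (analytic integral over between-trial drift
//    variability; Gauss-Legendre quadrature over start point and
//    non-decision time)
//  - Euler-Maruyama trial simulator with per-trial RNG substreams so that
//    the same trial sees the same noise at every candidate threshold
//    (common random numbers for the reward-rate grid search)
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>
using namespace Rcpp;

static const double WFPT_EPS = 1e-7;  // series truncation tolerance

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// engine for trial `trial` under master seed `seed`: independent substreams,
// identical for a given (seed, trial) pair regardless of other settings
static inline std::mt19937_64 trial_engine(uint64_t seed, uint64_t trial) {
  return std::mt19937_64(splitmix64(splitmix64(seed) ^ (0x9E3779B97F4A7C15ULL * (trial + 1))));
}

// density of the first passage time at the LOWER boundary, time normalized:
// tau = t / a^2, w = relative start. Standardized (v = 0, a = 1) kernel.
static double wfpt_kernel(double tau, double w) {
  if (tau <= 0.0) return 0.0;
  // choose series by the number of terms each needs for tolerance WFPT_EPS
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * WFPT_EPS < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * WFPT_EPS * std::sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tau * WFPT_EPS < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * WFPT_EPS) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }
  double p = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2), hi = ((K - 1) % 2 == 0) ? (K - 1) / 2 : (K + 1) / 2;
    for (int k = lo; k <= hi; ++k) {
      double u = w + 2.0 * k;
      p += u * std::exp(-u * u / (2.0 * tau));
    }
    p /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;
}

// density (not log) of decision time t at a boundary, full drift-variability
// integral included (sv = 0 gives the fixed-drift Wiener density).
// upper: TRUE for the upper boundary. All quantities pre-scaled by s.
static double ddm_density_sv(double t, bool upper, double v, double a,
                             double w, double sv) {
  if (t <= 0.0) return 0.0;
  double vv = v, ww = w;
  if (upper) { vv = -v; ww = 1.0 - w; }
  double kern = wfpt_kernel(t / (a * a), ww);
  if (kern <= 0.0) return 0.0;
  double sv2t = sv * sv * t;
  double expo = (a * a * ww * ww * sv * sv - 2.0 * vv * a * ww - vv * vv * t) /
                (2.0 * (1.0 + sv2t));
  return kern / (a * a) * std::exp(expo) / std::sqrt(1.0 + sv2t);
}

// [[Rcpp::export(name = ".cpp_wfpt_logpdf")]]
NumericVector cpp_wfpt_logpdf(NumericVector t, LogicalVector upper,
                              double v, double a, double z_rel, double s) {
  int n = t.size();
  NumericVector out(n);
  double vs = v / s, as = a / s;
  for (int i = 0; i < n; ++i) {
    bool up = upper.size() == 1 ? upper[0] : upper[i];
    double d = ddm_density_sv(t[i], up, vs, as, z_rel, 0.0);
    out[i] = d > 0.0 ? std::log(d) : R_NegInf;
  }
  return out;
}

// Full-DDM log-likelihood. rt/upper: data; wn/wwt, tn/twt: Gauss-Legendre
// nodes and weights on [-0.5, 0.5] (weights summing to 1) for the start-point
// and non-decision-time uniforms. Per-trial threshold supported through `a`
// (length 1 or length n), for block-varying-threshold models.
// [[Rcpp::export(name = ".cpp_full_ddm_loglik")]]
double cpp_full_ddm_loglik(NumericVector rt, LogicalVector upper,
                           double v, NumericVector a, double z_rel, double ter,
                           double sv, double sz_rel, double ster, double s,
                           NumericVector wn, NumericVector wwt,
                           NumericVector tn, NumericVector twt) {
  int n = rt.size();
  bool a_per_trial = a.size() > 1;
  int nw = (sz_rel > 0.0) ? wn.size() : 1;
  int nt = (ster > 0.0) ? tn.size() : 1;
  double vs = v / s, svs = sv / s;
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double ai = (a_per_trial ? a[i] : a[0]) / s;
    bool up = upper[i];
    double dens = 0.0;
    for (int j = 0; j < nt; ++j) {
      double terj = (nt == 1) ? ter : ter + ster * tn[j];
      double wj = (nt == 1) ? 1.0 : twt[j];
      double tdec = rt[i] - terj;
      if (tdec <= 0.0) continue;
      for (int k = 0; k < nw; ++k) {
        double wk = (nw == 1) ? z_rel : z_rel + sz_rel * wn[k];
        double wwk = (nw == 1) ? 1.0 : wwt[k];
        if (wk <= 0.0 || wk >= 1.0) continue;
        dens += wj * wwk * ddm_density_sv(tdec, up, vs, ai, wk, svs);
      }
    }
    if (dens <= 0.0) return R_NegInf;
    total += std::log(dens);
  }
  return total;
}

struct SimOut {
  int boundary;        // 1 upper, 0 lower, -1 timed out
  double dec_time;
  double ndt;
};

static SimOut sim_one_trial(double v, double a, double z_rel, double ter,
                            double sv, double sz_rel, double ster, double s,
                            double dt, double max_dt, std::mt19937_64& eng) {
  std::normal_distribution<double> norm(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  // between-trial draws come first so that a trial's noise stream lines up
  // across candidate thresholds
  double vt = v + (sv > 0.0 ? sv * norm(eng) : 0.0);
  double w0 = z_rel + (sz_rel > 0.0 ? sz_rel * (unif(eng) - 0.5) : 0.0);
  double ndt = ter + (ster > 0.0 ? ster * (unif(eng) - 0.5) : 0.0);
  double x = w0 * a;
  double sq = s * std::sqrt(dt);
  double s2dt = s * s * dt;
  double t = 0.0;
  SimOut out;
  out.ndt = ndt;
  // Euler-Maruyama with Brownian-bridge crossing detection inside each step:
  // removes the O(sqrt(dt)) first-passage bias of naive endpoint checking.
  // Both bridge uniforms are drawn unconditionally so each trial's RNG stream
  // stays aligned across candidate thresholds (common random numbers).
  while (true) {
    double x_new = x + vt * dt + sq * norm(eng);
    t += dt;
    double u_up = unif(eng), u_lo = unif(eng);
    if (x_new >= a) { out.boundary = 1; out.dec_time = t; return out; }
    if (x_new <= 0.0) { out.boundary = 0; out.dec_time = t; return out; }
    double pu = std::exp(-2.0 * (a - x) * (a - x_new) / s2dt);
    if (u_up < pu) { out.boundary = 1; out.dec_time = t; return out; }
    double pl = std::exp(-2.0 * x * x_new / s2dt);
    if (u_lo < pl) { out.boundary = 0; out.dec_time = t; return out; }
    if (t >= max_dt - 1e-12) { out.boundary = -1; out.dec_time = max_dt; return out; }
    x = x_new;
  }
}

// [[Rcpp::export(name = ".cpp_simulate_trials")]]
List cpp_simulate_trials(double v, double a, double z_rel, double ter,
                         double sv, double sz_rel, double ster, double s,
                         double dt, double max_dt, int n, double seed) {
  IntegerVector boundary(n);
  NumericVector dec(n), rt(n);
  LogicalVector timed(n);
  for (int i = 0; i < n; ++i) {
    std::mt19937_64 eng = trial_engine((uint64_t)seed, (uint64_t)i);
    SimOut o = sim_one_trial(v, a, z_rel, ter, sv, sz_rel, ster, s, dt, max_dt, eng);
    timed[i] = (o.boundary < 0);
    boundary[i] = timed[i] ? NA_INTEGER : o.boundary;
    dec[i] = o.dec_time;
    rt[i] = o.dec_time + o.ndt;
  }
  return List::create(_["boundary"] = boundary, _["decision_time"] = dec,
                      _["rt"] = rt, _["timed_out"] = timed);
}

// Reward rate at each candidate threshold, simulated with common random
// numbers: trial i re-uses its RNG substream at every grid value.
// timeout_as_error: timed-out trials enter as errors at decision time max_dt.
// [[Rcpp::export(name = ".cpp_rr_curve_sim")]]
NumericVector cpp_rr_curve_sim(NumericVector grid, double v, double z_rel,
                               double ter, double sv, double sz_rel,
                               double ster, double s, double dt, double max_dt,
                               int n, double seed, double iti, double fdt,
                               double et, bool timeout_as_error) {
  int G = grid.size();
  NumericVector rr(G);
  for (int g = 0; g < G; ++g) {
    double a = grid[g];
    int n_correct = 0, n_used = 0;
    double sum_rt = 0.0;
    for (int i = 0; i < n; ++i) {
      std::mt19937_64 eng = trial_engine((uint64_t)seed, (uint64_t)i);
      SimOut o = sim_one_trial(v, a, z_rel, ter, sv, sz_rel, ster, s, dt, max_dt, eng);
      if (o.boundary < 0 && !timeout_as_error) continue;
      ++n_used;
      if (o.boundary == 1) ++n_correct;
      sum_rt += o.dec_time + o.ndt;
    }
    if (n_used == 0) { rr[g] = NA_REAL; continue; }
    double pc = (double)n_correct / n_used;
    double mrt = sum_rt / n_used;
    rr[g] = pc / (mrt + iti + fdt + (1.0 - pc) * et);
  }
  return rr;
}
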