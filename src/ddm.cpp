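#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Marsaglia-Tsang ziggurat sampler for standard normals, driven by R's
// unif_rand() so set.seed() fully determines the stream. Roughly 2-3x
// faster than the inversion sampler behind norm_rand(), which dominates
// the cost of path simulation here.
static uint32_t zig_kn[128];
static double zig_wn[128], zig_fn[128];
static bool zig_ready = false;

static void zig_init() {
  const double m1 = 2147483648.0;
  double dn = 3.442619855899, tn = dn;
  const double vn = 9.91256303526217e-3;
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

static inline double zig_norm() {
  const double zig_r = 3.442619855899;
  for (;;) {
    int32_t hz = (int32_t)(uint32_t)(unif_rand() * 4294967296.0);
    int i = hz & 127;
    uint32_t az = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (az < zig_kn[i]) return hz * zig_wn[i];
    if (i == 0) {  // tail
      double x, y;
      do {
        x = -std::log(unif_rand()) / zig_r;
        y = -std::log(unif_rand());
      } while (y + y < x * x);
      return hz > 0 ? zig_r + x : -(zig_r + x);
    }
    double x = hz * zig_wn[i];
    if (zig_fn[i] + unif_rand() * (zig_fn[i - 1] - zig_fn[i]) <
        std::exp(-0.5 * x * x)) {
      return x;
    }
  }
}

// Two-boundary accumulator, one path per element of `drift`.
//
// EA_0 = 0; EA_t = EA_{t-1} + drift + eps_t, eps_t ~ N(0, noise_sd).
// A path terminates at the first step with |EA_t| >= threshold (inclusive
// crossing); `choice` is 1 for the upper boundary, 2 for the lower, and
// NA when max_steps elapses without a crossing (censored path).
// `neural_activity` is sum_{t=0..t'} |EA_t| including the crossing sample
// (the t = 0 term is zero). Uses R's RNG so set.seed() governs results.
//
// [[Rcpp::export]]
DataFrame ddm_simulate_cpp(NumericVector drift, double threshold,
                           double noise_sd, int max_steps) {
  const R_xlen_t n = drift.size();
  if (!zig_ready) zig_init();
  if (threshold <= 0.0) stop("`threshold` must be > 0");
  if (noise_sd <= 0.0) stop("`noise_sd` must be > 0");
  if (max_steps <= 0) stop("`max_steps` must be a positive integer");

  IntegerVector choice(n);
  IntegerVector steps(n);
  NumericVector activity(n);
  LogicalVector capped(n);

  for (R_xlen_t i = 0; i < n; ++i) {
    const double d = drift[i];
    if (!R_finite(d)) stop("non-finite drift at position %d", (int)(i + 1));
    double ea = 0.0, act = 0.0;
    int t = 0, ch = NA_INTEGER;
    bool hit_cap = true;
    while (t < max_steps) {
      ++t;
      ea += d + noise_sd * zig_norm();
      act += std::fabs(ea);
      if (ea >= threshold)  { ch = 1; hit_cap = false; break; }
      if (ea <= -threshold) { ch = 2; hit_cap = false; break; }
    }
    choice[i] = ch;
    steps[i] = t;
    activity[i] = act;
    capped[i] = hit_cap;
  }

  return DataFrame::create(_["choice"] = choice,
                           _["decision_steps"] = steps,
                           _["neural_activity"] = activity,
                           _["hit_max_steps"] = capped);
}

// Boundary-hit tallies only (no per-path output), for large grid
// experiments where the per-cell aggregates are all that is kept.
// Returns, per drift value, counts and sums needed for choice fractions
// and per-choice mean RT / mean activity.
//
// [[Rcpp::export]]
List ddm_tally_cpp(NumericVector drift, int n_sims, double threshold,
                   double noise_sd, int max_steps) {
  const R_xlen_t k = drift.size();
  if (!zig_ready) zig_init();
  if (n_sims <= 0) stop("`n_sims` must be positive");
  if (threshold <= 0.0) stop("`threshold` must be > 0");
  if (noise_sd <= 0.0) stop("`noise_sd` must be > 0");
  if (max_steps <= 0) stop("`max_steps` must be a positive integer");

  IntegerVector n_up(k), n_down(k), n_capped(k);
  NumericVector steps_up(k), steps_down(k), act_up(k), act_down(k);

  for (R_xlen_t j = 0; j < k; ++j) {
    const double d = drift[j];
    if (!R_finite(d)) stop("non-finite drift at position %d", (int)(j + 1));
    for (int s = 0; s < n_sims; ++s) {
      double ea = 0.0, act = 0.0;
      int t = 0;
      int ch = 0;
      while (t < max_steps) {
        ++t;
        ea += d + noise_sd * zig_norm();
        act += std::fabs(ea);
        if (ea >= threshold)  { ch = 1; break; }
        if (ea <= -threshold) { ch = 2; break; }
      }
      if (ch == 1) {
        ++n_up[j]; steps_up[j] += t; act_up[j] += act;
      } else if (ch == 2) {
        ++n_down[j]; steps_down[j] += t; act_down[j] += act;
      } else {
        ++n_capped[j];
      }
    }
  }

  return List::create(_["n_up"] = n_up, _["n_down"] = n_down,
                      _["n_capped"] = n_capped,
                      _["steps_up"] = steps_up, _["steps_down"] = steps_down,
                      _["activity_up"] = act_up,
                      _["activity_down"] = act_down);
}

// First-passage histogram for the simulated likelihood: for each of k
// drift values, simulates n_sims paths and bins decision RT
// (ndt + steps * step_duration) into `n_bins` bins of width `bin_width`
// starting at 0, separately per boundary, with one extra cell per drift
// for censored paths (no crossing before max_steps). Layout per drift:
// [upper bins 1..n_bins | lower bins 1..n_bins | censored].
//
// [[Rcpp::export]]
IntegerVector ddm_fp_histogram_cpp(NumericVector drift, int n_sims,
                                   double threshold, double noise_sd,
                                   int max_steps, double ndt,
                                   double step_duration, double bin_width,
                                   int n_bins) {
  const R_xlen_t k = drift.size();
  if (!zig_ready) zig_init();
  if (n_sims <= 0) stop("`n_sims` must be positive");
  if (threshold <= 0.0) stop("`threshold` must be > 0");
  if (noise_sd <= 0.0) stop("`noise_sd` must be > 0");
  if (bin_width <= 0.0) stop("`bin_width` must be > 0");
  if (n_bins <= 0) stop("`n_bins` must be positive");

  const int row = 2 * n_bins + 1;
  IntegerVector counts(k * row);

  for (R_xlen_t j = 0; j < k; ++j) {
    const double d = drift[j];
    if (!R_finite(d)) stop("non-finite drift at position %d", (int)(j + 1));
    for (int s = 0; s < n_sims; ++s) {
      double ea = 0.0;
      int t = 0, ch = 0;
      while (t < max_steps) {
        ++t;
        ea += d + noise_sd * zig_norm();
        if (ea >= threshold)  { ch = 1; break; }
        if (ea <= -threshold) { ch = 2; break; }
      }
      int cell;
      if (ch == 0) {
        cell = 2 * n_bins;               // censored
      } else {
        const double rt = ndt + t * step_duration;
        int b = (int)(rt / bin_width);   // 0-based bin
        if (b >= n_bins) b = n_bins - 1;
        cell = (ch - 1) * n_bins + b;
      }
      ++counts[j * row + cell];
    }
  }
  return counts;
}

// Simulated log-likelihood with Gaussian-kernel RT smoothing, fully in
// C++: for each of k drift values, simulates n_sims paths, then scores
// each observation against the simulated first-passage sample of its
// stimulus. obs_u is the 1-based stimulus index per observation,
// obs_choice is 1/2 for upper/lower boundary and 0 for a missed
// (censored) trial, obs_rt the observed RT in seconds (ignored for
// missed trials). Observed-trial contributions are
// log(mean_matching kernel(rt_obs - rt_sim) + eps_dens); missed trials
// contribute log((n_censored + 0.5) / (n_sims + 1)).
//
// [[Rcpp::export]]
double ddm_kde_loglik_cpp(NumericVector drift, int n_sims, double threshold,
                          double noise_sd, int max_steps, double ndt,
                          double step_duration, double bw, double eps_dens,
                          IntegerVector obs_u, IntegerVector obs_choice,
                          NumericVector obs_rt) {
  const R_xlen_t k = drift.size();
  const R_xlen_t n_obs = obs_u.size();
  if (!zig_ready) zig_init();
  if (n_sims <= 0) stop("`n_sims` must be positive");
  if (threshold <= 0.0) stop("`threshold` must be > 0");
  if (noise_sd <= 0.0) stop("`noise_sd` must be > 0");
  if (bw <= 0.0) stop("`bw` must be > 0");

  std::vector<double> rt_sim(n_sims);
  std::vector<int> ch_sim(n_sims);
  const double inv2bw2 = 1.0 / (2.0 * bw * bw);
  const double knorm = 1.0 / (bw * std::sqrt(2.0 * M_PI));
  double ll = 0.0;

  for (R_xlen_t j = 0; j < k; ++j) {
    const double d = drift[j];
    if (!R_finite(d)) stop("non-finite drift at position %d", (int)(j + 1));
    int n_cens = 0;
    for (int s = 0; s < n_sims; ++s) {
      double ea = 0.0;
      int t = 0, ch = 0;
      while (t < max_steps) {
        ++t;
        ea += d + noise_sd * zig_norm();
        if (ea >= threshold)  { ch = 1; break; }
        if (ea <= -threshold) { ch = 2; break; }
      }
      ch_sim[s] = ch;
      rt_sim[s] = ndt + t * step_duration;
      if (ch == 0) ++n_cens;
    }
    for (R_xlen_t i = 0; i < n_obs; ++i) {
      if (obs_u[i] != (int)(j + 1)) continue;
      if (obs_choice[i] == 0) {
        ll += std::log((n_cens + 0.5) / (double)(n_sims + 1));
      } else {
        double acc = 0.0;
        const double r = obs_rt[i];
        for (int s = 0; s < n_sims; ++s) {
          if (ch_sim[s] != obs_choice[i]) continue;
          const double z = r - rt_sim[s];
          acc += std::exp(-z * z * inv2bw2);
        }
        ll += std::log(acc * knorm / n_sims + eps_dens);
      }
    }
  }
  return ll;
}
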