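#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Two-channel jump process of the auto-activation circuit:
//   N -> N + burst at rate alpha * (1/f + w^n) / (1 + w^n), w = theta*N/(V*K)
//   N -> N - 1     at rate beta * N
// Direct-method SSA with a dedicated 64-bit Mersenne Twister per call, so
// replicate r of a batch can be seeded as (seed + r) independently of R's
// global RNG state.

static inline double prod_rate(int N, double theta, double alpha_max,
                               double fold, double hill_n, double K,
                               double volume) {
  double xh = theta * (double)N / volume;
  double u = std::pow(xh / K, hill_n);
  return alpha_max * (1.0 / fold + u) / (1.0 + u);
}

// [[Rcpp::export(name = ".ssa_trace_cpp")]]
List ssa_trace_cpp(double alpha_max, double fold, double hill_n, double K,
                   double beta, int burst, double volume,
                   double theta_before, double theta_after, double t_switch,
                   double t_end, int n0, double seed, double max_events) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> times;
  std::vector<int> counts;
  double t = 0.0;
  int N = n0;
  times.push_back(0.0);
  counts.push_back(N);
  bool truncated = false;
  double ev = 0.0;
  while (t < t_end) {
    double theta = (t < t_switch) ? theta_before : theta_after;
    double a1 = prod_rate(N, theta, alpha_max, fold, hill_n, K, volume);
    double a2 = beta * (double)N;
    double a0 = a1 + a2;
    if (a0 <= 0.0) break;
    double u1 = unif(rng);
    while (u1 <= 0.0) u1 = unif(rng);
    double tau = -std::log(u1) / a0;
    // the regulation rate changes at t_switch even without an event
    if (t < t_switch && t + tau > t_switch) {
      t = t_switch;
      continue;
    }
    t += tau;
    if (t > t_end) break;
    if (unif(rng) * a0 < a1) N += burst; else N -= 1;
    times.push_back(t);
    counts.push_back(N);
    ev += 1.0;
    if (ev >= max_events) { truncated = true; break; }
  }
  return List::create(_["times"] = wrap(times), _["counts"] = wrap(counts),
                      _["truncated"] = truncated);
}

// First-passage sampling: replicate r starts at n0[r] with theta = 1 from
// t = 0 and runs until N >= threshold (0 if already above); per-replicate
// RNG substream seeded as seed + r.
// [[Rcpp::export(name = ".ssa_induction_cpp")]]
NumericVector ssa_induction_cpp(double alpha_max, double fold, double hill_n,
                                double K, double beta, int burst,
                                double volume, IntegerVector n0,
                                int threshold, double seed,
                                double max_events) {
  int reps = n0.size();
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    std::mt19937_64 rng((uint64_t)seed + (uint64_t)r);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    double t = 0.0;
    int N = n0[r];
    double ev = 0.0;
    while (N < threshold) {
      double a1 = prod_rate(N, 1.0, alpha_max, fold, hill_n, K, volume);
      double a2 = beta * (double)N;
      double a0 = a1 + a2;
      double u1 = unif(rng);
      while (u1 <= 0.0) u1 = unif(rng);
      t += -std::log(u1) / a0;
      if (unif(rng) * a0 < a1) N += burst; else N -= 1;
      ev += 1.0;
      if (ev >= max_events) { t = NA_REAL; break; }
    }
    out[r] = t;
  }
  return out;
}
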