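// Euler-Maruyama particle simulators. These are deliberately independent of
// the Fokker-Planck engine: they serve as stochastic cross-checks of the
// grid solver and as the generative engine for synthetic sessions.
//
// Barrier crossings between time steps are handled with the standard
// Brownian-bridge correction: given surviving endpoints x0, x1 within a
// step of variance s2, the path crossed the upper bound b with probability
// exp(-2 (b - x0)(b - x1) / s2). Without it, discrete monitoring biases
// absorption probabilities by O(sqrt(dt)).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding; fast, reproducible across platforms
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool has_spare = false;
  double spare = 0.0;
  inline double norm() {  // Box-Muller with caching
    if (has_spare) { has_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u)), a = 6.283185307179586 * v;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

}  // namespace

// Constant-drift DDM run to absorption: returns the number of paths that hit
// the upper bound +B first (out of n_paths). dt is the Euler step; bridge
// enables the Brownian-bridge crossing correction; t_max caps path length
// (survivors are counted by the sign of their final position).
// [[Rcpp::export]]
List ddm_absorb_mc_cpp(double mu, double bound, double sigma2, double init,
                       int n_paths, double dt, double t_max, double seed,
                       bool bridge = true) {
  Rng rng((uint64_t)seed);
  const double sd = std::sqrt(sigma2 * dt);
  const int kmax = (int)std::ceil(t_max / dt);
  long n_up = 0, n_censored = 0;
  for (int p = 0; p < n_paths; ++p) {
    double x = init;
    bool done = false;
    for (int k = 0; k < kmax; ++k) {
      double x1 = x + mu * dt + sd * rng.norm();
      if (x1 >= bound) { ++n_up; done = true; break; }
      if (x1 <= -bound) { done = true; break; }
      if (bridge) {
        double pu = std::exp(-2.0 * (bound - x) * (bound - x1) / (sigma2 * dt));
        double pl = std::exp(-2.0 * (bound + x) * (bound + x1) / (sigma2 * dt));
        double u = rng.unif();
        if (u < pu) { ++n_up; done = true; break; }
        if (u < pu + pl) { done = true; break; }
      }
      x = x1;
    }
    if (!done) { ++n_censored; if (x > 0) ++n_up; }
  }
  return List::create(_["n_up"] = (double)n_up,
                      _["n_censored"] = (double)n_censored);
}

// Particle simulation of the click accumulator (one trial, many particles).
// click_time / click_sign / click_mag give the merged, adaptation-scaled
// train: each click delivers click_sign * click_mag * xi with
// xi ~ N(1, sigma2_s). Between clicks: dx = lambda x dt + sigma_a dW, with
// sticky bounds at +-bound. In fixed-duration mode particles that survive
// to t_total report their final position; hit times are recorded either way.
// Returns per-particle outcome: side (+1 upper, -1 lower, 0 unabsorbed),
// hit time (NA if unabsorbed), final x (NA if absorbed).
// [[Rcpp::export]]
List click_trial_mc_cpp(NumericVector click_time, NumericVector click_sign,
                        NumericVector click_mag, double lambda,
                        double sigma2_a, double sigma2_s, double bound,
                        double init, double t_total, int n_particles,
                        double dt, double seed, bool bridge = true) {
  Rng rng((uint64_t)seed);
  const int n_clicks = click_time.size();
  const int kmax = (int)std::ceil(t_total / dt - 1e-9);
  const double sd = std::sqrt(sigma2_a * dt);
  const double ss = std::sqrt(sigma2_s);
  // click -> step assignment (click in (t_{k-1}, t_k] applied at end of step k)
  std::vector<std::vector<int> > at_step(kmax + 1);
  for (int c = 0; c < n_clicks; ++c) {
    int k = (int)std::ceil(click_time[c] / dt - 1e-12);
    if (k < 1) k = 1;
    if (k > kmax) k = kmax;
    at_step[k].push_back(c);
  }
  IntegerVector side(n_particles);
  NumericVector hit(n_particles), xfin(n_particles);
  for (int p = 0; p < n_particles; ++p) {
    double x = init;
    int s = 0;
    double th = NA_REAL;
    if (x >= bound) { s = 1; th = 0.0; }
    else if (x <= -bound) { s = -1; th = 0.0; }
    for (int k = 1; s == 0 && k <= kmax; ++k) {
      double x1 = x + lambda * x * dt + (sd > 0 ? sd * rng.norm() : 0.0);
      // diffusion sub-step with bridge correction
      if (x1 >= bound) { s = 1; th = k * dt; }
      else if (x1 <= -bound) { s = -1; th = k * dt; }
      else if (bridge && sd > 0) {
        double s2 = sigma2_a * dt;
        double pu = std::exp(-2.0 * (bound - x) * (bound - x1) / s2);
        double pl = std::exp(-2.0 * (bound + x) * (bound + x1) / s2);
        double u = rng.unif();
        if (u < pu) { s = 1; th = k * dt; }
        else if (u < pu + pl) { s = -1; th = k * dt; }
      }
      if (s == 0) {
        x = x1;
        const std::vector<int> &cl = at_step[k];
        for (size_t c = 0; c < cl.size(); ++c) {
          double xi = 1.0 + (ss > 0 ? ss * rng.norm() : 0.0);
          x += click_sign[cl[c]] * click_mag[cl[c]] * xi;
        }
        if (x >= bound) { s = 1; th = k * dt; }
        else if (x <= -bound) { s = -1; th = k * dt; }
      }
    }
    side[p] = s;
    hit[p] = th;
    xfin[p] = (s == 0) ? x : NA_REAL;
  }
  return List::create(_["side"] = side, _["hit_time"] = hit,
                      _["final_x"] = xfin);
}
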