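// Fast inner negative log likelihood for fitting: given per-trial
// likelihood-versus-initial-state curves (adjoint output, fixed while the
// accumulator parameters are fixed), run the history-filter recursion over
// the valid trials and accumulate the mixture likelihood. Must agree with
// the R reference path (initial_state_from_pairs + trial_likelihoods) to
// rounding error; tested against it.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// pair_code: 0 Rw, 1 Lw, 2 Rl, 3 Ll (valid trials, session order).
// variant: 0 motor, 1 inattention, 2 hybrid. lapse_g: per-trial NDT factor
// (reaction-time mode) or empty (choice-only).
// [[Rcpp::export]]
double inner_nll_cpp(NumericMatrix curves, NumericVector lo0,
                     NumericVector up0, double bound, int n_bins,
                     IntegerVector pair_code, LogicalVector choice_r,
                     NumericVector eta, NumericVector beta,
                     NumericVector start_filters, double kappa, int variant,
                     double rho, double match_slope, NumericVector lapse_g) {
  const int n = curves.nrow();
  const double dx = 2.0 * bound / (n_bins + 1);
  const double c0 = -bound + dx;  // first interior center
  const bool rt_mode = lapse_g.size() > 0;
  double f[4] = {start_filters[0], start_filters[1], start_filters[2],
                 start_filters[3]};
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    const double I = f[0] + f[1] + f[2] + f[3];
    // interpolate the trial's curve at I
    double acc;
    if (I <= -bound) acc = lo0[t];
    else if (I >= bound) acc = up0[t];
    else {
      double pos = (I - c0) / dx;
      int j0 = (int)std::floor(pos);
      if (j0 < 0) j0 = 0;
      if (j0 > n_bins - 2) j0 = n_bins - 2;
      double fr = pos - j0;
      if (fr < 0) fr = 0;
      if (fr > 1) fr = 1;
      acc = curves(t, j0) * (1.0 - fr) + curves(t, j0 + 1) * fr;
    }
    // lapse probability of a rightward choice
    double pl;
    if (variant == 0) pl = rho;
    else if (variant == 1) {
      double d = I - rho;
      pl = d > 0 ? 1.0 : (d < 0 ? 0.0 : 0.5);
    } else {
      pl = 1.0 / (1.0 + std::exp(-match_slope * (I - rho)));
    }
    double lik;
    if (rt_mode) {
      double pl_obs = choice_r[t] ? pl : 1.0 - pl;
      lik = (1.0 - kappa) * acc + kappa * pl_obs * lapse_g[t];
    } else {
      double pr = (1.0 - kappa) * acc + kappa * pl;
      lik = choice_r[t] ? pr : 1.0 - pr;
    }
    nll -= std::log(lik > 1e-12 ? lik : 1e-12);
    // history update from this trial's realized pair
    const int pc = pair_code[t];
    for (int h = 0; h < 4; ++h) f[h] *= beta[h];
    f[pc] += eta[pc];
  }
  return nll;
}
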