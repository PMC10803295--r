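// Fokker-Planck engine for the click accumulator.
//
// The accumulator density P(x(t)) is discretized on n odd interior bins with
// centers c_j = -B + dx*(j+1), dx = 2B/(n+1), plus two sticky absorbing
// states at -B and +B. A click-free step moves mass from each source center
// x to a Gaussian with mean x + (lambda x + drift) dt and variance
// sigma2_a dt, assigned to destination bins by CDF differences over bin
// edges (mass beyond the outermost edges is absorbed at the bounds), with a
// Brownian-bridge within-step crossing correction that removes the
// O(sqrt(dt)) absorption bias of end-of-step monitoring. A step containing
// clicks applies the same diffusion sub-step followed by a position-
// independent Gaussian "kick" (mean = summed signed adapted magnitudes,
// variance = summed C^2 sigma2_s), realized as a single shared convolution
// kernel; this matches the particle simulator, which applies clicks at the
// end of the step after the diffusion sub-step. Deterministic sub-steps
// (vanishing variance) deposit by linear interpolation between the two
// neighboring bins, preserving the mean exactly. All operators conserve
// mass to machine precision.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline double norm_cdf(double z) { return 0.5 * std::erfc(-z * M_SQRT1_2); }

struct StepRow {
  int start;                  // first destination bin index
  std::vector<double> w;      // weights onto bins start..start+len-1
  double lo, up;              // absorbed mass fractions
};

// Diffusion/drift transition row for a source center x. The step Gaussian
// N(x + shift, sd^2) is projected onto linear hat functions on the node set
// {-B, c_0, ..., c_{n-1}, +B} (uniform spacing dx): each inter-node segment
// contributes its mass split between its two nodes in proportion to the
// conditional mean position. This preserves the distribution's mean exactly
// for any sd (in particular sub-bin drift at vanishing noise), and mass at
// the boundary nodes (plus both tails) is absorbed.
void make_row(double x, double shift, double sd, int n, double B, double dx,
              StepRow &row, bool bridge) {
  const double m = x + shift;
  row.w.clear();
  row.lo = row.up = 0.0;
  if (sd < 1e-9) {
    // deterministic: linear interpolation on the same node set
    if (m <= -B) { row.lo = 1.0; row.start = 0; return; }
    if (m >= B) { row.up = 1.0; row.start = 0; return; }
    double pos = (m + B) / dx;       // node index, node k at -B + k dx
    int k0 = (int)std::floor(pos);
    double f = pos - k0;
    row.start = std::max(k0 - 1, 0); // node k -> interior bin k-1
    if (k0 == 0) { row.lo = 1.0 - f; row.w.push_back(f); }
    else if (k0 >= n) { row.w.push_back(1.0 - f); row.up = f; }
    else { row.w.push_back(1.0 - f); row.w.push_back(f); }
    return;
  }
  // nodes within +-6 sd of the mean (clamped to [0, n+1])
  int klo = (int)std::floor((m - 6.0 * sd + B) / dx);
  int khi = (int)std::ceil((m + 6.0 * sd + B) / dx);
  if (klo < 0) klo = 0;
  if (khi > n + 1) khi = n + 1;
  if (klo >= khi) {  // support beyond the grid on one side
    if (m < 0) row.lo = 1.0; else row.up = 1.0;
    row.start = 0;
    return;
  }
  // node weights klo..khi accumulated over segments [y_k, y_{k+1}]
  std::vector<double> nodew(khi - klo + 1, 0.0);
  double zprev = (-B + klo * dx - m) / sd;
  double Fprev = norm_cdf(zprev);
  double phiprev = 0.3989422804014327 * std::exp(-0.5 * zprev * zprev);
  nodew[0] += Fprev;  // tail below the first node collapses onto it
  for (int k = klo; k < khi; ++k) {
    double znext = (-B + (k + 1) * dx - m) / sd;
    double Fnext = norm_cdf(znext);
    double phinext = 0.3989422804014327 * std::exp(-0.5 * znext * znext);
    double mass = Fnext - Fprev;
    if (mass > 0) {
      // first moment of the segment: m*mass - sd*(phi_next - phi_prev)
      double mom = m * mass - sd * (phinext - phiprev);
      double frac_hi = (mom - (-B + k * dx) * mass) / (dx * mass);
      if (frac_hi < 0) frac_hi = 0;
      if (frac_hi > 1) frac_hi = 1;
      nodew[k - klo] += mass * (1.0 - frac_hi);
      nodew[k + 1 - klo] += mass * frac_hi;
    }
    Fprev = Fnext;
    phiprev = phinext;
    zprev = znext;
  }
  nodew[khi - klo] += 1.0 - Fprev;  // upper tail onto the last node
  // nodes 0 and n+1 are the absorbing bounds; interior node k = bin k-1
  int wlo = std::max(klo, 1), whi = std::min(khi, n);
  row.start = wlo - 1;
  if (klo == 0) row.lo += nodew[0];
  if (khi == n + 1) row.up += nodew[khi - klo];
  if (wlo <= whi) {
    row.w.assign(nodew.begin() + (wlo - klo), nodew.begin() + (whi - klo + 1));
  }
  const int jlo = row.start;
  const int len = (int)row.w.size();
  if (bridge) {
    const double s2 = sd * sd;
    for (int j = 0; j < len; ++j) {
      double y = -B + dx * (jlo + j + 1);
      double pu = std::exp(-2.0 * (B - x) * (B - y) / s2);
      double pl = std::exp(-2.0 * (B + x) * (B + y) / s2);
      double tot = pu + pl;
      if (tot > 1.0) { pu /= tot; pl /= tot; tot = 1.0; }
      double wj = row.w[j];
      row.up += wj * pu;
      row.lo += wj * pl;
      row.w[j] = wj * (1.0 - tot);
    }
  }
}

// Position-independent click kick: kernel over destination-offset bins.
struct Kick {
  int off0;                   // first offset (in bins)
  std::vector<double> w;      // kernel weights for offsets off0..off0+len-1
  std::vector<double> head;   // prefix sums: mass at offsets < off0+i
  double tail_lo, tail_hi;    // kernel mass below/above the window
};

void make_kick(double m, double v, double dx, Kick &k) {
  k.w.clear();
  v -= dx * dx / 6.0;  // second-moment correction, as in the base step
  double sd = v > 0 ? std::sqrt(v) : 0.0;
  if (sd < 1e-9) {
    double pos = m / dx;
    int j0 = (int)std::floor(pos);
    double f = pos - j0;
    k.off0 = j0;
    k.w.push_back(1.0 - f);
    k.w.push_back(f);
    k.tail_lo = k.tail_hi = 0.0;
  } else {
    int jlo = (int)std::floor((m - 6.0 * sd) / dx);
    int jhi = (int)std::ceil((m + 6.0 * sd) / dx);
    k.off0 = jlo;
    int len = jhi - jlo + 1;
    k.w.resize(len);
    double Fprev = norm_cdf(((jlo - 0.5) * dx - m) / sd);
    k.tail_lo = Fprev;
    for (int j = 0; j < len; ++j) {
      double Fnext = norm_cdf(((jlo + j + 0.5) * dx - m) / sd);
      k.w[j] = Fnext - Fprev;
      Fprev = Fnext;
    }
    k.tail_hi = 1.0 - Fprev;
  }
  k.head.resize(k.w.size() + 1);
  k.head[0] = k.tail_lo;
  for (size_t j = 0; j < k.w.size(); ++j) k.head[j + 1] = k.head[j] + k.w[j];
}

struct Engine {
  int n;
  double B, dx, lambda, drift, dt, sigma2a;
  std::vector<double> centers;
  std::vector<StepRow> base;
  bool base_ready = false;

  Engine(int n_, double B_, double lambda_, double drift_, double dt_,
         double s2a)
      : n(n_), B(B_), lambda(lambda_), drift(drift_), dt(dt_), sigma2a(s2a) {
    dx = 2.0 * B / (n + 1);
    centers.resize(n);
    for (int j = 0; j < n; ++j) centers[j] = -B + dx * (j + 1);
  }
  void ensure_base() {
    if (base_ready) return;
    base.resize(n);
    // hat-function projection adds dx^2/6 variance per step; shrink the
    // step Gaussian accordingly so the discrete operator's second moment
    // matches the continuous one
    double v = sigma2a * dt - dx * dx / 6.0;
    double sd = std::sqrt(v > 0 ? v : 0);
    for (int i = 0; i < n; ++i)
      make_row(centers[i], (lambda * centers[i] + drift) * dt, sd, n, B, dx,
               base[i], sigma2a * dt > 0);
    base_ready = true;
  }
  // diffusion sub-step, forward
  void base_forward(std::vector<double> &p, double &abs_lo, double &abs_up,
                    std::vector<double> &buf) {
    ensure_base();
    std::fill(buf.begin(), buf.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double pi = p[i];
      if (pi <= 0.0) continue;
      const StepRow &row = base[i];
      abs_lo += pi * row.lo;
      abs_up += pi * row.up;
      const int len = (int)row.w.size();
      for (int j = 0; j < len; ++j) buf[row.start + j] += pi * row.w[j];
    }
    p.swap(buf);
  }
  // click kick, forward: convolution with absorption past the edges
  void kick_forward(std::vector<double> &p, const Kick &k, double &abs_lo,
                    double &abs_up, std::vector<double> &buf) {
    std::fill(buf.begin(), buf.end(), 0.0);
    const int len = (int)k.w.size();
    for (int i = 0; i < n; ++i) {
      double pi = p[i];
      if (pi <= 0.0) continue;
      int jmin = i + k.off0;            // destination of first kernel weight
      int a = std::min(std::max(0, -jmin), len);
      int b = std::max(std::min(len, n - jmin), a);
      // kernel mass below bin 0 -> lower bound; above bin n-1 -> upper
      abs_lo += pi * k.head[a];
      abs_up += pi * (k.head[len] + k.tail_hi - k.head[b]);
      for (int j = a; j < b; ++j) buf[jmin + j] += pi * k.w[j];
    }
    p.swap(buf);
  }
  // adjoints
  void base_backward(std::vector<double> &w, double pay_lo, double pay_up,
                     std::vector<double> &buf) {
    ensure_base();
    for (int i = 0; i < n; ++i) {
      const StepRow &row = base[i];
      double acc = row.lo * pay_lo + row.up * pay_up;
      const int len = (int)row.w.size();
      for (int j = 0; j < len; ++j) acc += row.w[j] * w[row.start + j];
      buf[i] = acc;
    }
    w.swap(buf);
  }
  void kick_backward(std::vector<double> &w, const Kick &k, double pay_lo,
                     double pay_up, std::vector<double> &buf) {
    const int len = (int)k.w.size();
    for (int i = 0; i < n; ++i) {
      int jmin = i + k.off0;
      int a = std::min(std::max(0, -jmin), len);
      int b = std::max(std::min(len, n - jmin), a);
      double acc = k.head[a] * pay_lo +
        (k.head[len] + k.tail_hi - k.head[b]) * pay_up;
      for (int j = a; j < b; ++j) acc += k.w[j] * w[jmin + j];
      buf[i] = acc;
    }
    w.swap(buf);
  }
};

}  // namespace

// Forward evolution of one trial. click_step: 1-based step index of each
// click packet; click_mean/click_var: its mean input and variance
// contribution. init_w: interior initial mass (typically a two-point
// interpolation of a delta at I).
// [[Rcpp::export]]
List fp_forward_cpp(NumericVector init_w, double init_lo, double init_up,
                    int n_bins, double bound, double lambda, double drift,
                    double dt, double sigma2_a, int n_steps,
                    IntegerVector click_step, NumericVector click_mean,
                    NumericVector click_var) {
  Engine eng(n_bins, bound, lambda, drift, dt, sigma2_a);
  std::vector<double> p(init_w.begin(), init_w.end()), buf(n_bins, 0.0);
  NumericVector abs_lo(n_steps), abs_up(n_steps);
  // clicks sharing a step are applied as sequential kicks in input order
  // (callers supply clicks in time order), with absorption checked between
  std::vector<std::vector<int> > at(n_steps + 1);
  for (int c = 0; c < click_step.size(); ++c) {
    int k = click_step[c];
    if (k < 1) k = 1;
    if (k > n_steps) k = n_steps;
    at[k].push_back(c);
  }
  double lo = init_lo, up = init_up;
  Kick kick;
  for (int k = 1; k <= n_steps; ++k) {
    double dlo = 0.0, dup = 0.0;
    eng.base_forward(p, dlo, dup, buf);
    for (size_t c = 0; c < at[k].size(); ++c) {
      make_kick(click_mean[at[k][c]], click_var[at[k][c]], eng.dx, kick);
      eng.kick_forward(p, kick, dlo, dup, buf);
    }
    lo += dlo;
    up += dup;
    abs_lo[k - 1] = dlo;
    abs_up[k - 1] = dup;
  }
  return List::create(_["interior"] = NumericVector(p.begin(), p.end()),
                      _["absorbed_lo"] = abs_lo, _["absorbed_up"] = abs_up,
                      _["total_lo"] = lo, _["total_up"] = up,
                      _["centers"] = NumericVector(eng.centers.begin(),
                                                   eng.centers.end()));
}

// Batch adjoint pass: for each trial, the payoff expectation as a function
// of the initial-state bin. Payoffs: terminal vector over interior bins at
// the final step, plus per-step payoffs (NULL, scalar, or length-n_steps)
// for mass absorbed at the lower/upper bound in that step; pay_lo0/pay_up0
// report the payoff when the initial state itself starts outside a bound.
// Used by the likelihood engine: the result is the per-trial choice or
// choice-RT likelihood versus the initial state.
// [[Rcpp::export]]
NumericMatrix fp_curve_batch_cpp(int n_bins, double bound, double lambda,
                                 double drift, double dt, double sigma2_a,
                                 List trials) {
  Engine eng(n_bins, bound, lambda, drift, dt, sigma2_a);
  const int n_tr = trials.size();
  NumericMatrix out(n_tr, n_bins + 2);
  std::vector<double> w(n_bins), buf(n_bins);
  Kick kick;
  for (int t = 0; t < n_tr; ++t) {
    List tr = trials[t];
    int K = as<int>(tr["n_steps"]);
    IntegerVector cs = tr["click_step"];
    NumericVector cm = tr["click_mean"], cv = tr["click_var"];
    std::vector<std::vector<int> > at(K + 1);
    for (int c = 0; c < cs.size(); ++c) {
      int k = cs[c];
      if (k < 1) k = 1;
      if (k > K) k = K;
      at[k].push_back(c);
    }
    SEXP pt = tr["pay_terminal"];
    if (Rf_isNull(pt)) std::fill(w.begin(), w.end(), 0.0);
    else {
      NumericVector v(pt);
      std::copy(v.begin(), v.end(), w.begin());
    }
    bool have_lo = !Rf_isNull(tr["pay_lo"]), have_up = !Rf_isNull(tr["pay_up"]);
    NumericVector plo = have_lo ? NumericVector(tr["pay_lo"]) : NumericVector(0);
    NumericVector pup = have_up ? NumericVector(tr["pay_up"]) : NumericVector(0);
    for (int k = K; k >= 1; --k) {
      double pl = have_lo ? (plo.size() == 1 ? plo[0] : plo[k - 1]) : 0.0;
      double pu = have_up ? (pup.size() == 1 ? pup[0] : pup[k - 1]) : 0.0;
      for (int c = (int)at[k].size() - 1; c >= 0; --c) {
        make_kick(cm[at[k][c]], cv[at[k][c]], eng.dx, kick);
        eng.kick_backward(w, kick, pl, pu, buf);
      }
      eng.base_backward(w, pl, pu, buf);
    }
    for (int j = 0; j < n_bins; ++j) out(t, j) = w[j];
    out(t, n_bins) = as<double>(tr["pay_lo0"]);
    out(t, n_bins + 1) = as<double>(tr["pay_up0"]);
  }
  return out;
}

// Interior bin centers for a grid (kept in C++ so R and C++ always agree).
// [[Rcpp::export]]
NumericVector fp_centers_cpp(int n_bins, double bound) {
  double dx = 2.0 * bound / (n_bins + 1);
  NumericVector c(n_bins);
  for (int j = 0; j < n_bins; ++j) c[j] = -bound + dx * (j + 1);
  return c;
}
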