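#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) on the quartic double well
//   U(y) = barrier * ((2y/sep)^2 - 1)^2
// Force: -dU/dy = -16 * barrier * y * ((2y/sep)^2 - 1) / sep^2.
// Uses R's RNG, so set.seed() in R controls the stream.
// [[Rcpp::export]]
NumericVector cpp_simulate_doublewell(double barrier, double sep, double D,
                                      double n_steps_d, double dt, int stride,
                                      double y0) {
  R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  R_xlen_t n_saved = n_steps / stride;
  NumericVector out(n_saved);
  double y = y0;
  const double amp = std::sqrt(2.0 * D * dt);
  const double c = 16.0 * barrier / (sep * sep);
  const double inv = 2.0 / sep;
  const double bound = 10.0 * sep;
  R_xlen_t isave = 0;
  for (R_xlen_t t = 1; t <= n_steps; ++t) {
    double u = y * inv;
    double force = -c * y * (u * u - 1.0);
    y += force * dt + amp * norm_rand();
    // instability can only come from the drift term; free diffusion
    // (barrier 0) legitimately wanders without bound
    if (barrier > 0 && std::abs(y) > bound)
      stop("integration instability: |y| exceeded 10*well_separation at step %td",
           (ptrdiff_t)t);
    if (t % stride == 0) out[isave++] = y;
  }
  return out;
}

// Raw level-crossing counts for the cut partition function.
// A pair (t, t+k) crosses level l iff (x_t <= l) != (x_{t+k} <= l)
// (frames exactly at a level sit on the left side).  Equivalently the
// crossed levels are those in [min, max) of the pair, counted here with a
// difference array over the sorted level grid: O(N log L + L).
// all_phases = TRUE uses every pair t = 0..N-1-k; FALSE uses t = 0, k, 2k, ...
// [[Rcpp::export]]
NumericVector cpp_cut_counts(NumericVector x, NumericVector levels, int k,
                             bool all_phases) {
  R_xlen_t n = x.size(), L = levels.size();
  std::vector<double> diffarr(L + 1, 0.0);
  const double* lv = REAL(levels);
  R_xlen_t step = all_phases ? 1 : k;
  for (R_xlen_t t = 0; t + k < n; t += step) {
    double a = x[t], b = x[t + k];
    if (a == b) continue;
    double lo = a < b ? a : b, hi = a < b ? b : a;
    R_xlen_t i0 = std::lower_bound(lv, lv + L, lo) - lv;
    R_xlen_t i1 = std::lower_bound(lv, lv + L, hi) - lv;
    if (i1 > i0) { diffarr[i0] += 1.0; diffarr[i1] -= 1.0; }
  }
  NumericVector out(L);
  double acc = 0.0;
  for (R_xlen_t i = 0; i < L; ++i) { acc += diffarr[i]; out[i] = acc; }
  return out;
}

// Direct first-passage sampling on the quartic double well: start at a,
// integrate until first crossing of b, record the elapsed time, restart.
// [[Rcpp::export]]
NumericVector cpp_first_passage(double barrier, double sep, double D,
                                double dt, double a, double b, int n_events,
                                double max_steps_d) {
  R_xlen_t max_steps = (R_xlen_t)max_steps_d;
  NumericVector out(n_events);
  const double amp = std::sqrt(2.0 * D * dt);
  const double c = 16.0 * barrier / (sep * sep);
  const double inv = 2.0 / sep;
  const bool upward = b > a;
  R_xlen_t total = 0;
  for (int ev = 0; ev < n_events; ++ev) {
    double y = a;
    R_xlen_t t = 0;
    while (true) {
      double u = y * inv;
      y += (-c * y * (u * u - 1.0)) * dt + amp * norm_rand();
      ++t;
      if (++total > max_steps)
        stop("first-passage sampling exceeded max_steps before %d events", ev);
      if ((upward && y >= b) || (!upward && y <= b)) break;
    }
    out[ev] = t * dt;
  }
  return out;
}
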