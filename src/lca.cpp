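#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of the two-accumulator leaky competing
// accumulator with staggered route onsets and an exponentially decaying
// irrelevant drive.  Accumulator 1 is driven by the relevant route (the
// correct response); the irrelevant route feeds accumulator 1 on congruent
// trials and accumulator 2 on incongruent trials.  Time 0 is the onset of
// the first stimulus feature; the returned rt includes non-decision time.
// Uses R's RNG so results are reproducible under set.seed().
//
// Returns an n x 2 matrix: column 1 = rt (ms, NA if no response by t_max),
// column 2 = correct (1/0, NA if no response).
// [[Rcpp::export]]
NumericMatrix lca_sim_cpp(int n, double theta, double leak, double beta,
                          double drift, double amp, double tau, double sigma,
                          double t_nd, double t_rel, double t_irr,
                          double d_rel, double d_irr, double dt, double t_max,
                          bool congruent) {
  NumericMatrix out(n, 2);
  const double rel_on = t_rel + d_rel;
  const double irr_on = t_irr + d_irr;
  const double sq = sigma * std::sqrt(dt);
  // integration stops once rt (= crossing time + t_nd) would exceed t_max
  const int max_steps = (int)std::ceil((t_max - t_nd) / dt);

  for (int i = 0; i < n; ++i) {
    double x1 = 0.0, x2 = 0.0;
    double rt = NA_REAL, corr = NA_REAL;
    for (int s = 1; s <= max_steps; ++s) {
      const double tprev = (s - 1) * dt;  // drive evaluated at step start
      double I1 = 0.0, I2 = 0.0;
      if (tprev >= rel_on) I1 += drift;
      if (tprev >= irr_on) {
        const double a = amp * std::exp(-(tprev - irr_on) / tau);
        if (congruent) I1 += a; else I2 += a;
      }
      double nx1 = x1 + (I1 - leak * x1 - beta * x2) * dt;
      double nx2 = x2 + (I2 - leak * x2 - beta * x1) * dt;
      if (sq > 0.0) {
        nx1 += sq * norm_rand();
        nx2 += sq * norm_rand();
      }
      if (nx1 < 0.0) nx1 = 0.0;
      if (nx2 < 0.0) nx2 = 0.0;
      if (!std::isfinite(nx1) || !std::isfinite(nx2))
        stop("non-finite accumulator state; check parameter values");
      x1 = nx1;
      x2 = nx2;
      if (x1 >= theta || x2 >= theta) {
        rt = s * dt + t_nd;
        corr = (x1 >= x2) ? 1.0 : 0.0;
        break;
      }
    }
    out(i, 0) = rt;
    out(i, 1) = corr;
  }
  return out;
}
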