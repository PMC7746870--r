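#include <Rcpp.h>
using namespace Rcpp;

// First-order excitation-to-neural-activation dynamics
//   du/dt = (c1 * e(t) + c2) * (e(t) - u(t))
// integrated with the explicit midpoint rule on a uniform grid of spacing dt.
// e is the (already delay-shifted) excitation sampled at the grid nodes;
// between nodes e is taken piecewise-linear.  Sub-steps bound the local
// truncation error: the per-step rate-time product dt * (c1 + c2) is kept
// below 0.05, which also guarantees stability with a wide margin.

// [[Rcpp::export]]
NumericVector activation_ode_c(NumericVector e, double dt, double c1,
                               double c2, double u0) {
  const int n = e.size();
  NumericVector u(n);
  if (n == 0) return u;
  u[0] = u0;

  double rate = std::fabs(c1) + std::fabs(c2);
  int nsub = (int)std::ceil(dt * rate / 0.05);
  if (nsub < 1) nsub = 1;
  const double h = dt / nsub;

  for (int i = 0; i < n - 1; ++i) {
    double ui = u[i];
    for (int s = 0; s < nsub; ++s) {
      double f0 = (s + 0.0) / nsub;   // fraction through the frame
      double fm = (s + 0.5) / nsub;
      double e0 = e[i] + f0 * (e[i + 1] - e[i]);
      double em = e[i] + fm * (e[i + 1] - e[i]);
      double k1 = (c1 * e0 + c2) * (e0 - ui);
      double umid = ui + 0.5 * h * k1;
      double k2 = (c1 * em + c2) * (em - umid);
      ui += h * k2;
    }
    if (!std::isfinite(ui))
      stop("activation dynamics integration diverged at frame %d", i + 2);
    u[i + 1] = ui;
  }
  return u;
}
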