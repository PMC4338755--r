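#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

// Population input-output curve H(x) = (a*x - b) / (1 - exp(-d*(a*x - b))).
// The removable singularity at a*x = b is handled by a short series
// expansion: H = 1/d + y/2 + d*y^2/12 + O(y^3), y = a*x - b.
static inline double transfer(double x, double a, double b, double d) {
  const double y = a * x - b;
  const double u = d * y;
  if (std::fabs(u) < 1e-8) {
    return 1.0 / d + y / 2.0 + d * y * y / 12.0;
  }
  if (u < -700.0) return 0.0;  // denominator overflows to -Inf; limit is 0
  return y / (-std::expm1(-u));
}

// Euler-Maruyama integration of the dynamical mean-field model
//   dS_i = [ -S_i/tau_S + (1 - S_i) * gamma * H(x_i) ] dt + sigma dW_i
//   x_i  = w*J_N*S_i + sign*G*J_N*(C S)_i + I_0 + applied_i(t)
// on a sparse symmetric coupling matrix C passed in compressed
// column-oriented form (slots p, i, x of a Matrix::dgCMatrix).
//
// Noise: one mt19937_64 stream seeded from `seed`, standard normal draws in
// node order within each step; increment sigma*sqrt(dt)*z (sqrt_dt = true)
// or plain per-step sigma*z (sqrt_dt = false). sigma == 0 draws nothing.
//
// Samples are recorded every `steps_per_sample` steps at t_k = k*sps*dt,
// k = 1..n_samples; the recorded rate is H(x) evaluated at the sampled
// state (including any applied current active at t_k). Each loop
// iteration evaluates the network input once, records if the current time
// lies on the sample grid, then advances the state.
// [[Rcpp::export(name = ".mf_integrate")]]
List mf_integrate(IntegerVector Cp, IntegerVector Ci, NumericVector Cx,
                  int n,
                  double w, double a, double b, double d, double gamma_,
                  double tau_S, double J_N, double I_0,
                  double sigma, double G, double coupling_sign,
                  double dt, int n_steps, int steps_per_sample,
                  NumericVector S0, bool clamp, bool sqrt_dt,
                  NumericMatrix stim_amp, NumericVector stim_on,
                  NumericVector stim_off,
                  int seed) {
  const int n_samples = n_steps / steps_per_sample;
  const int n_stim = stim_on.size();
  NumericMatrix S_out(n_samples, n), R_out(n_samples, n);
  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> x(n), coup(n);
  const int *cp = INTEGER(Cp);
  const int *ci = INTEGER(Ci);
  const double *cx = REAL(Cx);

  std::mt19937_64 gen(static_cast<uint64_t>(seed));
  std::normal_distribution<double> norm(0.0, 1.0);
  const double noise_fac = sqrt_dt ? sigma * std::sqrt(dt) : sigma;

  int out_row = 0;
  for (int step = 0; step <= n_steps; ++step) {
    const double t = step * dt;
    // x = w*J_N*S + sign*G*J_N*(C S) + I_0 + applied(t)
    // gather form: C is symmetric so the CSC columns are also its rows
    for (int i = 0; i < n; ++i) {
      const int k1 = cp[i + 1];
      double a0 = 0.0, a1 = 0.0;
      int k = cp[i];
      for (; k + 1 < k1; k += 2) {
        a0 += cx[k] * S[ci[k]];
        a1 += cx[k + 1] * S[ci[k + 1]];
      }
      if (k < k1) a0 += cx[k] * S[ci[k]];
      coup[i] = a0 + a1;
    }
    const double gj = coupling_sign * G * J_N;
    const double wj = w * J_N;
    for (int i = 0; i < n; ++i) x[i] = wj * S[i] + gj * coup[i] + I_0;
    for (int s = 0; s < n_stim; ++s) {
      if (t >= stim_on[s] && t < stim_off[s]) {
        for (int i = 0; i < n; ++i) x[i] += stim_amp(i, s);
      }
    }

    if (step > 0 && step % steps_per_sample == 0) {
      for (int i = 0; i < n; ++i) {
        S_out(out_row, i) = S[i];
        R_out(out_row, i) = transfer(x[i], a, b, d);
      }
      ++out_row;
    }
    if (step == n_steps) break;

    for (int i = 0; i < n; ++i) {
      const double drift = -S[i] / tau_S +
        (1.0 - S[i]) * gamma_ * transfer(x[i], a, b, d);
      double Si = S[i] + dt * drift;
      if (noise_fac != 0.0) Si += noise_fac * norm(gen);
      if (clamp) {
        if (Si < 0.0) Si = 0.0;
        else if (Si > 1.0) Si = 1.0;
      }
      if (!std::isfinite(Si)) {
        stop("mean-field integration diverged (non-finite state) at step %d "
             "(t = %g s), node %d", step + 1, t, i + 1);
      }
      S[i] = Si;
    }
  }
  return List::create(_["S"] = S_out, _["rate"] = R_out);
}
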