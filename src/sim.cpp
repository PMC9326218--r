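#include <Rcpp.h>
using namespace Rcpp;

// Advance the full network n_steps with constant external input.
//
// Update order within a step is synchronous: all membrane potentials are
// integrated using the firing rates of the previous step, then all rates are
// recomputed from the new potentials, then all plastic weights are updated
// from the new rates. This makes the trajectory independent of unit ordering.
//
// W is indexed [post, pre]. Plasticity touches only the entries listed in
// (plastic_i, plastic_j) (0-based); each carries its own learning rate,
// plasticity threshold and clip bounds. Learning rates passed here must
// already include any cortical slow-down and psi gain.
//
// [[Rcpp::export(name = ".sim_run")]]
List sim_run(NumericVector V0, NumericVector F0, NumericMatrix W0,
             NumericVector I, NumericVector tau, NumericVector theta,
             double dt, int n_steps, bool learning,
             IntegerVector plastic_i, IntegerVector plastic_j,
             NumericVector alpha, NumericVector rho,
             NumericVector wmin, NumericVector wmax,
             int record_stride, double late_frac) {
  const int n = V0.size();
  const int np = plastic_i.size();
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (dt <= 0) stop("dt must be > 0");
  for (int i = 0; i < n; ++i) {
    if (!R_finite(V0[i]) || !R_finite(I[i]))
      stop("non-finite potential or input");
    if (tau[i] <= 0) stop("tau must be > 0");
    if (dt > tau[i]) stop("dt must not exceed tau (Euler stability)");
  }

  NumericVector V = clone(V0);
  NumericVector F = clone(F0);
  NumericMatrix W = clone(W0);
  std::vector<double> Vnew(n);

  const int n_rec = record_stride > 0 ? n_steps / record_stride : 0;
  NumericMatrix trace(n_rec, n);
  IntegerVector trace_step(n_rec);

  int n_late = (int)std::floor(n_steps * late_frac);
  if (n_late < 1) n_late = 1;
  NumericVector late_sum(n), mean_sum(n), peak(n);
  int rec = 0;

  std::vector<double> syn(n);
  const double *Wp = W.begin();  // column-major, stride n

  for (int t = 0; t < n_steps; ++t) {
    // potentials (leaky integration, Euler)
    std::fill(syn.begin(), syn.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double fj = F[j];
      if (fj == 0.0) continue;  // silent presynaptic units contribute nothing
      const double *wcol = Wp + (size_t)j * n;
      for (int i = 0; i < n; ++i) syn[i] += wcol[i] * fj;
    }
    for (int i = 0; i < n; ++i)
      Vnew[i] = V[i] + dt / tau[i] * (-V[i] + I[i] + syn[i]);
    // rates: positive part of tanh(V - theta)
    for (int i = 0; i < n; ++i) {
      V[i] = Vnew[i];
      double x = std::tanh(V[i] - theta[i]);
      F[i] = x > 0.0 ? x : 0.0;
    }
    // weights: BCM with per-connection threshold, clipped
    if (learning && np > 0) {
      for (int k = 0; k < np; ++k) {
        const int i = plastic_i[k], j = plastic_j[k];
        double w = W(i, j) + alpha[k] * (F[i] - rho[k]) * F[j];
        if (w > wmax[k]) w = wmax[k];
        if (w < wmin[k]) w = wmin[k];
        W(i, j) = w;
      }
    }
    for (int i = 0; i < n; ++i) {
      mean_sum[i] += F[i];
      if (t >= n_steps - n_late) late_sum[i] += F[i];
      if (F[i] > peak[i]) peak[i] = F[i];
    }
    if (record_stride > 0 && (t + 1) % record_stride == 0 && rec < n_rec) {
      for (int i = 0; i < n; ++i) trace(rec, i) = F[i];
      trace_step[rec] = t + 1;
      ++rec;
    }
  }

  for (int i = 0; i < n; ++i) {
    late_sum[i] /= n_late;
    mean_sum[i] /= n_steps;
  }

  return List::create(
      _["V"] = V, _["F"] = F, _["W"] = W,
      _["F_late"] = late_sum, _["F_mean"] = mean_sum, _["F_peak"] = peak,
      _["trace"] = trace, _["trace_step"] = trace_step);
}
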