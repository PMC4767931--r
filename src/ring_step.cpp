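#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Explicit-Euler updates of the vascular ring.
//
// ring_substeps: advance (g, u) by `nsteps` steps with the deficit signal I
// held fixed (one coupled-training interval).
//
// ring_run: advance the full vessel + deficit system under constant demand
// N_d, with E integrated every step and I = E - n/2 recomputed, recording S
// every `rec_every` steps after `skip` steps.

// [[Rcpp::export(name = ".ring_substeps_cpp")]]
List ring_substeps_cpp(NumericVector g0, NumericVector u0, NumericMatrix T,
                       double I, double dt, double tau_v, double lambda_v,
                       int nsteps) {
  int n = g0.size();
  NumericVector g = clone(g0), u = clone(u0), S(n);
  std::vector<double> gn(n);
  double *gp = REAL(g), *up = REAL(u), *Sp = REAL(S), *Tp = REAL(T);
  for (int j = 0; j < n; ++j) Sp[j] = tanh(lambda_v * gp[j]);
  for (int it = 0; it < nsteps; ++it) {
    for (int j = 0; j < n; ++j) {
      double lat = 0.0;
      const double *Tcol = Tp + (size_t)j;  // row j via column-major stride
      for (int k = 0; k < n; ++k) lat += Tcol[(size_t)k * n] * Sp[k];
      gn[j] = gp[j] + dt * (-gp[j] - up[j] + lat + I);
    }
    for (int j = 0; j < n; ++j) {
      up[j] += (dt / tau_v) * (-up[j] + Sp[j]);
      gp[j] = gn[j];
      Sp[j] = tanh(lambda_v * gp[j]);
    }
  }
  for (int j = 0; j < n; ++j)
    if (!R_finite(g[j]) || !R_finite(u[j]))
      stop("vascular state became non-finite; reduce `dt` or coupling strength");
  return List::create(_["g"] = g, _["u"] = u, _["S"] = S);
}

// [[Rcpp::export(name = ".ring_run_cpp")]]
List ring_run_cpp(NumericVector g0, NumericVector u0, double E0,
                  NumericMatrix T, double N_d, double dt, double tau_v,
                  double lambda_v, double tau_e, double lambda_e,
                  int nsteps, int skip, int rec_every) {
  int n = g0.size();
  NumericVector g = clone(g0), u = clone(u0), S(n);
  double E = E0;
  std::vector<double> gn(n);
  double *gp = REAL(g), *up = REAL(u), *Sp = REAL(S), *Tp = REAL(T);
  for (int j = 0; j < n; ++j) Sp[j] = tanh(lambda_v * gp[j]);
  int n_rec = (nsteps - skip) / rec_every;
  NumericMatrix S_hist(n, n_rec);
  NumericVector times(n_rec);
  int k_rec = 0;
  for (int it = 1; it <= nsteps; ++it) {
    double I = E - n / 2.0;
    double N_s = 0.0;
    for (int j = 0; j < n; ++j) {
      double lat = 0.0;
      const double *Tcol = Tp + (size_t)j;
      for (int k = 0; k < n; ++k) lat += Tcol[(size_t)k * n] * Sp[k];
      gn[j] = gp[j] + dt * (-gp[j] - up[j] + lat + I);
    }
    for (int j = 0; j < n; ++j) {
      up[j] += (dt / tau_v) * (-up[j] + Sp[j]);
      gp[j] = gn[j];
      Sp[j] = tanh(lambda_v * gp[j]);
      N_s += Sp[j];
    }
    E += (dt / tau_e) * tanh(lambda_e * (N_d - N_s));
    if (it > skip && (it - skip) % rec_every == 0 && k_rec < n_rec) {
      for (int j = 0; j < n; ++j) S_hist(j, k_rec) = Sp[j];
      times[k_rec] = it * dt;
      ++k_rec;
    }
  }
  for (int j = 0; j < n; ++j)
    if (!R_finite(g[j]) || !R_finite(u[j]))
      stop("vascular state became non-finite; reduce `dt` or coupling strength");
  return List::create(_["g"] = g, _["u"] = u, _["E"] = E,
                      _["S_history"] = S_hist, _["times"] = times);
}
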