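#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact logistic propagation: dV/dt = A V - B V^2 from v0 over dt.
static inline double logistic_step_c(double v0, double A, double B,
                                     double dt) {
  if (dt == 0.0) return v0;
  if (A == 0.0) return v0 / (1.0 + B * v0 * dt);
  return A * v0 / (B * v0 + (A - B * v0) * std::exp(-A * dt));
}

// One-compartment model with impulsive LQ kill, marched exactly between
// dose times; scans on a dose day report the post-dose volume.
// eval_days must be sorted ascending; dose_days sorted ascending.
// Returns a length(eval_days) x length(beta) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_predict_1c(double A, double B, double alpha,
                             NumericVector beta, NumericVector dose_days,
                             double dose, double V0, NumericVector eval_days,
                             double t0) {
  int ne = eval_days.size(), nb = beta.size();
  NumericMatrix out(ne, nb);
  for (int j = 0; j < nb; ++j) {
    double sf = std::exp(-alpha * dose - beta[j] * dose * dose);
    double v = V0, t = t0;
    int id = 0, nd = dose_days.size();
    while (id < nd && dose_days[id] <= t0) ++id;
    for (int i = 0; i < ne; ++i) {
      double te = eval_days[i];
      while (id < nd && dose_days[id] <= te) {
        v = logistic_step_c(v, A, B, dose_days[id] - t);
        v *= sf;
        t = dose_days[id];
        ++id;
      }
      out(i, j) = logistic_step_c(v, A, B, te - t);
    }
  }
  return out;
}

// Two-compartment model (viable V, necrotic N) with impulsive transfer
// V -> SF*V, N -> N + (1-SF)*V at dose times; classical RK4 with fixed
// step h between events. eval_days and dose_days sorted ascending.
// Returns list(tumor = V+N, necrotic = N) matrices.
// [[Rcpp::export]]
List cpp_predict_2c(double lambda, double K, double eta, double zeta,
                    double alpha, NumericVector beta,
                    NumericVector dose_days, double dose, double V0,
                    double N0, NumericVector eval_days, double t0,
                    double h) {
  int ne = eval_days.size(), nb = beta.size();
  NumericMatrix out_t(ne, nb), out_n(ne, nb);
  for (int j = 0; j < nb; ++j) {
    double sf = std::exp(-alpha * dose - beta[j] * dose * dose);
    double v = V0, n = N0, t = t0;
    int id = 0, nd = dose_days.size();
    while (id < nd && dose_days[id] <= t0) ++id;
    for (int i = 0; i < ne; ++i) {
      double te = eval_days[i];
      while (true) {
        double t_stop = (id < nd && dose_days[id] <= te) ? dose_days[id] : te;
        double dt = t_stop - t;
        if (dt > 0) {
          int steps = (int)std::ceil(dt / h);
          double hh = dt / steps;
          for (int s = 0; s < steps; ++s) {
            double k1v = lambda * v * (1 - v / K) - eta * v;
            double k1n = eta * v - zeta * n;
            double v2 = v + 0.5 * hh * k1v, n2 = n + 0.5 * hh * k1n;
            double k2v = lambda * v2 * (1 - v2 / K) - eta * v2;
            double k2n = eta * v2 - zeta * n2;
            double v3 = v + 0.5 * hh * k2v, n3 = n + 0.5 * hh * k2n;
            double k3v = lambda * v3 * (1 - v3 / K) - eta * v3;
            double k3n = eta * v3 - zeta * n3;
            double v4 = v + hh * k3v, n4 = n + hh * k3n;
            double k4v = lambda * v4 * (1 - v4 / K) - eta * v4;
            double k4n = eta * v4 - zeta * n4;
            v += hh / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
            n += hh / 6.0 * (k1n + 2 * k2n + 2 * k3n + k4n);
          }
          t = t_stop;
        }
        if (id < nd && dose_days[id] <= te && t == dose_days[id]) {
          n += (1 - sf) * v;
          v *= sf;
          ++id;
        } else break;
      }
      out_t(i, j) = v + n;
      out_n(i, j) = n;
    }
  }
  return List::create(_["tumor"] = out_t, _["necrotic"] = out_n);
}
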