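// Dormand-Prince RK45 integrator for the quasi-steady-state TMDD system.
//
// State (3): Ctot [nM] total drug in central, Rtot [nM] total target,
//            A2 [nmol] free drug amount in the peripheral compartment.
// The free-drug concentration C is the nonnegative root of the QSS
// quadratic, evaluated in a cancellation-safe form. Infusions enter as a
// piecewise-constant rate; integration restarts at every rate boundary.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static inline double qss_free(double Ctot, double Rtot, double Kss) {
  if (Ctot <= 0.0) return 0.0;
  double b = Ctot - Rtot - Kss;
  double disc = std::sqrt(b * b + 4.0 * Kss * Ctot);
  // b >= 0: standard root is well conditioned; b < 0: rationalized form
  return (b >= 0.0) ? 0.5 * (b + disc) : 2.0 * Kss * Ctot / (disc - b);
}

struct TmddPars {
  double CL, V1, Q, V2, CLRC, kin, kout, Kss;
};

static inline void tmdd_rhs(const double *y, double rate, const TmddPars &p,
                            double *dy) {
  double Ctot = y[0] > 0.0 ? y[0] : 0.0;
  double Rtot = y[1] > 0.0 ? y[1] : 0.0;
  double C = qss_free(Ctot, Rtot, p.Kss);
  double occ = C / (p.Kss + C);  // receptor occupancy fraction RC/Rtot
  dy[0] = rate / p.V1 - (p.CL / p.V1 + p.Q / p.V1) * C -
          Rtot * (p.CLRC / p.V1) * occ + (p.Q / p.V2) * y[2] / p.V1;
  dy[1] = p.kin - p.kout * Rtot - (p.CLRC / p.V1 - p.kout) * Rtot * occ;
  dy[2] = p.Q * C - (p.Q / p.V2) * y[2];
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// Integrate one segment [t0, t1] with constant infusion rate; y updated in
// place. Throws on step-size underflow.
static void integrate_segment(double *y, double t0, double t1, double rate,
                              const TmddPars &p, double rtol, double atol) {
  const int n = 3;
  if (t1 <= t0) return;
  double t = t0;
  double h = std::min(0.01, t1 - t0);
  double k1[n], k2[n], k3[n], k4[n], k5[n], k6[n], k7[n], yt[n], ynew[n];
  tmdd_rhs(y, rate, p, k1);
  int iter = 0;
  while (t < t1) {
    if (++iter > 2000000)
      stop("TMDD solver exceeded iteration budget at t = %f", t);
    if (h > t1 - t) h = t1 - t;
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * a21 * k1[i];
    tmdd_rhs(yt, rate, p, k2);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    tmdd_rhs(yt, rate, p, k3);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    tmdd_rhs(yt, rate, p, k4);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    tmdd_rhs(yt, rate, p, k5);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    tmdd_rhs(yt, rate, p, k6);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    tmdd_rhs(ynew, rate, p, k7);
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / n);
    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) {
        y[i] = ynew[i];
        k1[i] = k7[i];  // FSAL
      }
    }
    double fac = errnorm > 1e-12 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-13) stop("TMDD solver step-size underflow at t = %f", t);
  }
}

// [[Rcpp::export]]
NumericMatrix tmdd_solve_cpp(NumericVector params, NumericVector dose_times,
                             NumericVector dose_amounts,
                             NumericVector dose_durations,
                             NumericVector obs_times, double rtol = 1e-8,
                             double atol = 1e-10) {
  TmddPars p;
  p.CL = params["CL"];
  p.V1 = params["V1"];
  p.Q = params["Q"];
  p.V2 = params["V2"];
  p.CLRC = params["CL_RC"];
  p.kout = params["kout"];
  p.Kss = params["Kss"];
  double BM0 = params["BM0"];
  p.kin = BM0 * p.kout;

  int nd = dose_times.size();
  int nt = obs_times.size();
  for (int i = 1; i < nt; ++i)
    if (obs_times[i] < obs_times[i - 1]) stop("obs_times must be sorted");

  // event boundaries where the infusion rate changes
  std::vector<double> bounds;
  for (int i = 0; i < nd; ++i) {
    bounds.push_back(dose_times[i]);
    bounds.push_back(dose_times[i] + dose_durations[i]);
  }
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());

  double y[3] = {0.0, BM0, 0.0};
  NumericMatrix out(nt, 3);
  colnames(out) = CharacterVector::create("Ctot", "Rtot", "A2");

  double t = 0.0;
  int iobs = 0;
  // emit any observations at or before time zero
  while (iobs < nt && obs_times[iobs] <= 0.0) {
    out(iobs, 0) = y[0];
    out(iobs, 1) = y[1];
    out(iobs, 2) = y[2];
    ++iobs;
  }
  // march over merged boundary/observation checkpoints
  size_t ib = 0;
  while (ib < bounds.size() && bounds[ib] <= t) ++ib;
  while (iobs < nt || ib < bounds.size()) {
    double tnext;
    bool is_obs;
    double next_bound =
        ib < bounds.size() ? bounds[ib] : std::numeric_limits<double>::max();
    double next_obs =
        iobs < nt ? obs_times[iobs] : std::numeric_limits<double>::max();
    if (next_obs <= next_bound) {
      tnext = next_obs;
      is_obs = true;
    } else {
      tnext = next_bound;
      is_obs = false;
    }
    // infusion rate active over (t, tnext]
    double rate = 0.0;
    double tm = 0.5 * (t + tnext);
    for (int i = 0; i < nd; ++i)
      if (tm >= dose_times[i] && tm < dose_times[i] + dose_durations[i])
        rate += dose_amounts[i] / dose_durations[i];
    integrate_segment(y, t, tnext, rate, p, rtol, atol);
    t = tnext;
    if (is_obs) {
      out(iobs, 0) = y[0];
      out(iobs, 1) = y[1];
      out(iobs, 2) = y[2];
      ++iobs;
    } else {
      ++ib;
    }
  }
  return out;
}
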