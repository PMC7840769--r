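// Core overdamped Langevin loop for a single enzyme coupled to a
// treadmilling filament through truncated-parabola binding wells.
// Units throughout: nm, s, kBT == 1.  D in nm^2/s, forces in kBT/nm.
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// Nearest-live-subunit force.  Subunit centers sit at xS + j*L0 for
// j = 0..n-1 (j = 0 is the shrinking end).  Wells of adjacent interior
// subunits tile the filament when a == L0/2; ties at well boundaries go to
// the smaller index via the rounding convention of floor(u + 0.5).
inline double well_force(double x, double xS, int nsub, double L0,
                         double a, double U0) {
  double u = (x - xS) / L0;
  long j = static_cast<long>(std::floor(u + 0.5));
  if (j < 0) j = 0;
  if (j > nsub - 1) j = nsub - 1;
  double dx = x - (xS + j * L0);
  if (std::fabs(dx) <= a) return -2.0 * U0 * dx / (a * a);
  return 0.0;
}

inline double well_energy(double x, double xS, int nsub, double L0,
                          double a, double U0) {
  double u = (x - xS) / L0;
  long j = static_cast<long>(std::floor(u + 0.5));
  if (j < 0) j = 0;
  if (j > nsub - 1) j = nsub - 1;
  double dx = x - (xS + j * L0);
  if (std::fabs(dx) <= a) return -U0 * (1.0 - (dx / a) * (dx / a));
  return 0.0;
}

// One integration step.  scheme 0: exact Ornstein-Uhlenbeck propagator
// inside a well (the force is linear there, so mean decay E = exp(-kD dt)
// and variance (1 - E^2)/k are exact at any dt) and a plain diffusive step
// outside; scheme 1: explicit Euler-Maruyama everywhere.
struct Stepper {
  double D, U0, a, L0, dt, sigma, k, E, S;
  int nsub, scheme;
  template <class RNG, class DIST>
  inline double step(double x, double xS, RNG &rng, DIST &gauss) const {
    double u = (x - xS) / L0;
    long j = static_cast<long>(std::floor(u + 0.5));
    if (j < 0) j = 0;
    if (j > nsub - 1) j = nsub - 1;
    double xc = xS + j * L0;
    double dx = x - xc;
    if (U0 > 0.0 && std::fabs(dx) <= a) {
      if (scheme == 0) return xc + E * dx + S * gauss(rng);
      return x - D * (2.0 * U0 * dx / (a * a)) * dt + sigma * gauss(rng);
    }
    return x + sigma * gauss(rng);
  }
};

inline Stepper make_stepper(double D, double U0, double a, double L0,
                            int nsub, double dt, int scheme) {
  Stepper st;
  st.D = D; st.U0 = U0; st.a = a; st.L0 = L0; st.dt = dt;
  st.nsub = nsub; st.scheme = scheme;
  st.sigma = std::sqrt(2.0 * D * dt);
  st.k = (U0 > 0.0) ? 2.0 * U0 / (a * a) : 0.0;
  if (st.k > 0.0) {
    st.E = std::exp(-st.k * D * dt);
    st.S = std::sqrt((1.0 - st.E * st.E) / st.k);
  } else {
    st.E = 1.0; st.S = st.sigma;
  }
  return st;
}

} // namespace

// [[Rcpp::export]]
double cpp_binding_energy(double x, double xS, int nsub, double L0,
                          double a, double U0) {
  return well_energy(x, xS, nsub, L0, a, U0);
}

// [[Rcpp::export]]
double cpp_binding_force(double x, double xS, int nsub, double L0,
                         double a, double U0) {
  return well_force(x, xS, nsub, L0, a, U0);
}

// Single-enzyme trajectory.
//
// stop_mode: 0 = run to tmax or escape-termination (beyond escape_margin of
//                either end continuously for > escape_hold seconds);
//            1 = as 0, but return as soon as the persistence criterion is
//                met (propensity screening);
//            2 = first-passage lifetime: stop the first instant the enzyme
//                is more than escape_margin beyond either end.
// track_end: 0 = shrinking end, 1 = growing end (reference for the
//                persistence gap criterion).
// [[Rcpp::export]]
List cpp_simulate(double D, double U0, double a, double L0, int nsub,
                  double vz, double dt, double tmax, double x0,
                  int record_every, int stop_mode, int track_end,
                  double max_gap, double min_dur, double speed_frac,
                  double escape_margin, double escape_hold, double seed,
                  int scheme) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  const Stepper st = make_stepper(D, U0, a, L0, nsub, dt, scheme);
  const long nstep = static_cast<long>(std::ceil(tmax / dt));
  long period = 0;
  if (vz > 0.0) {
    period = static_cast<long>(std::lround(L0 / (vz * dt)));
    if (period < 1) stop("time step too large for this treadmilling speed");
  }

  double x = x0, xS = 0.0;
  const double span = (nsub - 1) * L0;
  long countdown = period;

  const std::size_t cap = static_cast<std::size_t>(nstep / record_every) + 2;
  std::vector<double> rec_t, rec_x, rec_xS;
  std::vector<int> rec_b;
  rec_t.reserve(cap); rec_x.reserve(cap); rec_xS.reserve(cap);
  rec_b.reserve(cap);

  bool persistent = false;
  double persistent_onset = NA_REAL;
  bool in_run = false;
  bool dropped = false;      // drop event since the last record sample
  bool touched = true;       // reached the tracked end's well this period
  double run_t0 = 0.0, run_x0 = 0.0;
  long run_n = 0, run_close = 0; // samples in run / within L0 of the end
  double out_since = -1.0;   // time at which enzyme went beyond the margin
  double escape_time = NA_REAL;
  int terminated = 0;        // 0 = tmax, 1 = escape, 2 = persistent stop
  std::vector<double> drop_times;

  auto record = [&](double t) {
    rec_t.push_back(t);
    rec_x.push_back(x);
    rec_xS.push_back(xS);
    double u = (x - xS) / L0;
    long j = static_cast<long>(std::floor(u + 0.5));
    if (j < 0) j = 0;
    if (j > nsub - 1) j = nsub - 1;
    rec_b.push_back(std::fabs(x - (xS + j * L0)) <= a ? 1 : 0);
  };

  record(0.0);

  long step = 0;
  while (step < nstep) {
    ++step;
    // treadmilling clock: one subunit off the shrinking end, one onto the
    // growing end; filament length is conserved.  A "drop" is a failed
    // catch-up: the enzyme stayed behind the tracked end's well for an
    // entire event period, i.e. it never reached the end subunit before
    // that subunit itself departed.  Drops terminate persistent-following
    // runs (the event-wise mirror of the analytic stay-on/catch-up
    // decomposition).
    if (period > 0 && --countdown == 0) {
      if (!touched) {
        drop_times.push_back(step * dt);
        dropped = true;
      }
      xS += L0;
      countdown = period;
      touched = (x >= ((track_end == 0) ? xS : xS + span) - a);
    }
    x = st.step(x, xS, rng, gauss);
    double t = step * dt;
    if (!touched && x >= ((track_end == 0) ? xS : xS + span) - a) {
      touched = true;
    }

    if (!std::isfinite(x)) stop("non-finite enzyme position at t = %f", t);

    double xG = xS + span;
    bool outside = (x < xS - escape_margin) || (x > xG + escape_margin);

    if (stop_mode == 2) {
      if (outside) {
        escape_time = t;
        terminated = 1;
        record(t);
        break;
      }
    } else {
      if (outside) {
        if (out_since < 0.0) out_since = t;
        if (t - out_since > escape_hold) {
          escape_time = out_since;
          terminated = 1;
          record(t);
          break;
        }
      } else {
        out_since = -1.0;
      }
    }

    if (step % record_every == 0) {
      record(t);
      if (stop_mode != 2) {
        double ref = (track_end == 0) ? xS : xG;
        bool near = std::fabs(x - ref) < max_gap && !dropped;
        dropped = false;
        if (near && !in_run) {
          in_run = true; run_t0 = t; run_x0 = x;
          run_n = 0; run_close = 0;
        } else if (!near) {
          in_run = false;
        }
        if (in_run) {
          ++run_n;
          // "at the end" = within the catch-up zone: no farther from the
          // end-subunit center than the neighbouring well's edge
          if (std::fabs(x - ref) <= L0 + a) ++run_close;
        }
        // follow test: long enough, advancing with the end, and spending
        // at least half its samples in the catch-up zone
        if (in_run && !persistent && (t - run_t0) >= min_dur &&
            (x - run_x0) > std::max(1e-12, speed_frac * vz * (t - run_t0)) &&
            2 * run_close >= run_n) {
          persistent = true;
          persistent_onset = t;
          if (stop_mode == 1) { terminated = 2; break; }
        }
      }
    }
  }

  return List::create(
    _["t"] = rec_t, _["x"] = rec_x, _["x_S"] = rec_xS,
    _["bound"] = rec_b,
    _["span"] = span,
    _["persistent"] = persistent,
    _["persistent_onset"] = persistent_onset,
    _["escape_time"] = escape_time,
    _["drop_times"] = drop_times,
    _["terminated"] = terminated,
    _["censored"] = (terminated == 0));
}

// Multiple enzymes on one filament with optional hard-core exclusion of
// diameter `excl`: a proposed move that would land within `excl` of another
// enzyme is rejected (positions cannot cross in 1D under this rule).
// [[Rcpp::export]]
List cpp_simulate_multi(double D, double U0, double a, double L0, int nsub,
                        double vz, double dt, double tmax,
                        NumericVector x0, int record_every,
                        double escape_margin, bool exclusion, double excl,
                        double seed, int scheme) {
  const int ne = x0.size();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  const Stepper st = make_stepper(D, U0, a, L0, nsub, dt, scheme);
  const long nstep = static_cast<long>(std::ceil(tmax / dt));
  long period = 0;
  if (vz > 0.0) {
    period = static_cast<long>(std::lround(L0 / (vz * dt)));
    if (period < 1) stop("time step too large for this treadmilling speed");
  }

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> lifetime(ne, NA_REAL);
  std::vector<bool> alive(ne, true);
  double xS = 0.0;
  const double span = (nsub - 1) * L0;
  long countdown = period;

  const std::size_t cap = static_cast<std::size_t>(nstep / record_every) + 2;
  std::vector<double> rec_t; rec_t.reserve(cap);
  std::vector<std::vector<double>> rec_x(ne);
  for (int i = 0; i < ne; ++i) rec_x[i].reserve(cap);
  std::vector<double> rec_xS; rec_xS.reserve(cap);

  auto record = [&](double t) {
    rec_t.push_back(t);
    rec_xS.push_back(xS);
    for (int i = 0; i < ne; ++i) rec_x[i].push_back(x[i]);
  };
  record(0.0);

  long step = 0;
  int n_alive = ne;
  while (step < nstep && n_alive > 0) {
    ++step;
    if (period > 0 && --countdown == 0) {
      xS += L0;
      countdown = period;
    }
    double t = step * dt;
    for (int i = 0; i < ne; ++i) {
      if (!alive[i]) continue;
      double prop = st.step(x[i], xS, rng, gauss);
      bool ok = true;
      if (exclusion) {
        for (int j = 0; j < ne; ++j) {
          if (j != i && alive[j] && std::fabs(prop - x[j]) < excl) {
            ok = false; break;
          }
        }
      }
      if (ok) x[i] = prop;
      double xG = xS + span;
      if (x[i] < xS - escape_margin || x[i] > xG + escape_margin) {
        alive[i] = false;
        lifetime[i] = t;
        --n_alive;
      }
    }
    if (step % record_every == 0) record(t);
  }

  List xs(ne);
  for (int i = 0; i < ne; ++i) xs[i] = rec_x[i];
  return List::create(
    _["t"] = rec_t, _["x"] = xs, _["x_S"] = rec_xS, _["span"] = span,
    _["lifetime"] = lifetime);
}

// Mean dwell micro-simulation for tau_D: a single static well at the
// origin; first time the enzyme is more than d_esc from the well center.
// Returns NA when censored at tmax.
// [[Rcpp::export]]
double cpp_escape_time(double D, double U0, double a, double d_esc,
                       double dt, double tmax, double seed, int scheme) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  const Stepper st = make_stepper(D, U0, a, 1e9, 1, dt, scheme);
  const long nstep = static_cast<long>(std::ceil(tmax / dt));
  // single well at the origin: place the one subunit center there
  double x = 0.0;
  const double xS = 0.0;
  for (long step = 1; step <= nstep; ++step) {
    x = st.step(x, xS, rng, gauss);
    if (std::fabs(x) > d_esc) return step * dt;
  }
  return NA_REAL;
}

// Catch-up micro-simulation for tau_C: the enzyme starts at the former
// position of a departed end subunit (origin); the new end well sits at
// +L0.  Success = entering the new well (x >= L0 - a); failure = drifting
// further than fail_dist behind.  Returns the catch-up time, or -1 on
// failure, or NA when censored.
// [[Rcpp::export]]
double cpp_catchup_time(double D, double U0, double a, double L0,
                        double fail_dist, double dt, double tmax,
                        double seed, int scheme) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  // one well centered at +L0 (the new end subunit); enzyme starts at the
  // departed subunit's former center (origin)
  const Stepper st = make_stepper(D, U0, a, 1e9, 1, dt, scheme);
  const long nstep = static_cast<long>(std::ceil(tmax / dt));
  double x = 0.0;
  const double xS = L0;
  for (long step = 1; step <= nstep; ++step) {
    x = st.step(x, xS, rng, gauss);
    if (x >= L0 - a) return step * dt;
    if (x <= -fail_dist) return -1.0;
  }
  return NA_REAL;
}
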