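#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <numeric>
using namespace Rcpp;

// Positivity-preserving conservative finite-volume time stepper for the
// three model variants on [-1, 1] with zero-flux boundaries:
//   scheme 1: du/dt = d/dx( u d/dx[ u - gamma K*u - A ] )
//   scheme 2: du/dt = d/dx( u d/dx[ (1-gamma) u - (gamma sigma^2/2) u'' - A ] )
//   scheme 3: du/dt = d2u/dx2 - d/dx( u d/dx[ gamma K*u + A ] )
// Fluxes upwind the advected density on the sign of the interface velocity,
// so mass telescopes exactly and vanishing cells cannot go negative.

static inline void band_conv(const std::vector<double>& u,
                             const std::vector<double>& kw,
                             int rad, std::vector<double>& out) {
  const int n = (int)u.size();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const int jlo = std::max(-rad, -i);
    const int jhi = std::min(rad, n - 1 - i);
    const double* uw = u.data() + i;
    const double* ww = kw.data() + rad;
    for (int j = jlo; j <= jhi; ++j) s += ww[j] * uw[j];
    out[i] = s;
  }
}

static inline void second_diff(const std::vector<double>& u, double dx,
                               std::vector<double>& d2) {
  const int n = (int)u.size();
  const double idx2 = 1.0 / (dx * dx);
  for (int i = 1; i < n - 1; ++i)
    d2[i] = (u[i - 1] - 2.0 * u[i] + u[i + 1]) * idx2;
  d2[0] = (2.0 * u[0] - 5.0 * u[1] + 4.0 * u[2] - u[3]) * idx2;
  d2[n - 1] = (2.0 * u[n - 1] - 5.0 * u[n - 2] + 4.0 * u[n - 3] - u[n - 4]) * idx2;
}

// [[Rcpp::export]]
List fv_run_cpp(NumericVector u0, double dx, double dt, double max_time,
                double tol, int scheme, double gamma, double sigma,
                NumericVector A, NumericVector kw, double p_target,
                int record_every) {
  const int n = u0.size();
  const int rad = (kw.size() - 1) / 2;
  const bool need_conv = (scheme == 1 || scheme == 3);
  const double sig2h = 0.5 * gamma * sigma * sigma;

  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> unew(n), xi(n), KU(n, 0.0), d2(n, 0.0), F(n - 1);
  std::vector<double> kwv(kw.begin(), kw.end());
  std::vector<double> Av(A.begin(), A.end());

  const double mass0 = std::accumulate(u.begin(), u.end(), 0.0) * dx;
  double max_mass_err = 0.0, min_u = 0.0, max_e_inc = -INFINITY;
  double clip_total = 0.0, e_prev = NA_REAL, maxdiff = NA_REAL;
  bool have_prev = false, converged = false;
  int error_code = 0;
  long nmax = (long)std::ceil(max_time / dt);
  if (nmax < 1) nmax = 1;
  long steps = 0;

  std::vector<double> e_series, e_times;
  e_series.reserve(2048); e_times.reserve(2048);

  for (long it = 0; it < nmax; ++it) {
    // auxiliary fields of the current state
    if (need_conv) band_conv(u, kwv, rad, KU);
    if (scheme == 2) second_diff(u, dx, d2);
    if (scheme == 1) {
      for (int i = 0; i < n; ++i) xi[i] = u[i] - gamma * KU[i] - Av[i];
    } else if (scheme == 2) {
      for (int i = 0; i < n; ++i)
        xi[i] = (1.0 - gamma) * u[i] - sig2h * d2[i] - Av[i];
    } else {
      for (int i = 0; i < n; ++i) xi[i] = gamma * KU[i] + Av[i]; // potential V
    }

    // discrete energy of the current state
    double e = 0.0;
    if (scheme == 1) { // E1 = int u (u - 2A - gamma K*u)
      for (int i = 0; i < n; ++i)
        e += u[i] * (u[i] - 2.0 * Av[i] - gamma * KU[i]);
    } else if (scheme == 2) {
      for (int i = 0; i < n; ++i)
        e += u[i] * ((1.0 - gamma) * u[i] - 2.0 * Av[i] - sig2h * d2[i]);
    } else { // free energy of the linear-diffusion model
      for (int i = 0; i < n; ++i) {
        double ul = (u[i] > 0.0) ? u[i] * std::log(u[i]) : 0.0;
        e += 2.0 * ul - 2.0 * Av[i] * u[i] - gamma * u[i] * KU[i];
      }
    }
    e *= dx;
    if (have_prev && (e - e_prev) > max_e_inc) max_e_inc = e - e_prev;
    e_prev = e; have_prev = true;
    if (it % record_every == 0) {
      e_series.push_back(e);
      e_times.push_back(it * dt);
    }

    // interface fluxes
    if (scheme != 3) {
      for (int i = 0; i < n - 1; ++i) {
        double s = (xi[i + 1] - xi[i]) / dx;      // d(xi)/dx at interface
        double uup = (s < 0.0) ? u[i] : u[i + 1]; // upwind on velocity -s
        F[i] = uup * s;
      }
      for (int i = 0; i < n; ++i) {
        double fr = (i < n - 1) ? F[i] : 0.0;
        double fl = (i > 0) ? F[i - 1] : 0.0;
        unew[i] = u[i] + dt * (fr - fl) / dx;
      }
    } else {
      for (int i = 0; i < n - 1; ++i) {
        double sv = (xi[i + 1] - xi[i]) / dx;      // dV/dx, advection velocity
        double uup = (sv > 0.0) ? u[i] : u[i + 1]; // upwind on +sv
        F[i] = (u[i + 1] - u[i]) / dx - uup * sv;  // G = u_x - u V_x
      }
      for (int i = 0; i < n; ++i) {
        double fr = (i < n - 1) ? F[i] : 0.0;
        double fl = (i > 0) ? F[i - 1] : 0.0;
        unew[i] = u[i] + dt * (fr - fl) / dx;
      }
    }

    // diagnostics, clipping, convergence
    double mn = unew[0], md = 0.0;
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(unew[i])) { bad = true; break; }
      if (unew[i] < mn) mn = unew[i];
      double d = std::fabs(unew[i] - u[i]);
      if (d > md) md = d;
    }
    if (bad) { error_code = 1; break; }
    if (mn < min_u) min_u = mn;
    if (mn < 0.0) {
      double clipped = 0.0, msum = 0.0;
      for (int i = 0; i < n; ++i) {
        if (unew[i] < 0.0) { clipped -= unew[i]; unew[i] = 0.0; }
        msum += unew[i];
      }
      clip_total += clipped * dx;
      if (msum > 0.0) {
        double scale = (mass0 / dx) / msum;
        for (int i = 0; i < n; ++i) unew[i] *= scale;
      }
      if (clip_total > 1e-8 * p_target) { error_code = 2; break; }
    }
    double mass = std::accumulate(unew.begin(), unew.end(), 0.0) * dx;
    double merr = std::fabs(mass - mass0);
    if (merr > max_mass_err) max_mass_err = merr;

    u.swap(unew);
    ++steps;
    maxdiff = md;
    if (md < tol) { converged = true; break; }
  }

  // energy of the final state
  if (error_code == 0) {
    if (need_conv) band_conv(u, kwv, rad, KU);
    if (scheme == 2) second_diff(u, dx, d2);
    double e = 0.0;
    if (scheme == 1) {
      for (int i = 0; i < n; ++i)
        e += u[i] * (u[i] - 2.0 * Av[i] - gamma * KU[i]);
    } else if (scheme == 2) {
      for (int i = 0; i < n; ++i)
        e += u[i] * ((1.0 - gamma) * u[i] - 2.0 * Av[i] - sig2h * d2[i]);
    } else {
      for (int i = 0; i < n; ++i) {
        double ul = (u[i] > 0.0) ? u[i] * std::log(u[i]) : 0.0;
        e += 2.0 * ul - 2.0 * Av[i] * u[i] - gamma * u[i] * KU[i];
      }
    }
    e *= dx;
    if (have_prev && (e - e_prev) > max_e_inc) max_e_inc = e - e_prev;
    e_series.push_back(e);
    e_times.push_back(steps * dt);
  }

  return List::create(
    _["u"] = NumericVector(u.begin(), u.end()),
    _["t"] = steps * dt,
    _["steps"] = (double)steps,
    _["converged"] = converged,
    _["max_diff"] = maxdiff,
    _["max_mass_err"] = max_mass_err,
    _["min_u"] = min_u,
    _["max_energy_increase"] = (have_prev ? max_e_inc : NA_REAL),
    _["clipped_mass"] = clip_total,
    _["energy"] = NumericVector(e_series.begin(), e_series.end()),
    _["energy_t"] = NumericVector(e_times.begin(), e_times.end()),
    _["error_code"] = error_code);
}
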