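// Simulation kernels: OU spring, stochastic elastic pendulum, spherical
// Brownian motion of the transition dipole, the per-excitation
// time-inhomogeneous photon CTMC, and the exact two-state reference engine.
//
// All randomness comes from R's RNG (norm_rand/exp_rand/unif_rand), so a
// set.seed() on the R side makes every kernel call bitwise reproducible.
// Units: ns, nm, rates 1/ns.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double POLE_EPS = 1e-6;   // |sin(theta)| rejection threshold
static const double R_MIN    = 1e-3;   // nm, radial floor for the pendulum

// ---------------------------------------------------------------- OU spring

// Euler-Heun step; additive noise, so the Heun corrector only averages the
// drift (Ito and Stratonovich coincide).
static inline void ou_step(double x[3], const double k[3], const double xeq[3],
                           double sigma, double dt) {
  const double sq = sigma * std::sqrt(dt);
  for (int i = 0; i < 3; ++i) {
    const double dW = (sigma > 0.0) ? sq * norm_rand() : 0.0;
    const double f0 = -k[i] * (x[i] - xeq[i]);
    const double xp = x[i] + f0 * dt + dW;
    const double f1 = -k[i] * (xp - xeq[i]);
    x[i] += 0.5 * (f0 + f1) * dt + dW;
  }
}

// ---------------------------------------------------------- elastic pendulum

struct PendPars { double kr, req, kth, sr, sth, sph; };

// state s = (r, theta, phi)
static inline void pend_drift_diff(const double s[3], const PendPars &p,
                                   double f[3], double g[3]) {
  const double r = s[0], th = s[1];
  f[0] = -p.kr * (r - p.req);
  if (p.sr > 0.0) f[0] += p.sr * p.sr / r;        // radial curvature drift
  f[1] = -p.kth * std::sin(th);
  if (p.sth > 0.0)                                 // polar curvature drift
    f[1] += p.sth * p.sth / (2.0 * r * r * std::tan(th));
  f[2] = 0.0;
  g[0] = p.sr;
  g[1] = p.sth / r;
  g[2] = (p.sph > 0.0) ? p.sph / (r * std::sin(th)) : 0.0;
}

// One Stratonovich-Heun attempt; returns false if the step must be rejected
// (radius hit the floor or an angular-noise step crossed a pole).
static bool pend_try(double s[3], const PendPars &p, double dt) {
  const bool ang_noise = (p.sth > 0.0) || (p.sph > 0.0);
  double f0[3], g0[3], f1[3], g1[3], dW[3], sp[3], sn[3];
  const double sq = std::sqrt(dt);
  for (int i = 0; i < 3; ++i) dW[i] = sq * norm_rand();
  pend_drift_diff(s, p, f0, g0);
  for (int i = 0; i < 3; ++i) sp[i] = s[i] + f0[i] * dt + g0[i] * dW[i];
  if (sp[0] < R_MIN) return false;
  if (ang_noise && std::fabs(std::sin(sp[1])) < POLE_EPS) return false;
  pend_drift_diff(sp, p, f1, g1);
  for (int i = 0; i < 3; ++i)
    sn[i] = s[i] + 0.5 * (f0[i] + f1[i]) * dt + 0.5 * (g0[i] + g1[i]) * dW[i];
  if (sn[0] < R_MIN) return false;
  double th = sn[1], ph = sn[2];
  if (th < -M_PI || th > 2.0 * M_PI) return false;  // wild step
  if (th < 0.0)   { th = -th;            ph += M_PI; }
  if (th > M_PI)  { th = 2.0 * M_PI - th; ph += M_PI; }
  if (ang_noise && std::sin(th) < POLE_EPS) return false;
  ph -= 2.0 * M_PI * std::floor(ph / (2.0 * M_PI));   // wrap into [0, 2pi)
  s[0] = sn[0]; s[1] = th; s[2] = ph;
  return true;
}

// Rejected steps are retried as two half steps (fresh noise), up to 25
// levels; a final fallback nudges the state off the singular set.
static void pend_step(double s[3], const PendPars &p, double dt, int depth) {
  double tmp[3] = { s[0], s[1], s[2] };
  if (pend_try(tmp, p, dt)) { s[0] = tmp[0]; s[1] = tmp[1]; s[2] = tmp[2]; return; }
  if (depth >= 25) {
    if (s[0] < R_MIN) s[0] = R_MIN;
    if (s[1] < 1e-5) s[1] = 1e-5;
    if (s[1] > M_PI - 1e-5) s[1] = M_PI - 1e-5;
    return;
  }
  pend_step(s, p, 0.5 * dt, depth + 1);
  pend_step(s, p, 0.5 * dt, depth + 1);
}

static inline void pend_pos(const double s[3], const double a[3],
                            double pos[3]) {
  const double st = std::sin(s[1]);
  pos[0] = a[0] + s[0] * st * std::cos(s[2]);
  pos[1] = a[1] + s[0] * st * std::sin(s[2]);
  pos[2] = a[2] + s[0] * std::cos(s[1]);
}

// ------------------------------------------------------------------- dipole

static inline void rand_sphere(double m[3]) {
  double n2;
  do {
    m[0] = norm_rand(); m[1] = norm_rand(); m[2] = norm_rand();
    n2 = m[0] * m[0] + m[1] * m[1] + m[2] * m[2];
  } while (n2 < 1e-12);
  const double inv = 1.0 / std::sqrt(n2);
  m[0] *= inv; m[1] *= inv; m[2] *= inv;
}

// Tangent-plane Gaussian increment + renormalization: Brownian motion on
// S^2 with generator D * Laplacian (per-step E[mu.mu0] factor 1 - 2 D dt).
static inline void dipole_step(double mu[3], double D, double dt) {
  if (D <= 0.0) return;
  const double sq = std::sqrt(2.0 * D * dt);
  double xi[3] = { sq * norm_rand(), sq * norm_rand(), sq * norm_rand() };
  const double dot = xi[0] * mu[0] + xi[1] * mu[1] + xi[2] * mu[2];
  double v[3], n2 = 0.0;
  for (int i = 0; i < 3; ++i) {
    v[i] = mu[i] + xi[i] - dot * mu[i];
    n2 += v[i] * v[i];
  }
  const double inv = 1.0 / std::sqrt(n2);
  for (int i = 0; i < 3; ++i) mu[i] = v[i] * inv;
}

static inline double kappa2_of(const double muD[3], const double muA[3],
                               const double rv[3], double r) {
  const double rh0 = rv[0] / r, rh1 = rv[1] / r, rh2 = rv[2] / r;
  const double dDA = muD[0] * muA[0] + muD[1] * muA[1] + muD[2] * muA[2];
  const double dD  = rh0 * muD[0] + rh1 * muD[1] + rh2 * muD[2];
  const double dA  = rh0 * muA[0] + rh1 * muA[1] + rh2 * muA[2];
  const double c = dDA - 3.0 * dD * dA;
  return c * c;
}

// --------------------------------------------------------- exported paths

// [[Rcpp::export]]
NumericMatrix cpp_ou_path(NumericVector x0, NumericVector krate,
                          NumericVector xeq, double sigma,
                          NumericVector tgrid) {
  const int n = tgrid.size();
  NumericMatrix out(n, 3);
  double x[3] = { x0[0], x0[1], x0[2] };
  double k[3] = { krate[0], krate[1], krate[2] };
  double xe[3] = { xeq[0], xeq[1], xeq[2] };
  for (int j = 0; j < 3; ++j) out(0, j) = x[j];
  for (int i = 1; i < n; ++i) {
    ou_step(x, k, xe, sigma, tgrid[i] - tgrid[i - 1]);
    for (int j = 0; j < 3; ++j) out(i, j) = x[j];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_pendulum_path(NumericVector s0, NumericVector pars,
                                NumericVector tgrid) {
  const int n = tgrid.size();
  NumericMatrix out(n, 3);
  double s[3] = { s0[0], s0[1], s0[2] };
  PendPars p = { pars[0], pars[1], pars[2], pars[3], pars[4], pars[5] };
  for (int j = 0; j < 3; ++j) out(0, j) = s[j];
  for (int i = 1; i < n; ++i) {
    pend_step(s, p, tgrid[i] - tgrid[i - 1], 0);
    for (int j = 0; j < 3; ++j) out(i, j) = s[j];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_dipole_path(NumericVector mu0, double D,
                              NumericVector tgrid) {
  const int n = tgrid.size();
  NumericMatrix out(n, 3);
  double mu[3] = { mu0[0], mu0[1], mu0[2] };
  for (int j = 0; j < 3; ++j) out(0, j) = mu[j];
  for (int i = 1; i < n; ++i) {
    dipole_step(mu, D, tgrid[i] - tgrid[i - 1]);
    for (int j = 0; j < 3; ++j) out(i, j) = mu[j];
  }
  return out;
}

// -------------------------------------------------------------- burst engine

// One burst of the simulated smFRET experiment.
//
// model: 0 = spring (isotropic/anisotropic/frozen via spring pars),
//        1 = elastic pendulum.
// Per excitation: dipoles are resampled uniformly (photoselection not
// modeled); the donor clock T_D ~ Exp(k_D) competes with the
// inhomogeneous transfer hazard k_ET(t) = k_D * C * kappa2(t) / r(t)^6 via
// integrated-hazard (trapezoid) inversion; if transfer wins, the acceptor
// emits after an extra Exp(k_A) residence. Translational state evolves on
// the fine grid over the full donor-clock window [0, min(T_D, horizon)]
// and persists across excitations within the burst, so the per-excitation
// path-average kappa2 diagnostic is computed on a window independent of
// the kappa2 path itself (unbiased, mean 2/3).
//
// Returns per-excitation outcome (0 donor, 1 acceptor, 2 censored), delay,
// detection flags, path-average kappa2, and the final translational state.
// [[Rcpp::export]]
List cpp_simulate_burst(int model, bool dynamic_kappa,
                        NumericVector stateD0, NumericVector stateA0,
                        NumericVector attachD, NumericVector attachA,
                        NumericVector springKD, NumericVector springKA,
                        NumericVector xeqD, NumericVector xeqA,
                        double sigmaD, double sigmaA,
                        NumericVector pendParsD, NumericVector pendParsA,
                        double DrotD, double DrotA,
                        double k_D, double k_A, double Cconst,
                        double kappa2_static,
                        int n_ex, double dt, double horizon,
                        double det_D, double det_A) {
  double sD[3] = { stateD0[0], stateD0[1], stateD0[2] };
  double sA[3] = { stateA0[0], stateA0[1], stateA0[2] };
  const double aD[3] = { attachD[0], attachD[1], attachD[2] };
  const double aA[3] = { attachA[0], attachA[1], attachA[2] };
  double kD3[3] = { springKD[0], springKD[1], springKD[2] };
  double kA3[3] = { springKA[0], springKA[1], springKA[2] };
  double xeD[3] = { xeqD[0], xeqD[1], xeqD[2] };
  double xeA[3] = { xeqA[0], xeqA[1], xeqA[2] };
  PendPars pD = { pendParsD[0], pendParsD[1], pendParsD[2],
                  pendParsD[3], pendParsD[4], pendParsD[5] };
  PendPars pA = { pendParsA[0], pendParsA[1], pendParsA[2],
                  pendParsA[3], pendParsA[4], pendParsA[5] };

  IntegerVector outcome(n_ex);
  NumericVector delay(n_ex), kbar(n_ex), ttrans(n_ex);
  LogicalVector detected(n_ex);

  double posD[3], posA[3], rv[3], muD[3], muA[3];

  // current hazard and kappa2 from the current state
  auto eval = [&](double &kap, double &haz) {
    if (model == 0) {
      for (int i = 0; i < 3; ++i) { posD[i] = sD[i]; posA[i] = sA[i]; }
    } else {
      pend_pos(sD, aD, posD);
      pend_pos(sA, aA, posA);
    }
    double r2 = 0.0;
    for (int i = 0; i < 3; ++i) {
      rv[i] = posA[i] - posD[i];
      r2 += rv[i] * rv[i];
    }
    const double r6 = r2 * r2 * r2;
    if (dynamic_kappa) {
      kap = kappa2_of(muD, muA, rv, std::sqrt(r2));
    } else {
      kap = kappa2_static;
    }
    haz = k_D * Cconst * kap / r6;
  };

  auto advance = [&](double step) {
    if (model == 0) {
      ou_step(sD, kD3, xeD, sigmaD, step);
      ou_step(sA, kA3, xeA, sigmaA, step);
    } else {
      pend_step(sD, pD, step, 0);
      pend_step(sA, pA, step, 0);
    }
    if (dynamic_kappa) {
      dipole_step(muD, DrotD, step);
      dipole_step(muA, DrotA, step);
    }
  };

  for (int e = 0; e < n_ex; ++e) {
    if (dynamic_kappa) { rand_sphere(muD); rand_sphere(muA); }
    const double TD = exp_rand() / k_D;     // donor clock
    const double u  = exp_rand();           // integrated-hazard threshold
    const double Tend = (TD < horizon) ? TD : horizon;

    double t = 0.0, Lam = 0.0, kap_int = 0.0;
    double kprev, kapprev;
    eval(kapprev, kprev);
    bool transferred = false;
    double t_transfer = NA_REAL;

    while (t < Tend) {
      double step = Tend - t;
      if (step > dt) step = dt;
      advance(step);
      double kapnew, knew;
      eval(kapnew, knew);
      if (!transferred) {
        const double dLam = 0.5 * (kprev + knew) * step;
        if (Lam + dLam >= u) {
          // solve Lam + kprev*s + slope*s^2/2 = u on [0, step]
          const double a = (knew - kprev) / (2.0 * step);
          const double b = kprev;
          const double c = Lam - u;
          double sstar;
          if (std::fabs(a) < 1e-14 * (std::fabs(b) + 1.0)) {
            sstar = (b > 0.0) ? (u - Lam) / b : step;
          } else {
            double disc = b * b - 4.0 * a * c;
            if (disc < 0.0) disc = 0.0;
            sstar = (-b + std::sqrt(disc)) / (2.0 * a);
          }
          if (sstar < 0.0) sstar = 0.0;
          if (sstar > step) sstar = step;
          t_transfer = t + sstar;
          transferred = true;
        } else {
          Lam += dLam;
        }
        kprev = knew;
      }
      kap_int += 0.5 * (kapprev + kapnew) * step;
      kapprev = kapnew;
      t += step;
    }
    kbar[e] = (Tend > 0.0) ? kap_int / Tend : kapprev;

    if (transferred) {
      outcome[e] = 1;
      ttrans[e] = t_transfer;
      delay[e] = t_transfer + exp_rand() / k_A;
      detected[e] = (unif_rand() < det_A);
    } else if (TD <= horizon) {
      outcome[e] = 0;
      ttrans[e] = NA_REAL;
      delay[e] = TD;
      detected[e] = (unif_rand() < det_D);
    } else {
      outcome[e] = 2;                        // censored
      ttrans[e] = NA_REAL;
      delay[e] = NA_REAL;
      detected[e] = false;
    }
  }

  return List::create(
    _["outcome"] = outcome, _["delay"] = delay,
    _["transfer_time"] = ttrans, _["detected"] = detected,
    _["kbar"] = kbar,
    _["stateD"] = NumericVector::create(sD[0], sD[1], sD[2]),
    _["stateA"] = NumericVector::create(sA[0], sA[1], sA[2]));
}

// ----------------------------------------------------- two-state reference

// Exact event-driven burst for a transfer rate switching between kET1 and
// kET2 with symmetric rate lam (telegraph process): within an excitation,
// the next of {donor decay, transfer, switch} is sampled from competing
// exponentials; between excitations the state propagates over the laser
// repetition gap with the exact two-state transition probability.
// [[Rcpp::export]]
List cpp_twostate_burst(double kET1, double kET2, double lam,
                        double k_D, double k_A, int n_ex,
                        double t_rep, double horizon,
                        double det_D, double det_A, int state0) {
  IntegerVector outcome(n_ex), state_at(n_ex);
  NumericVector delay(n_ex);
  LogicalVector detected(n_ex);
  int s = state0;

  for (int e = 0; e < n_ex; ++e) {
    state_at[e] = s;
    double t = 0.0;
    int out = 2;
    double dl = NA_REAL;
    while (t < horizon) {
      const double ks = (s == 0) ? kET1 : kET2;
      const double tot = k_D + ks + lam;
      const double w = exp_rand() / tot;
      if (t + w > horizon) { t = horizon; break; }
      t += w;
      const double uu = unif_rand() * tot;
      if (uu < k_D) { out = 0; dl = t; break; }
      else if (uu < k_D + ks) { out = 1; dl = t + exp_rand() / k_A; break; }
      else s = 1 - s;
    }
    outcome[e] = out;
    delay[e] = dl;
    if (out == 0) detected[e] = (unif_rand() < det_D);
    else if (out == 1) detected[e] = (unif_rand() < det_A);
    else detected[e] = false;
    double gap = t_rep - t;
    if (gap > 0.0 && lam > 0.0) {
      const double pflip = 0.5 * (1.0 - std::exp(-2.0 * lam * gap));
      if (unif_rand() < pflip) s = 1 - s;
    }
  }
  return List::create(
    _["outcome"] = outcome, _["delay"] = delay,
    _["detected"] = detected, _["state_at"] = state_at,
    _["state_end"] = s);
}
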