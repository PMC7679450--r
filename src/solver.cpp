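#include <Rcpp.h>
using namespace Rcpp;

// 1D transient conduction on a node-centred finite-volume grid.
// Node 0 sits on the air-tissue surface, node n-1 on the bottom face;
// boundary nodes own half cells. Properties are per node so layered
// media reuse the same kernel; face conductivities use harmonic means.
//
// Surface flux (into the tissue, z positive downward):
//   q = h_nc (T_air - T0) + sigma * eps * (T_env_K^4 - T0_K^4)
// Radiation is evaluated on the Kelvin scale; state is held in Celsius.
//
// bottom_bc: 0 = fixed temperature T_b (Dirichlet), 1 = insulated.
// scheme:    0 = Crank-Nicolson (radiative term lagged, Picard-iterated
//                until the surface node moves < 1e-6 C, max 10 sweeps),
//            1 = explicit FTCS (caller enforces the stability bound).

static const double KELVIN = 273.15;
static const double SIGMA_SB = 5.67e-8;

static inline double rad_flux(double eps, double T_env, double T0) {
  if (eps <= 0.0) return 0.0;
  double te = T_env + KELVIN, ts = T0 + KELVIN;
  return SIGMA_SB * eps * (te * te * te * te - ts * ts * ts * ts);
}

// [[Rcpp::export(.heat_march)]]
List heat_march(NumericVector T0, double dz, double dt, int nsteps,
                NumericVector k_node, NumericVector rho_cp_node,
                double h_nc, double emissivity, double T_air, double T_env,
                int bottom_bc, double T_b, int scheme,
                IntegerVector record_steps, IntegerVector snapshot_steps) {
  const int n = T0.size();
  std::vector<double> T(T0.begin(), T0.end());
  std::vector<double> Tnew(n), kf(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    double ka = k_node[i], kb = k_node[i + 1];
    kf[i] = 2.0 * ka * kb / (ka + kb);  // harmonic mean at the face
  }

  NumericVector surface(record_steps.size());
  NumericMatrix snaps(n, snapshot_steps.size());
  int rec_i = 0, snap_i = 0;
  const int n_rec = record_steps.size(), n_snap = snapshot_steps.size();

  // capacity per unit area of each control volume
  std::vector<double> cap(n);
  for (int i = 0; i < n; ++i) cap[i] = rho_cp_node[i] * dz;
  cap[0] *= 0.5;
  cap[n - 1] *= 0.5;

  std::vector<double> a(n), b(n), c(n), d(n), bp(n), w(n);
  bool factored = false;

  for (int step = 0; step <= nsteps; ++step) {
    while (rec_i < n_rec && record_steps[rec_i] == step)
      surface[rec_i++] = T[0];
    while (snap_i < n_snap && snapshot_steps[snap_i] == step) {
      for (int i = 0; i < n; ++i) snaps(i, snap_i) = T[i];
      ++snap_i;
    }
    if (step == nsteps) break;

    if (scheme == 1) {  // explicit FTCS
      double q0 = h_nc * (T_air - T[0]) + rad_flux(emissivity, T_env, T[0]);
      Tnew[0] = T[0] + dt / cap[0] * (kf[0] * (T[1] - T[0]) / dz + q0);
      for (int i = 1; i < n - 1; ++i)
        Tnew[i] = T[i] + dt / cap[i] *
          (kf[i - 1] * (T[i - 1] - T[i]) / dz + kf[i] * (T[i + 1] - T[i]) / dz);
      if (bottom_bc == 0)
        Tnew[n - 1] = T_b;
      else
        Tnew[n - 1] = T[n - 1] + dt / cap[n - 1] *
          (kf[n - 2] * (T[n - 2] - T[n - 1]) / dz);
      std::swap(T, Tnew);
    } else {  // Crank-Nicolson (theta = 1/2), radiation lagged per Picard iterate
      const double th = 0.5;
      if (!factored) {
        // the system matrix is time-invariant (radiation enters only the
        // RHS), so the Thomas forward elimination is factored once
        b[0] = cap[0] / dt + th * (kf[0] / dz + h_nc);
        c[0] = -th * kf[0] / dz;
        for (int i = 1; i < n - 1; ++i) {
          a[i] = -th * kf[i - 1] / dz;
          c[i] = -th * kf[i] / dz;
          b[i] = cap[i] / dt + th * (kf[i - 1] / dz + kf[i] / dz);
        }
        if (bottom_bc == 0) {
          a[n - 1] = 0.0; c[n - 1] = 0.0; b[n - 1] = 1.0;
        } else {
          a[n - 1] = -th * kf[n - 2] / dz;
          c[n - 1] = 0.0;
          b[n - 1] = cap[n - 1] / dt + th * kf[n - 2] / dz;
        }
        bp[0] = b[0];
        for (int i = 1; i < n; ++i) {
          w[i] = a[i] / bp[i - 1];
          bp[i] = b[i] - w[i] * c[i - 1];
        }
        factored = true;
      }
      // explicit (old-time) halves of the fluxes
      double e0 = (1.0 - th) * (kf[0] * (T[1] - T[0]) / dz +
                                h_nc * (T_air - T[0]));
      double eb = (bottom_bc == 0) ? 0.0
                : (1.0 - th) * (kf[n - 2] * (T[n - 2] - T[n - 1]) / dz);
      double Ts_lag = T[0];
      for (int it = 0; it < 10; ++it) {
        // radiative flux at the time-centred surface temperature
        double Ts_mid = th * Ts_lag + (1.0 - th) * T[0];
        double q_rad = rad_flux(emissivity, T_env, Ts_mid);
        d[0] = cap[0] / dt * T[0] + e0 + th * h_nc * T_air + q_rad;
        for (int i = 1; i < n - 1; ++i)
          d[i] = cap[i] / dt * T[i] +
            (1.0 - th) * (kf[i - 1] * (T[i - 1] - T[i]) / dz +
                          kf[i] * (T[i + 1] - T[i]) / dz);
        d[n - 1] = (bottom_bc == 0) ? T_b
                 : cap[n - 1] / dt * T[n - 1] + eb;
        for (int i = 1; i < n; ++i) d[i] -= w[i] * d[i - 1];
        Tnew[n - 1] = d[n - 1] / bp[n - 1];
        for (int i = n - 2; i >= 0; --i)
          Tnew[i] = (d[i] - c[i] * Tnew[i + 1]) / bp[i];
        double dTs = std::fabs(Tnew[0] - Ts_lag);
        Ts_lag = Tnew[0];
        if (dTs < 1e-6 || emissivity <= 0.0) break;
      }
      std::swap(T, Tnew);
    }

    for (int i = 0; i < n; ++i)
      if (!std::isfinite(T[i]))
        stop("solver diverged: non-finite temperature at step %d", step + 1);
  }

  return List::create(_["surface"] = surface, _["snapshots"] = snaps);
}
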