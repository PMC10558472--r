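#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (separable lower-envelope algorithm).
// Squared 1-D transform over parabolas located at positions i*h.
// ---------------------------------------------------------------------------
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qh = q * h;
    double s;
    while (true) {
      double vh = v[k] * h;
      s = ((f[q] + qh * qh) - (f[v[k]] + vh * vh)) / (2.0 * qh - 2.0 * vh);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qh = q * h;
    while (z[k + 1] < qh) ++k;
    double vh = v[k] * h;
    d[q] = (qh - vh) * (qh - vh) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      if (nx > 1) dt1d(f, d, nx, spacing[0]); else d[0] = f[0];
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      if (ny > 1) dt1d(f, d, ny, spacing[1]); else d[0] = f[0];
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = out[base + stride * k];
      if (nz > 1) dt1d(f, d, nz, spacing[2]); else d[0] = f[0];
      for (int k = 0; k < nz; ++k) out[base + stride * k] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] >= INF) ? R_PosInf : std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Bioheat stepping kernel.
//
// One microwave ablation: explicit 7-point finite-difference diffusion in an
// enthalpy formulation (piecewise-linear H(T) absorbing the latent heat of
// water evaporation over the band [Tlow, Thigh]), an exact exponential
// relaxation sub-step for the Pennes perfusion term, a temperature-dependent
// absorption multiplier on the geometric deposition field, and Arrhenius
// damage accumulation.
//
// boundary_type: 0 = Dirichlet at the outer faces (ghost = 2*Tb_bc - T),
//                1 = insulated (zero flux, mirrored ghost).
// shutdown_rule: 0 = omega0 * exp(-Omega); 1 = step (omega0 while Omega < 1).
// ---------------------------------------------------------------------------

struct EnthalpyModel {
  double rho, cp, Tlow, Thigh, cpe; // cpe = cp + wf*L/(Thigh-Tlow)
  double H(double T) const {
    if (T <= Tlow) return rho * cp * T;
    if (T <= Thigh) return rho * cp * Tlow + rho * cpe * (T - Tlow);
    return rho * cp * Tlow + rho * cpe * (Thigh - Tlow) + rho * cp * (T - Thigh);
  }
  double T(double h) const {
    double h1 = rho * cp * Tlow;
    double h2 = h1 + rho * cpe * (Thigh - Tlow);
    if (h <= h1) return h / (rho * cp);
    if (h <= h2) return Tlow + (h - h1) / (rho * cpe);
    return Thigh + (h - h2) / (rho * cp);
  }
  double cp_at(double T) const {
    return (T > Tlow && T <= Thigh) ? cpe : cp;
  }
};

// [[Rcpp::export]]
List run_ablation_cpp(NumericVector T_init_vec, IntegerVector dims,
                      NumericVector spacing_m,
                      NumericVector Qgeom,        // W/m^3 at absorption 1
                      IntegerVector liver, IntegerVector vessel,
                      double rho, double cp_base, double lam,
                      double water_fraction, double Tlow, double Thigh,
                      double latent_heat,
                      double omega0, double rho_b, double cp_b, double T_b,
                      double vessel_enhancement, int sink_enabled,
                      int shutdown_rule,
                      double A, double Ea, double Rgas,
                      double dt, int n_steps,
                      int boundary_type, double boundary_T,
                      double abs_floor, double abs_Tmid, double abs_width,
                      NumericVector omega_init) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double hx2 = spacing_m[0] * spacing_m[0];
  const double hy2 = spacing_m[1] * spacing_m[1];
  const double hz2 = spacing_m[2] * spacing_m[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double dV = spacing_m[0] * spacing_m[1] * spacing_m[2];

  EnthalpyModel em;
  em.rho = rho; em.cp = cp_base; em.Tlow = Tlow; em.Thigh = Thigh;
  em.cpe = cp_base + water_fraction * latent_heat / (Thigh - Tlow);

  std::vector<double> Tc(n), Tn(n), Om(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    Tc[i] = T_init_vec[i];
    Om[i] = (omega_init.size() == n) ? omega_init[i] : 0.0;
  }

  double deposited = 0.0;
  double Tmax = -1e30;
  const double kperf = rho_b * cp_b;

  for (int step = 0; step < n_steps; ++step) {
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        R_xlen_t idx = sy * j + sz * k;
        for (int i = 0; i < nx; ++i, ++idx) {
          double T0 = Tc[idx];
          double lap = 0.0;
          if (nx > 1) {
            double tl = (i > 0) ? Tc[idx - sx]
                        : (boundary_type == 0 ? 2.0 * boundary_T - T0 : T0);
            double tr = (i < nx - 1) ? Tc[idx + sx]
                        : (boundary_type == 0 ? 2.0 * boundary_T - T0 : T0);
            lap += (tl - 2.0 * T0 + tr) / hx2;
          }
          if (ny > 1) {
            double tl = (j > 0) ? Tc[idx - sy]
                        : (boundary_type == 0 ? 2.0 * boundary_T - T0 : T0);
            double tr = (j < ny - 1) ? Tc[idx + sy]
                        : (boundary_type == 0 ? 2.0 * boundary_T - T0 : T0);
            lap += (tl - 2.0 * T0 + tr) / hy2;
          }
          if (nz > 1) {
            double tl = (k > 0) ? Tc[idx - sz]
                        : (boundary_type == 0 ? 2.0 * boundary_T - T0 : T0);
            double tr = (k < nz - 1) ? Tc[idx + sz]
                        : (boundary_type == 0 ? 2.0 * boundary_T - T0 : T0);
            lap += (tl - 2.0 * T0 + tr) / hz2;
          }
          double q = 0.0;
          if (Qgeom[idx] != 0.0) {
            double absf = abs_floor +
              (1.0 - abs_floor) / (1.0 + std::exp((T0 - abs_Tmid) / abs_width));
            q = Qgeom[idx] * absf;
            deposited += q * dt;
          }
          double H = em.H(T0) + dt * (lam * lap + q);
          double T1 = em.T(H);

          if (liver[idx]) {
            double om = omega0;
            if (shutdown_rule == 0) om *= std::exp(-Om[idx]);
            else if (Om[idx] >= 1.0) om = 0.0;
            if (vessel[idx] && sink_enabled) om *= vessel_enhancement;
            if (om > 0.0) {
              double kk = om * kperf / (rho * em.cp_at(T1));
              T1 = T_b + (T1 - T_b) * std::exp(-kk * dt);
            }
          }
          Tn[idx] = T1;
          if (T1 > Tmax) Tmax = T1;
          Om[idx] += dt * A * std::exp(-Ea / (Rgas * (T1 + 273.15)));
        }
      }
    }
    std::swap(Tc, Tn);
  }

  NumericVector Tout(n), Oout(n);
  for (R_xlen_t i = 0; i < n; ++i) { Tout[i] = Tc[i]; Oout[i] = Om[i]; }
  Tout.attr("dim") = dims;
  Oout.attr("dim") = dims;
  return List::create(_["T"] = Tout, _["omega"] = Oout,
                      _["deposited_J"] = deposited * dV,
                      _["T_max"] = Tmax);
}
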