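// Explicit forward-Euler engine for the radial exudation model.
//
// One step = rhizoplane boundary flux into annulus 0, conservative
// Fickian exchange between annuli (closed outer boundary), instantaneous
// Langmuir sorption equilibration, first-order mineralization. The
// engine iterates to the equilibrium criterion (max per-step relative
// concentration change below eq_tol) or max_time. All semantics mirror
// the R reference functions diffusion_step(), sorption_equilibrate(),
// mineralization_step(), boundary_flux(); tests assert step-for-step
// agreement.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List engine_run(NumericVector C_init, NumericVector sorbed_init,
                double r0, double dr, int n,
                double dt, double max_time, double eq_tol,
                double rho, double eps, double tau,
                double f_mb, double f_T, double T_K,
                double D_inf, double Smax, double Ks, double kd,
                double Ccyto, double P, double Imax, double KI, int Z,
                double A, double Em, double Fconst, double Rgas,
                double v0,
                bool retardation, int secant_slope,
                bool sorption_on, bool advection_on,
                int boundary_mode, double dirichlet_C) {
  std::vector<double> C(C_init.begin(), C_init.end());
  std::vector<double> sorbed(sorbed_init.begin(), sorbed_init.end());
  std::vector<double> V(n), A_int(n), invV(n), Cprev(n);
  std::vector<double> mineral_cum(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double ri = r0 + i * dr, ro = ri + dr;
    V[i] = M_PI * (ro * ro - ri * ri);
    A_int[i] = 2.0 * M_PI * ro;
    invV[i] = 1.0 / V[i];
  }

  // automatic sub-stepping keeps the explicit scheme inside the
  // stability bound De*dt/dr^2 <= 0.5 (retardation only lowers De)
  double De_max = D_inf * eps / (tau * tau);
  double dt_stab = 0.5 * dr * dr / De_max;
  int substeps = 1;
  if (dt > dt_stab) substeps = (int)std::ceil(dt / dt_stab);
  double dtu = dt / substeps;

  double k_eff = kd * f_mb * f_T / 3600.0;      // s^-1
  double decay = std::exp(-k_eff * dtu);
  double rse = (eps > 0.0) ? rho / eps : 0.0;   // retardation prefactor

  // boundary-flux coefficients (umol cm^-1 hr^-1, linear in Csoil)
  bool charged = (Z < 0);
  double gh_a = 0.0, gh_b = 0.0; // efflux = gh_a - gh_b * Csoil
  if (charged) {
    double u = Z * Em * Fconst / (Rgas * T_K);
    if (std::fabs(u) < 1e-12) {
      gh_a = A * P * Ccyto;
      gh_b = A * P;
    } else {
      double g = A * P * u / (std::exp(u) - 1.0);
      gh_a = g * Ccyto * std::exp(u);
      gh_b = g;
    }
  } else {
    gh_a = A * P * Ccyto;
    gh_b = A * P;
  }
  double per_s = dtu / 3600.0; // hr^-1 flux applied over one sub-step

  double t = 0.0, cum_eff = 0.0, cum_inf = 0.0, cum_min = 0.0;
  bool converged = false;
  double last_max_rel = NA_REAL;
  long steps = 0;
  long max_steps = (long)std::ceil(max_time / dtu);
  bool sorbing = sorption_on && Smax > 0.0 && Ks > 0.0;
  double aKs = Smax * Ks * rho; // per-bulk-volume initial isotherm slope

  double Dfac = D_inf * eps / (tau * tau);
  double bret = rse * Smax * Ks; // dilute-limit retardation excess
  bool ret_on = retardation && sorbing && bret > 0.0;
  // effective diffusivity at a given solution concentration
  auto De_at = [&](double c) {
    if (!ret_on) return Dfac;
    double q = 1.0 + Ks * c;
    double qq = secant_slope ? q : q * q;
    return Dfac * qq / (qq + bret);
  };
  // annular diffusive conductance between the wall and the first cell
  // centre, per cm root length (radial well coupling)
  double rc0 = r0 + 0.5 * dr;
  double ln_w = std::log(rc0 / r0);
  double Cw = 0.0; // wall concentration carried between steps

  if (boundary_mode == 1) C[0] = dirichlet_C;

  while (steps < max_steps && !converged) {
    std::copy(C.begin(), C.end(), Cprev.begin());

    // --- rhizoplane exchange (flux mode) ---
    if (boundary_mode == 0) {
      // wall concentration: the membrane flux (per hour) balances the
      // quasi-steady diffusive flux through the wall-to-centre annulus;
      // f(Cw) is monotone decreasing, solved by guarded Newton
      double g0 = 2.0 * M_PI * De_at(C[0]) / ln_w; // umol cm^-1 s^-1 per unit dC
      bool has_inf = (!charged && Imax > 0.0);
      if (Cw < 0.0) Cw = 0.0;
      for (int it = 0; it < 60; ++it) {
        double inf = 0.0, dinf = 0.0;
        if (has_inf) {
          double denom = KI + Cw;
          if (denom > 0.0) {
            inf = Imax * Cw / denom;
            dinf = Imax * KI / (denom * denom);
          }
        }
        double f = (gh_a - gh_b * Cw - inf) / 3600.0 - g0 * (Cw - C[0]);
        double fp = -(gh_b + dinf) / 3600.0 - g0;
        double step_n = f / fp;
        double Cw_new = Cw - step_n;
        if (Cw_new < 0.0) Cw_new = 0.5 * Cw;
        double scale = std::max(std::fabs(Cw_new), 1e-12);
        bool done = std::fabs(Cw_new - Cw) < 1e-14 * scale;
        Cw = Cw_new;
        if (done) break;
      }
      double eff = gh_a - gh_b * Cw;
      double inf = 0.0;
      if (has_inf) {
        double denom = KI + Cw;
        inf = (denom > 0.0) ? Imax * Cw / denom : 0.0;
      }
      C[0] += (eff - inf) * per_s / V[0];
      cum_eff += eff * per_s;
      cum_inf += inf * per_s;
    } else {
      C[0] = dirichlet_C;
    }

    // --- Fickian exchange, interface De = mean of adjacent shells ---
    {
      double De_lo = De_at(C[0]);
      double carry = 0.0; // mass change pending for shell i from inner side
      double fpref = dtu / dr;
      for (int i = 0; i < n - 1; ++i) {
        double De_hi = De_at(C[i + 1]);
        double De_if = 0.5 * (De_lo + De_hi);
        double flux = -De_if * (C[i + 1] - C[i]) * A_int[i] * fpref;
        C[i] += (carry - flux) * invV[i];
        carry = flux;
        De_lo = De_hi;
      }
      C[n - 1] += carry * invV[n - 1]; // closed outer boundary
    }

    // --- optional inward advection (upwind) ---
    if (advection_on && v0 > 0.0) {
      // upwind donor is the outer shell at every interface; solute
      // crossing the rhizoplane joins the root influx ledger
      double moved0 = v0 * C[0] * dtu;
      for (int i = 0; i < n - 1; ++i) {
        C[i] += (v0 * C[i + 1] * dtu - v0 * C[i] * dtu) / V[i];
      }
      C[n - 1] -= v0 * C[n - 1] * dtu / V[n - 1];
      cum_inf += moved0;
    }

    // --- instantaneous sorption equilibration (mass-conserving) ---
    if (sorbing) {
      for (int i = 0; i < n; ++i) {
        double Mtot = C[i] + sorbed[i];
        double b = 1.0 + aKs - Ks * Mtot;
        double disc = std::sqrt(b * b + 4.0 * Ks * Mtot);
        double Cn = (b >= 0.0) ? 2.0 * Mtot / (b + disc)
                               : (disc - b) / (2.0 * Ks);
        C[i] = Cn;
        sorbed[i] = aKs * Cn / (1.0 + Ks * Cn);
      }
      if (boundary_mode == 1) C[0] = dirichlet_C;
    }

    // --- first-order mineralization of the solution phase ---
    if (k_eff > 0.0) {
      for (int i = 0; i < n; ++i) {
        double removed = C[i] * (1.0 - decay);
        C[i] -= removed;
        mineral_cum[i] += removed * V[i];
        cum_min += removed * V[i];
      }
      if (boundary_mode == 1) {
        C[0] = dirichlet_C;
      }
    }

    // --- equilibrium criterion: max per-step relative change ---
    double max_rel = 0.0;
    int i0 = (boundary_mode == 1) ? 1 : 0;
    for (int i = i0; i < n; ++i) {
      double ref = std::max(C[i], 1e-15);
      double rel = std::fabs(C[i] - Cprev[i]) / ref;
      if (rel > max_rel) max_rel = rel;
    }
    last_max_rel = max_rel;
    t += dtu;
    ++steps;
    if (max_rel < eq_tol) converged = true;
    if (steps % 2000000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["C"] = NumericVector(C.begin(), C.end()),
    _["sorbed"] = NumericVector(sorbed.begin(), sorbed.end()),
    _["mineralized"] = NumericVector(mineral_cum.begin(), mineral_cum.end()),
    _["cum_efflux"] = cum_eff, _["cum_influx"] = cum_inf,
    _["cum_mineralized"] = cum_min, _["C_wall"] = Cw,
    _["t"] = t, _["steps"] = (double)steps, _["dt_used"] = dtu,
    _["substeps"] = substeps,
    _["converged"] = converged, _["last_max_rel"] = last_max_rel);
}
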