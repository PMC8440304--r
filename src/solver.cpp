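// One-dimensional pulse-wave propagation on a three-vessel bifurcation.
//
// Governing equations (per vessel, smooth flow regime):
//   A_t + (AU)_x = 0
//   U_t + (U^2/2 + P/rho)_x = f / (rho A),   f = -2 (zeta + 2) mu pi U
// closed by the tube law
//   P = Pext + Pd + beta (sqrt(A) - sqrt(Ad(x))) / Ad(x).
//
// Discretisation: MacCormack predictor-corrector on a uniform grid per
// vessel.  Boundaries are handled via Riemann invariants W_{1,2} = U +- 4c,
// c = sqrt(beta / (2 rho Ad)) A^{1/4}:
//   * inlet: prescribed flow rate (5th-order Fourier series), incoming
//     characteristic solved against the extrapolated outgoing one;
//   * bifurcation: mass conservation + continuity of total (or static)
//     pressure, 3x3 Newton solve;
//   * terminal outlets: three-element Windkessel (R1, C, R2), implicit
//     update of the compliance pressure.
// The solver runs whole cardiac cycles until the inlet pressure waveform is
// periodic (relative L2 change between successive cycles below tolerance).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Blood {
  double rho, mu, zeta, pext, pd;
  double fric_coef;  // -2 (zeta + 2) mu pi
};

struct Seg {
  int n;
  double dx, beta, L;
  std::vector<double> Ad;   // diastolic area at nodes
  std::vector<double> kc;   // sqrt(beta / (2 rho Ad))
  std::vector<double> A, U, As, Us, An, Un, F1, F2;
};

inline double tube_p(double A, double Ad, double beta, const Blood& bl) {
  return bl.pext + bl.pd + beta * (std::sqrt(A) - std::sqrt(Ad)) / Ad;
}

inline double dp_dA(double A, double Ad, double beta) {
  return beta / (2.0 * Ad * std::sqrt(A));
}

inline double wave_c(const Seg& s, int i, double A) {
  return s.kc[i] * std::pow(A, 0.25);
}

void fluxes(Seg& s, const std::vector<double>& A, const std::vector<double>& U,
            const Blood& bl) {
  for (int i = 0; i < s.n; ++i) {
    double p = tube_p(A[i], s.Ad[i], s.beta, bl);
    s.F1[i] = A[i] * U[i];
    s.F2[i] = 0.5 * U[i] * U[i] + p / bl.rho;
  }
}

// Linear interpolation of a Riemann invariant at the foot of a
// characteristic, distance |lambda| dt inside the domain from an end node.
inline double foot_interp(double v_end, double v_in, double lambda, double dt,
                          double dx) {
  double xi = std::fabs(lambda) * dt / dx;
  if (xi > 1.0) xi = 1.0;
  if (xi < 0.0) xi = 0.0;
  return (1.0 - xi) * v_end + xi * v_in;
}

bool solve3(double J[3][3], double g[3], double d[3]) {
  // Gaussian elimination with partial pivoting on a 3x3 system J d = -g.
  int p[3] = {0, 1, 2};
  double M[3][4];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) M[i][j] = J[i][j];
    M[i][3] = -g[i];
  }
  for (int c = 0; c < 3; ++c) {
    int piv = c;
    for (int r = c + 1; r < 3; ++r)
      if (std::fabs(M[r][c]) > std::fabs(M[piv][c])) piv = r;
    if (std::fabs(M[piv][c]) < 1e-300) return false;
    if (piv != c)
      for (int j = 0; j < 4; ++j) std::swap(M[c][j], M[piv][j]);
    for (int r = c + 1; r < 3; ++r) {
      double f = M[r][c] / M[c][c];
      for (int j = c; j < 4; ++j) M[r][j] -= f * M[c][j];
    }
  }
  for (int r = 2; r >= 0; --r) {
    double acc = M[r][3];
    for (int j = r + 1; j < 3; ++j) acc -= M[r][j] * d[j];
    d[r] = acc / M[r][r];
  }
  (void)p;
  return true;
}

}  // namespace

// [[Rcpp::export]]
List solve_bifurcation_cpp(List vessels, List blood_in, List inlet,
                           List outlets, List config) {
  Blood bl;
  bl.rho = as<double>(blood_in["density"]);
  bl.mu = as<double>(blood_in["viscosity"]);
  bl.zeta = as<double>(blood_in["zeta"]);
  bl.pext = as<double>(blood_in["external_pressure"]);
  bl.pd = as<double>(blood_in["diastolic_pressure"]);
  bl.fric_coef = -2.0 * (bl.zeta + 2.0) * bl.mu * M_PI;

  std::vector<Seg> seg(3);
  for (int v = 0; v < 3; ++v) {
    List vs = vessels[v];
    Seg& s = seg[v];
    s.L = as<double>(vs["length"]);
    s.beta = as<double>(vs["beta"]);
    NumericVector ad = vs["Ad"];
    s.n = ad.size();
    s.dx = s.L / (s.n - 1);
    s.Ad.assign(ad.begin(), ad.end());
    s.kc.resize(s.n);
    for (int i = 0; i < s.n; ++i)
      s.kc[i] = std::sqrt(s.beta / (2.0 * bl.rho * s.Ad[i]));
    s.A = s.Ad;  // start at diastolic area, zero velocity
    s.U.assign(s.n, 0.0);
    s.As.resize(s.n);
    s.Us.resize(s.n);
    s.An.resize(s.n);
    s.Un.resize(s.n);
    s.F1.resize(s.n);
    s.F2.resize(s.n);
  }

  NumericVector ia = inlet["a"], ib = inlet["b"];
  const double T = as<double>(inlet["period"]);
  const double om = 2.0 * M_PI / T;
  const int nh = ia.size();  // harmonics 0..nh-1

  double R1[2], R2[2], Cc[2], Pout[2], Pc[2];
  for (int k = 0; k < 2; ++k) {
    List o = outlets[k];
    R1[k] = as<double>(o["R1"]);
    R2[k] = as<double>(o["R2"]);
    Cc[k] = as<double>(o["C"]);
    Pout[k] = as<double>(o["outflow_pressure"]);
  }

  const double cfl = as<double>(config["cfl"]);
  const int max_cycles = as<int>(config["max_cycles"]);
  const double tol = as<double>(config["periodic_tolerance"]);
  const int samples = as<int>(config["samples_per_cycle"]);
  const bool total_p = as<bool>(config["total_pressure_junction"]);
  const double u_margin = as<double>(config["u_margin"]);
  const double p_cap = as<double>(config["pressure_cap"]);

  // Mean inlet flow (b0) splits between the outlets by conductance; seed the
  // Windkessel compliance pressures and the 1D fields near their periodic
  // mean state to shorten the start-up transient.
  {
    double q0 = ib[0];
    double g1 = 1.0 / (R1[0] + R2[0]), g2 = 1.0 / (R1[1] + R2[1]);
    double q1 = q0 * g1 / (g1 + g2), q2 = q0 * g2 / (g1 + g2);
    Pc[0] = Pout[0] + q1 * R2[0];
    Pc[1] = Pout[1] + q2 * R2[1];
    if (Pc[0] < bl.pd) Pc[0] = bl.pd;
    if (Pc[1] < bl.pd) Pc[1] = bl.pd;
    double pinit = 0.5 * (Pc[0] + q1 * R1[0] + Pc[1] + q2 * R1[1]);
    if (pinit < bl.pd) pinit = bl.pd;
    double qseg[3] = {q0, q1, q2};
    for (int v = 0; v < 3; ++v) {
      Seg& s = seg[v];
      for (int i = 0; i < s.n; ++i) {
        double sa = std::sqrt(s.Ad[i]) +
                    (pinit - bl.pd - bl.pext) * s.Ad[i] / s.beta;
        s.A[i] = sa * sa;
        s.U[i] = qseg[v] / s.A[i];
      }
    }
  }

  // Global stable time step: wave speed estimated at a capped pressure head
  // plus a velocity margin for stenotic jets.
  double dt = 1e30;
  for (int v = 0; v < 3; ++v) {
    Seg& s = seg[v];
    for (int i = 0; i < s.n; ++i) {
      double sa = std::sqrt(s.Ad[i]) +
                  (p_cap - bl.pd - bl.pext) * s.Ad[i] / s.beta;
      double amax = sa * sa;
      double cmax = wave_c(s, i, amax);
      double cand = cfl * s.dx / (cmax + u_margin);
      if (cand < dt) dt = cand;
    }
  }
  int nsteps = (int)std::ceil(T / dt);
  dt = T / nsteps;

  // Site recorders: P1,Q1 (aorta inlet), P2,Q2 (iliac-1 outlet),
  // P3,Q3 (iliac-2 outlet); one row per step within a cycle.
  NumericMatrix buf(nsteps, 6), prev(nsteps, 6);
  bool failed = false, converged = false;
  double resid = NA_REAL;
  int cycles = 0;

  // Junction unknowns persist across steps as Newton initial guesses.
  double Ajp = seg[0].A[seg[0].n - 1], Aj1 = seg[1].A[0], Aj2 = seg[2].A[0];
  double pc_hist[2][3] = {{Pc[0], Pc[0], Pc[0]}, {Pc[1], Pc[1], Pc[1]}};

  for (int cyc = 0; cyc < max_cycles && !failed && !converged; ++cyc) {
    for (int k = 0; k < nsteps; ++k) {
      // record state at time k*dt within the cycle
      {
        Seg& a = seg[0];
        Seg& i1 = seg[1];
        Seg& i2 = seg[2];
        buf(k, 0) = tube_p(a.A[0], a.Ad[0], a.beta, bl);
        buf(k, 1) = a.A[0] * a.U[0];
        int e1 = i1.n - 1, e2 = i2.n - 1;
        buf(k, 2) = tube_p(i1.A[e1], i1.Ad[e1], i1.beta, bl);
        buf(k, 3) = i1.A[e1] * i1.U[e1];
        buf(k, 4) = tube_p(i2.A[e2], i2.Ad[e2], i2.beta, bl);
        buf(k, 5) = i2.A[e2] * i2.U[e2];
      }

      const double tn1 = (k + 1) * dt;  // time at end of step (within cycle)

      // --- MacCormack interior update -------------------------------------
      for (int v = 0; v < 3; ++v) {
        Seg& s = seg[v];
        fluxes(s, s.A, s.U, bl);
        double r = dt / s.dx;
        for (int i = 0; i < s.n - 1; ++i) {
          s.As[i] = s.A[i] - r * (s.F1[i + 1] - s.F1[i]);
          s.Us[i] = s.U[i] - r * (s.F2[i + 1] - s.F2[i]) +
                    dt * bl.fric_coef * s.U[i] / (bl.rho * s.A[i]);
        }
        s.As[s.n - 1] = s.A[s.n - 1];
        s.Us[s.n - 1] = s.U[s.n - 1];
        for (int i = 0; i < s.n; ++i) {
          if (!(s.As[i] > 0.0) || !std::isfinite(s.Us[i])) { failed = true; }
        }
        if (failed) break;
        fluxes(s, s.As, s.Us, bl);
        for (int i = 1; i < s.n - 1; ++i) {
          double an = 0.5 * (s.A[i] + s.As[i] - r * (s.F1[i] - s.F1[i - 1]));
          double un = 0.5 * (s.U[i] + s.Us[i] - r * (s.F2[i] - s.F2[i - 1]) +
                             dt * bl.fric_coef * s.Us[i] / (bl.rho * s.As[i]));
          s.An[i] = an;
          s.Un[i] = un;
        }
      }
      if (failed) break;

      // --- inlet: prescribed Fourier-series flow --------------------------
      {
        Seg& s = seg[0];
        double t_abs = tn1;  // series is T-periodic; cycle offset irrelevant
        double qin = 0.0;
        for (int n = 0; n < nh; ++n)
          qin += ia[n] * std::sin(n * om * t_abs) +
                 ib[n] * std::cos(n * om * t_abs);
        double c0 = wave_c(s, 0, s.A[0]);
        double lam2 = s.U[0] - c0;  // incoming-from-interior characteristic
        double w2_0 = s.U[0] - 4.0 * wave_c(s, 0, s.A[0]);
        double w2_1 = s.U[1] - 4.0 * wave_c(s, 1, s.A[1]);
        double W2 = foot_interp(w2_0, w2_1, lam2, dt, s.dx);
        double A = s.A[0];
        for (int it = 0; it < 60; ++it) {
          double c = wave_c(s, 0, A);
          double F = A * (W2 + 4.0 * c) - qin;
          double dF = W2 + 5.0 * c;
          double dA = -F / dF;
          if (A + dA <= 0.0) dA = -0.5 * A;
          A += dA;
          if (std::fabs(dA) < 1e-14 * A) break;
        }
        if (!(A > 0.0) || !std::isfinite(A)) { failed = true; }
        else {
          s.An[0] = A;
          s.Un[0] = W2 + 4.0 * wave_c(s, 0, A);
        }
      }
      if (failed) break;

      // --- bifurcation: mass + pressure-continuity Newton solve ----------
      {
        Seg& p = seg[0];
        Seg& d1 = seg[1];
        Seg& d2 = seg[2];
        int e = p.n - 1;
        double cpe = wave_c(p, e, p.A[e]);
        double lam1 = p.U[e] + cpe;
        double w1_e = p.U[e] + 4.0 * cpe;
        double w1_i = p.U[e - 1] + 4.0 * wave_c(p, e - 1, p.A[e - 1]);
        double W1p = foot_interp(w1_e, w1_i, lam1, dt, p.dx);

        double W2d[2];
        Seg* dd[2] = {&d1, &d2};
        for (int q = 0; q < 2; ++q) {
          Seg& s = *dd[q];
          double c0 = wave_c(s, 0, s.A[0]);
          double lam2 = s.U[0] - c0;
          double w2_0 = s.U[0] - 4.0 * c0;
          double w2_1 = s.U[1] - 4.0 * wave_c(s, 1, s.A[1]);
          W2d[q] = foot_interp(w2_0, w2_1, lam2, dt, s.dx);
        }

        double Ap = Ajp, A1 = Aj1, A2 = Aj2;
        bool ok = false;
        for (int it = 0; it < 60; ++it) {
          double cp = wave_c(p, e, Ap);
          double c1 = wave_c(d1, 0, A1);
          double c2 = wave_c(d2, 0, A2);
          double Up = W1p - 4.0 * cp;
          double U1 = W2d[0] + 4.0 * c1;
          double U2 = W2d[1] + 4.0 * c2;
          double Pp = tube_p(Ap, p.Ad[e], p.beta, bl);
          double P1 = tube_p(A1, d1.Ad[0], d1.beta, bl);
          double P2 = tube_p(A2, d2.Ad[0], d2.beta, bl);
          double kin = total_p ? 0.5 * bl.rho : 0.0;
          double g[3], J[3][3];
          g[0] = Ap * Up - A1 * U1 - A2 * U2;
          g[1] = Pp + kin * Up * Up - (P1 + kin * U1 * U1);
          g[2] = Pp + kin * Up * Up - (P2 + kin * U2 * U2);
          double dUp = -cp / Ap, dU1 = c1 / A1, dU2 = c2 / A2;
          J[0][0] = Up + Ap * dUp;
          J[0][1] = -(U1 + A1 * dU1);
          J[0][2] = -(U2 + A2 * dU2);
          J[1][0] = dp_dA(Ap, p.Ad[e], p.beta) + 2.0 * kin * Up * dUp;
          J[1][1] = -(dp_dA(A1, d1.Ad[0], d1.beta) + 2.0 * kin * U1 * dU1);
          J[1][2] = 0.0;
          J[2][0] = J[1][0];
          J[2][1] = 0.0;
          J[2][2] = -(dp_dA(A2, d2.Ad[0], d2.beta) + 2.0 * kin * U2 * dU2);
          double d[3];
          if (!solve3(J, g, d)) { break; }
          double damp = 1.0;
          while ((Ap + damp * d[0] <= 0.0 || A1 + damp * d[1] <= 0.0 ||
                  A2 + damp * d[2] <= 0.0) && damp > 1e-6)
            damp *= 0.5;
          Ap += damp * d[0];
          A1 += damp * d[1];
          A2 += damp * d[2];
          double rel = std::fabs(d[0]) / Ap + std::fabs(d[1]) / A1 +
                       std::fabs(d[2]) / A2;
          if (rel < 1e-13) { ok = true; break; }
        }
        if (!ok && !(Ap > 0 && A1 > 0 && A2 > 0)) failed = true;
        if (!failed) {
          Ajp = Ap; Aj1 = A1; Aj2 = A2;
          p.An[e] = Ap;
          p.Un[e] = W1p - 4.0 * wave_c(p, e, Ap);
          d1.An[0] = A1;
          d1.Un[0] = W2d[0] + 4.0 * wave_c(d1, 0, A1);
          d2.An[0] = A2;
          d2.Un[0] = W2d[1] + 4.0 * wave_c(d2, 0, A2);
        }
      }
      if (failed) break;

      // --- terminal outlets: Windkessel coupling --------------------------
      for (int q = 0; q < 2; ++q) {
        Seg& s = seg[q + 1];
        int e = s.n - 1;
        double ce = wave_c(s, e, s.A[e]);
        double lam1 = s.U[e] + ce;
        double w1_e = s.U[e] + 4.0 * ce;
        double w1_i = s.U[e - 1] + 4.0 * wave_c(s, e - 1, s.A[e - 1]);
        double W1 = foot_interp(w1_e, w1_i, lam1, dt, s.dx);
        double A = s.A[e];
        for (int it = 0; it < 60; ++it) {
          double c = wave_c(s, e, A);
          double P = tube_p(A, s.Ad[e], s.beta, bl);
          double G = A * (W1 - 4.0 * c) - (P - Pc[q]) / R1[q];
          double dG = W1 - 5.0 * c - dp_dA(A, s.Ad[e], s.beta) / R1[q];
          double dA = -G / dG;
          if (A + dA <= 0.0) dA = -0.5 * A;
          A += dA;
          if (std::fabs(dA) < 1e-14 * A) break;
        }
        if (!(A > 0.0) || !std::isfinite(A)) { failed = true; break; }
        double Unew = W1 - 4.0 * wave_c(s, e, A);
        s.An[e] = A;
        s.Un[e] = Unew;
        double Q = A * Unew;
        // implicit update of the compliance (capacitor) pressure
        Pc[q] = (Pc[q] + dt / Cc[q] * (Q + Pout[q] / R2[q])) /
                (1.0 + dt / (R2[q] * Cc[q]));
      }
      if (failed) break;

      for (int v = 0; v < 3; ++v) {
        Seg& s = seg[v];
        s.A.swap(s.An);
        s.U.swap(s.Un);
        for (int i = 0; i < s.n; ++i)
          if (!(s.A[i] > 0.0) || !std::isfinite(s.U[i])) { failed = true; }
        if (failed) break;
      }
      if (failed) break;
    }
    if (failed) break;
    cycles = cyc + 1;

    if (cyc >= 1) {
      double num = 0.0, den = 0.0;
      for (int k = 0; k < nsteps; ++k) {
        double d = buf(k, 0) - prev(k, 0);
        num += d * d;
        den += prev(k, 0) * prev(k, 0);
      }
      resid = std::sqrt(num / den);
      if (resid < tol) converged = true;
    }
    if (!converged) prev = clone(buf);

    // Aitken acceleration of the slow Windkessel volume mode: the
    // compliance pressures approach their periodic means geometrically,
    // so extrapolate the geometric series every third cycle.
    pc_hist[0][cyc % 3] = Pc[0];
    pc_hist[1][cyc % 3] = Pc[1];
    if (!converged && cyc >= 2 && cyc % 3 == 2) {
      double jump[2] = {0.0, 0.0};
      for (int q = 0; q < 2; ++q) {
        double d2 = pc_hist[q][1] - pc_hist[q][0];
        double d1 = pc_hist[q][2] - pc_hist[q][1];
        if (std::fabs(d2) > 1e-12) {
          double lam = d1 / d2;
          if (lam > 0.0 && lam < 0.95) jump[q] = lam / (1.0 - lam) * d1;
        }
      }
      Pc[0] += jump[0];
      Pc[1] += jump[1];
      // shift the 1D fields consistently so the vessels do not have to
      // refill through the outlets
      double dP = 0.5 * (jump[0] + jump[1]);
      if (dP != 0.0) {
        for (int v = 0; v < 3; ++v) {
          Seg& s = seg[v];
          for (int i = 0; i < s.n; ++i) {
            double sa = std::sqrt(s.A[i]) + dP * s.Ad[i] / s.beta;
            if (sa > 0.0) s.A[i] = sa * sa;
          }
        }
      }
    }
  }

  // Resample the final cycle onto a uniform grid (periodic linear interp).
  NumericMatrix W(samples, 6);
  NumericVector tg(samples);
  if (!failed) {
    for (int j = 0; j < samples; ++j) {
      double t = (double)j * T / samples;
      tg[j] = t;
      double pos = t / dt;
      int k0 = (int)std::floor(pos);
      double fr = pos - k0;
      int k1 = (k0 + 1) % nsteps;
      k0 = k0 % nsteps;
      for (int c = 0; c < 6; ++c)
        W(j, c) = (1.0 - fr) * buf(k0, c) + fr * buf(k1, c);
    }
  }

  return List::create(
      _["time"] = tg, _["waveforms"] = W, _["cycles"] = cycles,
      _["residual"] = resid, _["converged"] = converged, _["failed"] = failed,
      _["steps_per_cycle"] = nsteps, _["dt"] = dt);
}
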