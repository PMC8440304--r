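# 1D pulse-wave solver: domain types and elementary closures.

#' Blood and wall-model constants
#'
#' Physical constants of the blood flow model: density \eqn{\rho}, dynamic
#' viscosity \eqn{\mu}, the velocity-profile constant \eqn{\zeta} entering
#' the wall friction term, the external pressure \eqn{P_{ext}} and the
#' diastolic pressure \eqn{P_d} entering the tube law.
#'
#' @param density blood density in kg m^-3.
#' @param viscosity dynamic viscosity in Pa s.
#' @param zeta dimensionless velocity-profile constant (9 corresponds to a
#'   fairly flat profile typical of large arteries).
#' @param external_pressure external (tissue) pressure in Pa.
#' @param diastolic_pressure diastolic reference pressure in Pa.
#' @return an object of class `blood_model`.
#' @export
blood_model <- function(density = 1060, viscosity = 4e-3, zeta = 9,
                        external_pressure = 0,
                        diastolic_pressure = mmhg_to_pa(75)) {
  stopifnot(density > 0, viscosity > 0, zeta >= 0)
  structure(list(density = density, viscosity = viscosity, zeta = zeta,
                 external_pressure = external_pressure,
                 diastolic_pressure = diastolic_pressure),
            class = "blood_model")
}

#' Wall stiffness coefficient
#'
#' \eqn{\beta = (4/3) E h \sqrt{\pi}} from the Young's modulus and wall
#' thickness; units Pa m.
#'
#' @param E Young's modulus in Pa.
#' @param h wall thickness in m.
#' @return stiffness beta in Pa m.
#' @export
compute_beta <- function(E, h) {
  if (any(E <= 0) || any(h <= 0)) {
    stop("compute_beta: E and h must be positive", call. = FALSE)
  }
  (4 / 3) * E * h * sqrt(pi)
}

#' Tube-law pressure
#'
#' Algebraic pressure--area closure
#' \eqn{P = P_{ext} + P_d + \beta(\sqrt{A}-\sqrt{A_d})/A_d}.
#'
#' @param A current cross-sectional area, m^2.
#' @param Ad diastolic reference area, m^2.
#' @param beta wall stiffness, Pa m (see [compute_beta()]).
#' @param blood a [blood_model()].
#' @return pressure in Pa.
#' @export
tube_law_pressure <- function(A, Ad, beta, blood = blood_model()) {
  if (any(A <= 0) || any(Ad <= 0)) {
    stop("tube_law_pressure: areas must be positive", call. = FALSE)
  }
  blood$external_pressure + blood$diastolic_pressure +
    beta * (sqrt(A) - sqrt(Ad)) / Ad
}

#' Wall friction force per unit length
#'
#' \eqn{f = -2(\zeta+2)\mu\pi U}; always opposes the flow.
#'
#' @param U axial velocity, m s^-1.
#' @param blood a [blood_model()].
#' @return friction force per unit length, N m^-1.
#' @export
friction_force <- function(U, blood = blood_model()) {
  -2 * (blood$zeta + 2) * blood$viscosity * pi * U
}

#' Fourier-series inlet flow
#'
#' Truncated Fourier series describing the periodic inlet volumetric
#' flow rate, \eqn{Q(t) = \sum_{n=0}^{N} a_n \sin(n\omega t) +
#' b_n \cos(n\omega t)} with \eqn{\omega = 2\pi/T}.  The constant sine
#' coefficient `a[1]` (i.e. \eqn{a_0}) must be zero, leaving 11 free
#' coefficients at the default order 5.
#'
#' @param a sine coefficients \eqn{a_0..a_N} in m^3 s^-1 (first must be 0).
#' @param b cosine coefficients \eqn{b_0..b_N} in m^3 s^-1.
#' @param period cardiac period T in s.
#' @return an object of class `inlet_series`.
#' @export
inlet_series <- function(a, b, period = 1) {
  stopifnot(length(a) == length(b), period > 0)
  if (abs(a[1]) > 0) stop("inlet_series: a0 must be zero", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 period = as.numeric(period)),
            class = "inlet_series")
}

#' Evaluate the inlet flow series
#'
#' @param t time(s) in s (any real; the series is T-periodic).
#' @param series an [inlet_series()].
#' @return flow rate(s) in m^3 s^-1.
#' @export
inlet_flow_at <- function(t, series) {
  om <- 2 * pi / series$period
  n <- seq_along(series$a) - 1
  vapply(t, function(ti) {
    sum(series$a * sin(n * om * ti) + series$b * cos(n * om * ti))
  }, numeric(1))
}

#' Three-element Windkessel outlet
#'
#' Lumped RCR model of the downstream vasculature: proximal resistance R1,
#' compliance C and distal resistance R2 in front of a venous reference
#' pressure.
#'
#' @param R1,R2 resistances in Pa s m^-3.
#' @param C compliance in m^3 Pa^-1.
#' @param outflow_pressure venous reference pressure in Pa.
#' @return an object of class `windkessel_outlet`.
#' @export
windkessel_outlet <- function(R1, R2, C, outflow_pressure = 0) {
  stopifnot(R1 > 0, R2 > 0, C > 0)
  structure(list(R1 = R1, R2 = R2, C = C,
                 outflow_pressure = outflow_pressure),
            class = "windkessel_outlet")
}

#' Advance a Windkessel model through a flow history
#'
#' Integrates the RCR ordinary differential relation
#' \eqn{C\,dP_c/dt = Q - (P_c - P_{out})/R_2},
#' \eqn{P = P_c + Q R_1}, with an implicit (backward Euler) step for the
#' compliance pressure.  Under constant inflow the pressure relaxes to
#' \eqn{P_{out} + Q(R_1+R_2)} with time constant \eqn{R_2 C}.
#'
#' @param Q numeric vector: inflow history, m^3 s^-1 (one value per step).
#' @param outlet a [windkessel_outlet()].
#' @param dt time step in s.
#' @param Pc0 initial compliance pressure in Pa.
#' @return numeric vector of interface pressures (Pa), one per step.
#' @export
windkessel_pressure <- function(Q, outlet, dt, Pc0 = 0) {
  stopifnot(dt > 0)
  pc <- Pc0
  out <- numeric(length(Q))
  for (i in seq_along(Q)) {
    pc <- (pc + dt / outlet$C * (Q[i] + outlet$outflow_pressure / outlet$R2)) /
      (1 + dt / (outlet$R2 * outlet$C))
    out[i] <- pc + Q[i] * outlet$R1
  }
  out
}

#' Vessel segment
#'
#' One straight 1D vessel with spatially constant wall properties and an
#' optional normalised diastolic-area profile (used to impose stenoses).
#'
#' @param length vessel length, m.
#' @param diameter healthy diastolic reference diameter, m.
#' @param wall_thickness wall thickness h, m.
#' @param youngs_modulus Young's modulus E, Pa.
#' @param area_factor `NULL` for a healthy vessel, otherwise a function of
#'   normalised position x_n in \[0,1\] returning the normalised diastolic
#'   area (1 = healthy); must be strictly positive.
#' @param elements number of grid elements (nodes = elements + 1).
#' @return an object of class `vessel_segment` with derived `beta` and
#'   reference area.
#' @export
vessel_segment <- function(length, diameter, wall_thickness, youngs_modulus,
                           area_factor = NULL, elements = 40) {
  stopifnot(length > 0, diameter > 0, wall_thickness > 0, youngs_modulus > 0,
            elements >= 4)
  structure(list(length = length, diameter = diameter,
                 wall_thickness = wall_thickness,
                 youngs_modulus = youngs_modulus,
                 reference_area = pi * diameter^2 / 4,
                 beta = compute_beta(youngs_modulus, wall_thickness),
                 area_factor = area_factor,
                 elements = as.integer(elements)),
            class = "vessel_segment")
}

#' Diastolic area profile of a vessel at nodes
#' @param vessel a [vessel_segment()].
#' @return numeric vector of nodal diastolic areas (m^2).
#' @keywords internal
vessel_Ad_nodes <- function(vessel) {
  xn <- seq(0, 1, length.out = vessel$elements + 1)
  fac <- if (is.null(vessel$area_factor)) rep(1, length(xn)) else
    vapply(xn, vessel$area_factor, numeric(1))
  if (any(fac <= 0)) {
    stop("vessel area profile must be strictly positive", call. = FALSE)
  }
  vessel$reference_area * fac
}

#' Three-vessel bifurcation network
#'
#' The abdominal aorta bifurcating into the two common iliacs, each iliac
#' terminated by a three-element Windkessel model.
#'
#' @param aorta,iliac_1,iliac_2 [vessel_segment()] objects.
#' @param outlet_1,outlet_2 [windkessel_outlet()] objects terminating
#'   iliac 1 and iliac 2.
#' @return an object of class `arterial_network`.
#' @export
arterial_network <- function(aorta, iliac_1, iliac_2, outlet_1, outlet_2) {
  stopifnot(inherits(aorta, "vessel_segment"),
            inherits(iliac_1, "vessel_segment"),
            inherits(iliac_2, "vessel_segment"),
            inherits(outlet_1, "windkessel_outlet"),
            inherits(outlet_2, "windkessel_outlet"))
  structure(list(aorta = aorta, iliac_1 = iliac_1, iliac_2 = iliac_2,
                 outlet_1 = outlet_1, outlet_2 = outlet_2),
            class = "arterial_network")
}

#' Solver configuration
#'
#' @param cfl Courant number for the explicit time step (<= 1).
#' @param max_cycles maximum number of cardiac cycles to integrate.
#' @param periodic_tolerance relative L2 change of the inlet pressure
#'   between successive cycles below which the solution is declared
#'   periodic.
#' @param junction_rule `"total_pressure"` (continuity of
#'   \eqn{P + \rho U^2/2}) or `"static_pressure"` at the bifurcation.
#' @param samples_per_cycle number of uniform samples the final cycle is
#'   resampled to.
#' @param u_margin velocity margin (m/s) added to the wave speed when
#'   choosing the stable time step (covers stenotic jets).
#' @param pressure_cap pressure (Pa) at which the maximum wave speed is
#'   estimated for the time step.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(cfl = 0.7, max_cycles = 60,
                          periodic_tolerance = 1e-4,
                          junction_rule = c("total_pressure",
                                            "static_pressure"),
                          samples_per_cycle = 256,
                          u_margin = 8, pressure_cap = mmhg_to_pa(260)) {
  junction_rule <- match.arg(junction_rule)
  stopifnot(max_cycles >= 2, periodic_tolerance > 0, cfl > 0, cfl <= 1,
            samples_per_cycle >= 16)
  structure(list(cfl = cfl, max_cycles = as.integer(max_cycles),
                 periodic_tolerance = periodic_tolerance,
                 junction_rule = junction_rule,
                 samples_per_cycle = as.integer(samples_per_cycle),
                 u_margin = u_margin, pressure_cap = pressure_cap),
            class = "solver_config")
}

#' Solve the bifurcation network to periodic steady state
#'
#' Integrates the 1D mass/momentum equations with the tube-law closure on
#' all three vessels, coupling them at the bifurcation (mass conservation
#' plus the configured pressure-continuity rule), imposing the
#' Fourier-series flow at the aortic inlet through the incoming
#' characteristic, and three-element Windkessel models at the iliac
#' outlets.  Whole cardiac cycles are run until the inlet pressure
#' waveform is periodic.
#'
#' @param network an [arterial_network()].
#' @param blood a [blood_model()].
#' @param inlet an [inlet_series()].
#' @param config a [solver_config()].
#' @return a `waveform_set`: list with `time` (s, uniform over one period),
#'   `series` (matrix with columns P1, Q1, P2, Q2, P3, Q3 in Pa and
#'   m^3 s^-1: inlet, iliac-1 outlet, iliac-2 outlet), `period`, and
#'   convergence diagnostics `cycles` and `residual`.
#' @export
solve_network <- function(network, blood = blood_model(), inlet,
                          config = solver_config()) {
  stopifnot(inherits(network, "arterial_network"),
            inherits(inlet, "inlet_series"))
  vs <- lapply(list(network$aorta, network$iliac_1, network$iliac_2),
               function(v) list(length = v$length, beta = v$beta,
                                Ad = vessel_Ad_nodes(v)))
  outs <- lapply(list(network$outlet_1, network$outlet_2),
                 function(o) o[c("R1", "R2", "C", "outflow_pressure")])
  res <- solve_bifurcation_cpp(
    vs, unclass(blood),
    list(a = inlet$a, b = inlet$b, period = inlet$period), outs,
    list(cfl = config$cfl, max_cycles = config$max_cycles,
         periodic_tolerance = config$periodic_tolerance,
         samples_per_cycle = config$samples_per_cycle,
         total_pressure_junction =
           config$junction_rule == "total_pressure",
         u_margin = config$u_margin, pressure_cap = config$pressure_cap))
  if (isTRUE(res$failed)) {
    stop(structure(class = c("stn_simulation_failure", "error", "condition"),
                   list(message = "1D solver blow-up (negative area or NaN)",
                        call = sys.call())))
  }
  if (!isTRUE(res$converged)) {
    stop(structure(class = c("stn_nonconvergence", "error", "condition"),
                   list(message = sprintf(
                     "no periodic state within %d cycles (residual %.3g)",
                     res$cycles, res$residual), call = sys.call())))
  }
  w <- res$waveforms
  colnames(w) <- c("P1", "Q1", "P2", "Q2", "P3", "Q3")
  structure(list(time = res$time, series = w, period = inlet$period,
                 cycles = res$cycles, residual = res$residual),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf(
    "<waveform_set> %d samples/cycle, T = %.3g s, %d cycles, residual %.2g\n",
    length(x$time), x$period, x$cycles, x$residual))
  pr <- range(pa_to_mmhg(x$series[, "P1"]))
  cat(sprintf("  inlet pressure %.1f-%.1f mmHg\n", pr[1], pr[2]))
  invisible(x)
}
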