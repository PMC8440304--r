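# Fast surrogate waveform generator for the machine-learning layer.
#
# Emulates the statistical shape of simulator output -- periodic,
# band-limited (5 harmonics) pressure and flow waveforms at the three
# measurement sites, with patient-to-patient variability and
# class-dependent perturbations whose strength grows with stenosis
# severity -- without solving the 1D equations.  It is orders of
# magnitude faster than the physics model and is used to exercise the
# feature/classifier/evaluation layers; it does not reproduce the
# physics (wave reflections, nonlinear severity response), so
# classifier accuracies on it carry no physiological meaning.

# harmonic template: amplitude (fraction of `amps` base) and fixed phases
surrogate_phases <- c(0.0, -1.15, -2.30, 2.75, 1.85)

# coefficients b0, a1..a5, b1..b5 for mean level m, harmonic amplitudes
# amp (length 5) and a patient-level phase offset
surrogate_coefs <- function(m, amp, phase_shift = 0) {
  ph <- surrogate_phases + (1:5) * phase_shift
  c(b0 = m,
    setNames(-amp * sin(ph), paste0("a", 1:5)),
    setNames(amp * cos(ph), paste0("b", 1:5)))
}

sample_disease_at <- function(site) {
  r <- runif(1, 0.2, 0.8)
  list(site = site, severity = runif(1, 0.5, 0.9),
       start = runif(1, 0.1, r - 0.05), end = runif(1, r + 0.05, 0.9),
       reference_location = r)
}

#' Surrogate virtual patient database
#'
#' Generates a VPD-shaped object whose waveforms come from a parametric
#' band-limited generative model rather than the 1D solver: each series
#' is a 5-harmonic Fourier waveform with patient-level amplitude, mean
#' and phase variability; stenoses perturb the series distal to (and the
#' flow split across) the diseased vessel in proportion to severity, in a
#' way that is exactly symmetric under the iliac relabelling.  Intended
#' for fast tests and demonstrations of the ML layer.
#'
#' @param targets named patient counts per class (healthy, aorta,
#'   iliac_1, iliac_2).
#' @param noise multiplicative coefficient noise (SD, fraction).
#' @param effect overall disease effect-size multiplier (0 = classes
#'   indistinguishable).
#' @param informative measurements that carry the class-dependent signal;
#'   others receive only patient variability and noise.
#' @param samples samples per cycle; @param period cardiac period (s).
#' @return a `vpd` object (see [build_vpd()]).
#' @export
surrogate_vpd <- function(targets = c(healthy = 150, aorta = 50,
                                      iliac_1 = 50, iliac_2 = 50),
                          noise = 0.05, effect = 1,
                          informative = measurement_names(),
                          samples = 256, period = 1) {
  stopifnot(all(class_levels() %in% names(targets)))
  labels <- sample(rep(class_levels(), targets[class_levels()]))
  X <- fourier_design(samples, period, 5)
  base_amp_p <- c(16, 7, 3.5, 1.5, 0.7)      # mmHg
  base_amp_q <- c(32, 14, 6, 2.5, 1) * 1e-6  # m^3/s
  patients <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    disease <- if (lab == "healthy") list(site = "none") else
      sample_disease_at(lab)
    s <- if (lab == "healthy") 0 else disease$severity
    # patient-level haemodynamic variability
    gp <- exp(rnorm(1, 0, 0.08))
    gq <- exp(rnorm(1, 0, 0.08))
    mp <- rnorm(1, 95, 6)
    mq <- rnorm(1, 20e-6, 2.5e-6)
    frac <- min(max(rnorm(1, 0.5, 0.04), 0.3), 0.7)
    shift <- rnorm(1, 0, 0.05)
    # class-dependent multipliers per series (mean, amplitude)
    mul <- matrix(1, 2, 6,
                  dimnames = list(c("mean", "amp"), measurement_names()))
    e <- effect * s
    if (disease$site == "aorta") {
      mul["amp", c("P2", "P3")] <- 1 - 0.35 * e
      mul["mean", c("P2", "P3")] <- 1 - 0.06 * e
      mul["amp", c("Q2", "Q3")] <- 1 - 0.25 * e
      mul["amp", "P1"] <- 1 + 0.15 * e
      mul["amp", "Q1"] <- 1 - 0.10 * e
    } else if (disease$site %in% c("iliac_1", "iliac_2")) {
      dn <- if (disease$site == "iliac_1") c("P2", "Q2", "Q3") else
        c("P3", "Q3", "Q2")
      mul["amp", dn[1]] <- 1 - 0.40 * e   # distal pressure damped
      mul["mean", dn[1]] <- 1 - 0.08 * e
      mul["mean", dn[2]] <- 1 - 0.30 * e  # flow through stenosis drops
      mul["amp", dn[2]] <- 1 - 0.30 * e
      mul["mean", dn[3]] <- 1 + 0.15 * e  # diverted to the other iliac
      mul["amp", "P1"] <- 1 + 0.08 * e
    }
    mul[, setdiff(measurement_names(), informative)] <- 1
    means <- c(Q1 = mq, Q2 = frac * mq, Q3 = (1 - frac) * mq,
               P1 = mmhg_to_pa(mp), P2 = mmhg_to_pa(0.985 * mp),
               P3 = mmhg_to_pa(0.985 * mp))
    amps <- list(Q1 = gq * base_amp_q, Q2 = gq * frac * base_amp_q,
                 Q3 = gq * (1 - frac) * base_amp_q,
                 P1 = mmhg_to_pa(gp * base_amp_p),
                 P2 = mmhg_to_pa(gp * 0.92 * base_amp_p),
                 P3 = mmhg_to_pa(gp * 0.92 * base_amp_p))
    ser <- matrix(0, samples, 6,
                  dimnames = list(NULL, measurement_names()))
    for (mm in measurement_names()) {
      cf <- surrogate_coefs(means[[mm]] * mul["mean", mm],
                            amps[[mm]] * mul["amp", mm],
                            phase_shift = shift)
      cf <- cf * (1 + rnorm(length(cf), 0, noise))
      ser[, mm] <- X %*% cf
    }
    w <- structure(list(time = seq(0, period, length.out = samples + 1)[
      -(samples + 1)], series = ser, period = period,
      cycles = NA_integer_, residual = NA_real_),
      class = "waveform_set")
    patients[[i]] <- list(id = i, params = c(gp = gp, gq = gq),
                          disease = disease, label = lab, waveforms = w,
                          filter_status = "accepted")
  }
  structure(list(patients = patients,
                 stats = list(attempts = length(labels),
                              accepted = length(labels), rejected = 0L,
                              failed = 0L, acceptance_rate = 1,
                              rejection_reasons = c(
                                max_inlet_pressure = 0L,
                                min_inlet_pressure = 0L,
                                pulse_pressure = 0L)),
                 targets = targets[class_levels()]),
            class = "vpd")
}
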