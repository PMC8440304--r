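# Virtual patient population: parameter distributions, disease geometry,
# physiological filters and VPD assembly.

#' Reference means of the 25 network parameters
#'
#' Means of the arterial network parameter distributions: geometry and
#' Young's moduli for the aorta and the (shared) iliac description, the
#' two Windkessel triplets, and the 11 inlet Fourier coefficients.  All
#' parameters are sampled independently and normally with standard
#' deviation 20% of the mean.
#'
#' @param inlet an [inlet_series()] supplying the mean Fourier
#'   coefficients (defaults to [default_inlet_series()]).
#' @return named list with `means` (named numeric, 25 entries), `period`,
#'   and the parameter names for each block.
#' @export
reference_parameters <- function(inlet = default_inlet_series()) {
  fs <- c(b0 = inlet$b[1],
          setNames(inlet$a[2:6], paste0("a", 1:5)),
          setNames(inlet$b[2:6], paste0("b", 1:5)))
  means <- c(
    aorta_length = 8.6e-2, aorta_wall_thickness = 1.03e-3,
    aorta_diameter = 1.72e-2, aorta_E = 500e3,
    iliac_length = 8.5e-2, iliac_wall_thickness = 0.72e-3,
    iliac_diameter = 1.2e-2, iliac_E = 700e3,
    wk1_R1 = 6.81e7, wk1_R2 = 3.10e9, wk1_C = 3.67e-10,
    wk2_R1 = 6.81e7, wk2_R2 = 3.10e9, wk2_C = 3.67e-10,
    fs)
  list(means = means, period = inlet$period,
       positive = names(means)[1:14])
}

#' Default inlet flow waveform
#'
#' A half-sine systolic ejection (peak 60 mL/s over a systole of 0.3 T,
#' zero in diastole) projected onto the 5th-order Fourier series.  This is
#' the mean inlet waveform the population is sampled around; it is
#' qualitatively representative of abdominal aortic inflow.
#'
#' @param peak peak systolic flow, m^3 s^-1.
#' @param systole_fraction fraction of the cycle in systole.
#' @param period cardiac period, s.
#' @return an [inlet_series()] of order 5.
#' @export
default_inlet_series <- function(peak = 60e-6, systole_fraction = 0.3,
                                 period = 1) {
  ts <- seq(0, period, length.out = 513)[-513]
  q <- ifelse(ts < systole_fraction * period,
              peak * sin(pi * ts / (systole_fraction * period)), 0)
  cf <- fit_fourier(q, period, order = 5)
  inlet_series(a = c(0, cf[paste0("a", 1:5)]),
               b = cf[c("b0", paste0("b", 1:5))], period = period)
}

#' Sample healthy network parameters
#'
#' Draws the 25 free parameters independently from
#' Normal(mean, 0.2 * mean) around the reference values.  Non-positive
#' draws of geometric, mechanical or Windkessel parameters are redrawn
#' (truncation, no point masses); Fourier coefficients with zero mean stay
#' exactly zero.
#'
#' @param n number of parameter vectors.
#' @param ref output of [reference_parameters()].
#' @param sd_fraction standard deviation as a fraction of the mean.
#' @param r1_sd_printed if `TRUE`, use the printed table value 1.36e6 for
#'   the R1 standard deviation instead of the 20%-of-mean rule (kept as a
#'   reproduction flag; the text rule is the default).
#' @return an n x 25 matrix (one row per patient) of parameters.
#' @export
sample_healthy <- function(n = 1, ref = reference_parameters(),
                           sd_fraction = 0.2, r1_sd_printed = FALSE) {
  mu <- ref$means
  sdv <- sd_fraction * abs(mu)
  if (r1_sd_printed) sdv[c("wk1_R1", "wk2_R1")] <- 1.36e6
  p <- length(mu)
  out <- matrix(rnorm(n * p, rep(mu, each = n), rep(sdv, each = n)),
                nrow = n, dimnames = list(NULL, names(mu)))
  out[, sdv == 0] <- matrix(rep(mu[sdv == 0], each = n), nrow = n)
  pos <- ref$positive
  bad <- which(out[, pos, drop = FALSE] <= 0, arr.ind = TRUE)
  while (nrow(bad) > 0) {
    for (k in seq_len(nrow(bad))) {
      j <- pos[bad[k, 2]]
      out[bad[k, 1], j] <- rnorm(1, mu[j], sdv[j])
    }
    bad <- which(out[, pos, drop = FALSE] <= 0, arr.ind = TRUE)
  }
  out
}

#' Sample a disease specification
#'
#' With probability `healthy_fraction` the patient is healthy; otherwise
#' the stenosed vessel is chosen uniformly among the three vessels and the
#' geometry parameters are sampled sequentially from uniform distributions
#' within the constraints
#' \deqn{0.2 \le r \le 0.8,\; 0.1 \le b \le r-0.05,\;
#'       r+0.05 \le e \le 0.9,\; 0.5 \le S \le 0.9,}
#' where r is a reference location enforcing a minimum stenosis extent of
#' 10% of the vessel length.
#'
#' @param healthy_fraction probability of no disease.
#' @return a list with `site` (one of `"none"`, `"aorta"`, `"iliac_1"`,
#'   `"iliac_2"`) and, if diseased, `severity`, `start`, `end`,
#'   `reference_location`.
#' @export
sample_disease <- function(healthy_fraction = 0.5) {
  stopifnot(healthy_fraction >= 0, healthy_fraction <= 1)
  if (runif(1) < healthy_fraction) {
    return(list(site = "none"))
  }
  site <- sample(c("aorta", "iliac_1", "iliac_2"), 1)
  r <- runif(1, 0.2, 0.8)
  b <- runif(1, 0.1, r - 0.05)
  e <- runif(1, r + 0.05, 0.9)
  S <- runif(1, 0.5, 0.9)
  list(site = site, severity = S, start = b, end = e,
       reference_location = r)
}

#' Normalised stenosis area map
#'
#' Cosine narrowing of the normalised diastolic area:
#' \deqn{A_n(x_n) = (1 - S/2) + (S/2)\cos(2\pi (x_n-b)/(e-b))}
#' for \eqn{b \le x_n \le e} and 1 otherwise.  The map is continuous at b
#' and e and attains its minimum 1 - S at the midpoint (b+e)/2.
#'
#' @param x_n normalised position(s) in \[0,1\].
#' @param spec disease specification from [sample_disease()].
#' @return normalised area factor(s).
#' @export
stenosis_area_factor <- function(x_n, spec) {
  if (identical(spec$site, "none")) return(rep(1, length(x_n)))
  S <- spec$severity; b <- spec$start; e <- spec$end
  ifelse(x_n >= b & x_n <= e,
         (1 - S / 2) + (S / 2) * cos(2 * (x_n - b) * pi / (e - b)),
         1)
}

#' Build the arterial network of a (possibly diseased) patient
#'
#' Constructs the three-vessel network from a sampled parameter vector and
#' applies the stenosis area map to the designated vessel.  Only the
#' diastolic area profile of the diseased vessel is modified; wall
#' thickness and Young's modulus keep their sampled values.
#'
#' @param params one row of [sample_healthy()] (named numeric, 25 entries).
#' @param disease a specification from [sample_disease()].
#' @param elements grid elements per vessel.
#' @return an [arterial_network()].
#' @export
apply_disease <- function(params, disease = list(site = "none"),
                          elements = 40) {
  params <- drop(params)
  fac <- function(site) {
    if (identical(disease$site, site)) {
      function(x) stenosis_area_factor(x, disease)
    } else NULL
  }
  mk <- function(prefix, site) {
    vessel_segment(length = params[[paste0(prefix, "_length")]],
                   diameter = params[[paste0(prefix, "_diameter")]],
                   wall_thickness = params[[paste0(prefix,
                                                   "_wall_thickness")]],
                   youngs_modulus = params[[paste0(prefix, "_E")]],
                   area_factor = fac(site), elements = elements)
  }
  arterial_network(
    aorta = mk("aorta", "aorta"),
    iliac_1 = mk("iliac", "iliac_1"),
    iliac_2 = mk("iliac", "iliac_2"),
    outlet_1 = windkessel_outlet(params[["wk1_R1"]], params[["wk1_R2"]],
                                 params[["wk1_C"]]),
    outlet_2 = windkessel_outlet(params[["wk2_R1"]], params[["wk2_R2"]],
                                 params[["wk2_C"]]))
}

#' Inlet series of a sampled patient
#' @param params named parameter vector (row of [sample_healthy()]).
#' @param period cardiac period, s.
#' @return an [inlet_series()].
#' @export
patient_inlet_series <- function(params, period = 1) {
  params <- drop(params)
  inlet_series(a = c(0, unname(params[paste0("a", 1:5)])),
               b = unname(params[c("b0", paste0("b", 1:5))]),
               period = period)
}

#' Hard physiological filter on inlet pressure
#'
#' Accepts a simulated patient only if the inlet pressure satisfies all of
#' max(P) < 225 mmHg, min(P) > 25 mmHg, and pulse pressure
#' max(P) - min(P) < 120 mmHg (strict inequalities).
#'
#' @param w a `waveform_set` from [solve_network()] (or any list with a
#'   `series` matrix containing a `P1` column in Pa).
#' @return list with `accept` (logical) and `reasons` (character vector of
#'   violated conditions, empty when accepted).
#' @export
hard_filter <- function(w) {
  p <- pa_to_mmhg(w$series[, "P1"])
  reasons <- character(0)
  if (!(max(p) < 225)) reasons <- c(reasons, "max_inlet_pressure")
  if (!(min(p) > 25)) reasons <- c(reasons, "min_inlet_pressure")
  if (!(max(p) - min(p) < 120)) reasons <- c(reasons, "pulse_pressure")
  list(accept = length(reasons) == 0, reasons = reasons)
}

#' Class label implied by a disease specification
#' @param disease a [sample_disease()] specification.
#' @return factor level among `healthy`, `aorta`, `iliac_1`, `iliac_2`.
#' @export
disease_label <- function(disease) {
  if (identical(disease$site, "none")) "healthy" else disease$site
}

#' Class levels of the screening problem
#' @return character vector C1..C4: healthy, aorta, iliac_1, iliac_2.
#' @export
class_levels <- function() c("healthy", "aorta", "iliac_1", "iliac_2")

#' Build a virtual patient database
#'
#' Repeatedly samples patients (healthy parameters, then disease), runs
#' the 1D simulation, applies the hard physiological filters, and keeps
#' accepted patients until each class reaches its target count.  Patients
#' of classes already at target are not simulated.  Fully reproducible
#' given the RNG state (`set.seed()` before calling).
#'
#' @param targets named integer vector of accepted-patient targets for the
#'   classes `healthy`, `aorta`, `iliac_1`, `iliac_2`.  The published
#'   study sizes are `c(healthy = 3564, aorta = 1188, iliac_1 = 1188,
#'   iliac_2 = 1188)`, derived from the events-per-variable rule (see
#'   [epv_requirements()]); scaled-down cohorts keep the same 3:1:1:1 mix.
#' @param blood a [blood_model()].
#' @param config a [solver_config()].
#' @param ref parameter distribution means, [reference_parameters()].
#' @param elements grid elements per vessel.
#' @param acceptance_floor abort if the running acceptance rate falls
#'   below this after 200 attempts.
#' @param r1_sd_printed see [sample_healthy()].
#' @param progress print a progress line every 200 attempts.
#' @return an object of class `vpd`: list with `patients` (each holding
#'   `id`, `params`, `disease`, `label`, `waveforms`, `filter_status`),
#'   `stats` (attempt/acceptance bookkeeping) and `targets`.
#' @export
build_vpd <- function(targets = c(healthy = 30, aorta = 10, iliac_1 = 10,
                                  iliac_2 = 10),
                      blood = blood_model(), config = solver_config(),
                      ref = reference_parameters(), elements = 40,
                      acceptance_floor = 0.02, r1_sd_printed = FALSE,
                      progress = FALSE) {
  stopifnot(all(class_levels() %in% names(targets)), all(targets >= 0))
  targets <- targets[class_levels()]
  counts <- setNames(rep(0L, 4), class_levels())
  patients <- vector("list", sum(targets))
  n_acc <- 0L
  attempts <- 0L
  rejected <- 0L
  failed <- 0L
  reasons <- c(max_inlet_pressure = 0L, min_inlet_pressure = 0L,
               pulse_pressure = 0L)
  healthy_fraction <- targets[["healthy"]] / sum(targets)
  while (any(counts < targets)) {
    attempts <- attempts + 1L
    params <- sample_healthy(1, ref, r1_sd_printed = r1_sd_printed)[1, ]
    disease <- sample_disease(healthy_fraction)
    label <- disease_label(disease)
    if (counts[[label]] >= targets[[label]]) next
    net <- apply_disease(params, disease, elements = elements)
    inlet <- patient_inlet_series(params, period = ref$period)
    w <- tryCatch(solve_network(net, blood, inlet, config),
                  stn_simulation_failure = function(e) e,
                  stn_nonconvergence = function(e) e)
    if (inherits(w, "condition")) {
      failed <- failed + 1L
      next
    }
    flt <- hard_filter(w)
    if (!flt$accept) {
      rejected <- rejected + 1L
      reasons[flt$reasons] <- reasons[flt$reasons] + 1L
      next
    }
    n_acc <- n_acc + 1L
    counts[[label]] <- counts[[label]] + 1L
    patients[[n_acc]] <- list(id = n_acc, params = params,
                              disease = disease, label = label,
                              waveforms = w, filter_status = "accepted")
    if (progress && attempts %% 200 == 0) {
      message(sprintf("VPD: %d accepted / %d attempts", n_acc, attempts))
    }
    if (attempts >= 200 && n_acc / attempts < acceptance_floor) {
      stop(sprintf(
        "build_vpd: acceptance rate %.3f below floor %.3f after %d attempts",
        n_acc / attempts, acceptance_floor, attempts), call. = FALSE)
    }
  }
  structure(list(patients = patients[seq_len(n_acc)],
                 stats = list(attempts = attempts, accepted = n_acc,
                              rejected = rejected, failed = failed,
                              rejection_reasons = reasons,
                              acceptance_rate = n_acc / attempts),
                 targets = targets),
            class = "vpd")
}

#' @export
print.vpd <- function(x, ...) {
  tab <- table(factor(vpd_labels(x), levels = class_levels()))
  cat(sprintf("<vpd> %d patients (%s); acceptance rate %.2f\n",
              length(x$patients),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              x$stats$acceptance_rate))
  invisible(x)
}

#' Labels, severities and manifest of a VPD
#' @param vpd a `vpd` object.
#' @return `vpd_labels`: character vector of class labels;
#'   `vpd_severities`: numeric vector (0 for healthy patients);
#'   `vpd_manifest`: data frame of id, parameters, disease fields, label
#'   and filter status.
#' @export
vpd_labels <- function(vpd) {
  vapply(vpd$patients, `[[`, character(1), "label")
}

#' @rdname vpd_labels
#' @export
vpd_severities <- function(vpd) {
  vapply(vpd$patients, function(p) {
    if (identical(p$disease$site, "none")) 0 else p$disease$severity
  }, numeric(1))
}

#' @rdname vpd_labels
#' @export
vpd_manifest <- function(vpd) {
  pm <- do.call(rbind, lapply(vpd$patients, function(p) p$params))
  dd <- do.call(rbind, lapply(vpd$patients, function(p) {
    d <- p$disease
    data.frame(site = d$site,
               severity = if (is.null(d$severity)) NA_real_ else d$severity,
               start = if (is.null(d$start)) NA_real_ else d$start,
               end = if (is.null(d$end)) NA_real_ else d$end,
               reference_location = if (is.null(d$reference_location))
                 NA_real_ else d$reference_location)
  }))
  cbind(data.frame(id = vapply(vpd$patients, `[[`, numeric(1), "id"),
                   label = vpd_labels(vpd),
                   filter_status = vapply(vpd$patients, `[[`,
                                          character(1), "filter_status")),
        as.data.frame(pm), dd)
}
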