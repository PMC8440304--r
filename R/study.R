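# Study orchestration: configuration, reproducible seeds, VPD file
# round-trip, and named experiment drivers.

#' Default study configuration
#'
#' A complete, serialisable configuration covering the solver, the
#' population targets, the classifier settings and the experiment sizes.
#' A master seed fans out to per-stage seeds by a fixed additive rule
#' (stage offsets: vpd = 1, experiments = 2), so partial reruns are
#' reproducible.
#'
#' @return nested list of settings.
#' @export
default_study_config <- function() {
  list(
    master_seed = 20260101L,
    population = list(
      targets = list(healthy = 30L, aorta = 10L, iliac_1 = 10L,
                     iliac_2 = 10L),
      elements = 40L, acceptance_floor = 0.02, r1_sd_printed = FALSE),
    solver = list(cfl = 0.7, max_cycles = 60L, periodic_tolerance = 1e-4,
                  junction_rule = "total_pressure",
                  samples_per_cycle = 256L),
    blood = list(density = 1060, viscosity = 4e-3, zeta = 9,
                 external_pressure = 0,
                 diastolic_pressure_mmhg = 75),
    inlet = list(peak_flow = 60e-6, systole_fraction = 0.3, period = 1),
    classifier = list(method = "lr", r = 1, decision_boundary = 0.5),
    evaluation = list(folds = 5L,
                      roc_boundaries = 101L,
                      learning_sizes = c(60L, 120L, 240L)))
}

#' Load a study configuration from YAML
#'
#' Reads a YAML file and merges it over [default_study_config()]; unknown
#' top-level fields raise a validation error naming the field.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return configuration list.
#' @export
study_config <- function(path = NULL) {
  cfg <- default_study_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad) > 0) {
    stop(sprintf("study_config: unknown field(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      badf <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
      if (length(badf) > 0) {
        stop(sprintf("study_config: unknown field(s) in '%s': %s", nm,
                     paste(badf, collapse = ", ")), call. = FALSE)
      }
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

# Polynomial rolling hash of the serialised configuration; stamped into
# outputs so results can be matched to the exact settings that produced
# them.
config_hash <- function(config) {
  bytes <- serialize(config, NULL, version = 2)
  h <- 5381
  for (b in as.integer(bytes)) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

blood_from_config <- function(cfg) {
  b <- cfg$blood
  blood_model(density = b$density, viscosity = b$viscosity, zeta = b$zeta,
              external_pressure = b$external_pressure,
              diastolic_pressure = mmhg_to_pa(b$diastolic_pressure_mmhg))
}

solver_from_config <- function(cfg) {
  s <- cfg$solver
  solver_config(cfl = s$cfl, max_cycles = s$max_cycles,
                periodic_tolerance = s$periodic_tolerance,
                junction_rule = s$junction_rule,
                samples_per_cycle = s$samples_per_cycle)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Generate a VPD and write its file set
#'
#' Runs [build_vpd()] under the configuration's population/solver
#' settings (seeded from `master_seed + 1`) and writes four files to
#' `out_dir`: `manifest.csv` (patient id, 25 parameters, disease fields,
#' label, filter status), `waveforms.csv` (long-format six-series store,
#' full double precision so the round-trip through [read_vpd_files()] is
#' bit-exact), `waveforms.json` (units and grid sidecar) and
#' `cohort.json` (seed, config hash, acceptance statistics).
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if missing).
#' @return the `vpd`, invisibly.
#' @export
generate_vpd_files <- function(config = default_study_config(),
                               out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$master_seed) + 1L
  set.seed(seed)
  inlet <- default_inlet_series(peak = config$inlet$peak_flow,
                                systole_fraction =
                                  config$inlet$systole_fraction,
                                period = config$inlet$period)
  vpd <- build_vpd(
    targets = unlist(config$population$targets),
    blood = blood_from_config(config),
    config = solver_from_config(config),
    ref = reference_parameters(inlet),
    elements = config$population$elements,
    acceptance_floor = config$population$acceptance_floor,
    r1_sd_printed = config$population$r1_sd_printed)

  man <- vpd_manifest(vpd)
  num <- vapply(man, is.numeric, logical(1))
  man[num] <- lapply(man[num], fmt_full)
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)

  rows <- lapply(vpd$patients, function(p) {
    s <- p$waveforms$series
    data.frame(id = p$id, sample = seq_len(nrow(s)) - 1L,
               time = fmt_full(p$waveforms$time),
               P1 = fmt_full(s[, "P1"]), Q1 = fmt_full(s[, "Q1"]),
               P2 = fmt_full(s[, "P2"]), Q2 = fmt_full(s[, "Q2"]),
               P3 = fmt_full(s[, "P3"]), Q3 = fmt_full(s[, "Q3"]))
  })
  write.csv(do.call(rbind, rows), file.path(out_dir, "waveforms.csv"),
            row.names = FALSE)

  jsonlite::write_json(
    list(units = list(pressure = "Pa", flow = "m3/s", time = "s"),
         sites = list(P1 = "aortic inlet", Q1 = "aortic inlet",
                      P2 = "iliac-1 outlet", Q2 = "iliac-1 outlet",
                      P3 = "iliac-2 outlet", Q3 = "iliac-2 outlet"),
         samples_per_cycle = config$solver$samples_per_cycle,
         period = config$inlet$period),
    file.path(out_dir, "waveforms.json"), auto_unbox = TRUE)

  jsonlite::write_json(
    list(seed = seed, master_seed = config$master_seed,
         config_hash = config_hash(config),
         accepted = vpd$stats$accepted, attempts = vpd$stats$attempts,
         acceptance_rate = vpd$stats$acceptance_rate,
         rejection_reasons = as.list(vpd$stats$rejection_reasons),
         class_counts = as.list(table(vpd_labels(vpd)))),
    file.path(out_dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  invisible(vpd)
}

#' Read a VPD back from its file set
#' @param dir directory written by [generate_vpd_files()].
#' @return a `vpd` object (waveforms bit-exact w.r.t. the written one).
#' @export
read_vpd_files <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"),
                  stringsAsFactors = FALSE)
  wv <- read.csv(file.path(dir, "waveforms.csv"),
                 stringsAsFactors = FALSE)
  side <- jsonlite::read_json(file.path(dir, "waveforms.json"),
                              simplifyVector = TRUE)
  cohort <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                simplifyVector = TRUE)
  par_cols <- setdiff(names(man),
                      c("id", "label", "filter_status", "site",
                        "severity", "start", "end",
                        "reference_location"))
  patients <- lapply(seq_len(nrow(man)), function(i) {
    sub <- wv[wv$id == man$id[i], ]
    sub <- sub[order(sub$sample), ]
    ser <- as.matrix(sub[, c("P1", "Q1", "P2", "Q2", "P3", "Q3")])
    rownames(ser) <- NULL
    dis <- if (man$site[i] == "none") list(site = "none") else
      list(site = man$site[i], severity = as.numeric(man$severity[i]),
           start = as.numeric(man$start[i]),
           end = as.numeric(man$end[i]),
           reference_location = as.numeric(man$reference_location[i]))
    list(id = man$id[i],
         params = setNames(as.numeric(man[i, par_cols]), par_cols),
         disease = dis, label = man$label[i],
         waveforms = structure(list(time = as.numeric(sub$time),
                                    series = ser,
                                    period = side$period,
                                    cycles = NA_integer_,
                                    residual = NA_real_),
                               class = "waveform_set"),
         filter_status = man$filter_status[i])
  })
  structure(list(patients = patients,
                 stats = list(attempts = cohort$attempts,
                              accepted = cohort$accepted,
                              acceptance_rate = cohort$acceptance_rate),
                 targets = unlist(cohort$class_counts)),
            class = "vpd")
}

#' Run a named experiment
#'
#' Dispatches the experiments of the study on an existing VPD (seeded
#' from `master_seed + 2` for reproducibility):
#' `learning_curve`, `enbc_search`, `ivbc_search`, `multiclass`,
#' `roc`, `severity`.
#'
#' @param name experiment name (see Details).
#' @param vpd a `vpd` object.
#' @param config a [study_config()].
#' @param out_dir optional directory: results are written as CSV with a
#'   JSON manifest carrying the seed and config hash.
#' @return the experiment's tidy result (data frame, or list for `roc`).
#' @export
run_experiment <- function(name, vpd, config = default_study_config(),
                           out_dir = NULL) {
  known <- c("learning_curve", "enbc_search", "ivbc_search", "multiclass",
             "roc", "severity")
  if (!name %in% known) {
    stop(sprintf("run_experiment: unknown experiment '%s' (known: %s)",
                 name, paste(known, collapse = ", ")), call. = FALSE)
  }
  if (is.null(vpd) || !inherits(vpd, "vpd")) {
    stop("run_experiment: a VPD is required (build_vpd/read_vpd_files)",
         call. = FALSE)
  }
  set.seed(as.integer(config$master_seed) + 2L)
  cl <- config$classifier
  ev <- config$evaluation
  feats <- features_from_vpd(vpd)
  y <- vpd_labels(vpd)
  res <- switch(name,
    learning_curve = learning_curve(vpd, vessel = "aorta",
                                    sizes = unlist(ev$learning_sizes),
                                    method = cl$method, folds = ev$folds,
                                    r = cl$r),
    enbc_search = combination_search(vpd, methods = cl$method,
                                     rule = list(type = "enbc"),
                                     r = cl$r, B = cl$decision_boundary,
                                     folds = ev$folds),
    ivbc_search = do.call(rbind, lapply(
      c("aorta", "iliac_1", "iliac_2"), function(v) {
        cbind(vessel = v,
              combination_search(vpd, methods = cl$method,
                                 rule = list(type = "ivbc", vessel = v),
                                 r = cl$r, B = cl$decision_boundary,
                                 folds = ev$folds))
      })),
    multiclass = {
      tr <- split_two_thirds(y)
      std <- fit_standardiser(feats[tr, , drop = FALSE])
      Xtr <- predict(std, feats[tr, , drop = FALSE])
      Xte <- predict(std, feats[-tr, , drop = FALSE])
      do.call(rbind, lapply(c("ova", "ovo", "cpc"), function(st) {
        ens <- train_multiclass(Xtr, y[tr], strategy = st,
                                method = cl$method, r = cl$r,
                                B = cl$decision_boundary)
        cbind(strategy = st,
              multiclass_report(predict(ens, Xte), y[-tr]))
      }))
    },
    roc = {
      tr <- split_two_thirds(y)
      std <- fit_standardiser(feats[tr, , drop = FALSE])
      ens <- train_multiclass(predict(std, feats[tr, , drop = FALSE]),
                              y[tr], strategy = "cpc",
                              method = cl$method, r = cl$r)
      roc_and_auc(ens, predict(std, feats[-tr, , drop = FALSE]), y[-tr],
                  boundaries = seq(0, 1,
                                   length.out = ev$roc_boundaries))
    },
    severity = {
      tau <- label_for(list(type = "enbc"), y)
      tr <- split_two_thirds(tau)
      std <- fit_standardiser(feats[tr, , drop = FALSE])
      model <- fit_binary(cl$method,
                          predict(std, feats[tr, , drop = FALSE]),
                          tau[tr],
                          w = class_weight(sum(tau[tr] == 1),
                                           sum(tau[tr] == 0), cl$r))
      sev <- vpd_severities(vpd)
      severity_analysis(model,
                        predict(std, feats[-tr, , drop = FALSE]),
                        tau[-tr], sev[-tr], B = cl$decision_boundary)
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- if (name == "roc") res$points else res
    write.csv(tab, file.path(out_dir, paste0(name, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(experiment = name, seed = config$master_seed + 2L,
           config_hash = config_hash(config)),
      file.path(out_dir, paste0(name, "_manifest.json")),
      auto_unbox = TRUE)
  }
  res
}
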