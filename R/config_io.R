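# Run configuration, report assembly, and serialization. A run config
# (YAML or JSON) names the particle spec, field sources, force
# calibrations, stimulation protocols, and measurement files; running it
# executes the particle -> magnetics -> kinetics -> protocol chain and
# emits a structured report.

REPORT_SCHEMA_VERSION <- "1.0"

#' Read and validate a run configuration
#'
#' @param path Path to a YAML (or JSON) configuration file. Relative
#'   measurement paths are resolved against the config file's directory.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  req <- function(field) {
    if (is.null(cfg[[field]]))
      stop("config schema violation: missing field '", field, "'",
           call. = FALSE)
  }
  for (f in c("particle", "force_calibration", "protocols")) req(f)
  cfg$moment_mode <- cfg$moment_mode %||% "calibrated"
  if (!cfg$moment_mode %in% c("calibrated", "model"))
    stop("config schema violation: moment_mode must be ",
         "'calibrated' or 'model'", call. = FALSE)
  if (!is.null(cfg$measurements$nerve_iron_csv)) {
    p <- cfg$measurements$nerve_iron_csv
    if (!file.exists(p) && !is.null(cfg$.dir)) p <- file.path(cfg$.dir, p)
    if (!file.exists(p))
      stop("config I/O error: measurement file not found: ",
           cfg$measurements$nerve_iron_csv, call. = FALSE)
    cfg$measurements$nerve_iron_csv <- p
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_particle_spec <- function(cfg) {
  p <- cfg$particle
  particle_spec(
    core_diameter_nm = p$core_diameter_nm %||% 56.60,
    crystallite_diameter_nm = p$crystallite_diameter_nm %||% 5.80,
    shell_thickness_nm = p$shell_thickness_nm %||% 5.79,
    packing_fraction = p$packing_fraction %||% 0.62,
    magnetite_density_g_cm3 = p$magnetite_density_g_cm3 %||% 5.18,
    fe_mass_fraction = p$fe_mass_fraction %||% FE_MASS_FRACTION_MAGNETITE,
    saturation_magnetization_emu_g =
      p$saturation_magnetization_emu_g %||% 30)
}

config_moment <- function(cfg, spec, which) {
  cal <- cfg$force_calibration[[which]]
  if (cfg$moment_mode == "calibrated") {
    if (is.null(cal))
      stop("config schema violation: calibrated mode needs ",
           "force_calibration$", which, call. = FALSE)
    particle_moment(spec, mode = "calibrated",
                    calibration = list(force_pN = cal$force_pN,
                                       gradient_T_m = cal$gradient_T_m))
  } else {
    b <- cfg$local_field_T[[which]]
    if (is.null(b))
      stop("config schema violation: model mode needs local_field_T$",
           which, call. = FALSE)
    particle_moment(spec, mode = "model", field_T = b)
  }
}

#' Execute the full dosimetry chain described by a run configuration
#'
#' Runs particle -> magnetics -> clearance kinetics -> protocol dose
#' accounting and assembles a structured report: per-particle iron mass
#' and forces, per-cell particle count and force, the per-tissue force
#' time-course with its clearance fit, schedule summaries, and the
#' cumulative mechanical impulse over the multi-day protocol.
#'
#' @param config A `run_config` from [read_run_config()], or a path to one.
#' @return A list of class `dose_report`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  spec <- config_particle_spec(config)
  m_fe <- iron_mass_per_particle(spec)             # pg

  report <- list(schema_version = REPORT_SCHEMA_VERSION,
                 moment_mode = config$moment_mode,
                 particle = list(iron_mass_per_particle_pg = m_fe))

  # --- in vitro: electromagnet, per-cell dose -------------------------
  if (!is.null(config$field_sources$electromagnet)) {
    em <- electromagnet_source(do.call(
      rbind, config$field_sources$electromagnet$calibration_points))
    current <- config$electromagnet_current_A %||%
      max(em$currents_A)
    grad <- electromagnet_gradient(current, em)
    moment <- config_moment(config, spec, "invitro")
    f_particle <- force_on_particle(moment, grad)
    cell_pg <- config$cell_iron_uptake_pg
    invitro <- list(current_A = current, gradient_T_m = grad,
                    moment_A_m2 = moment,
                    per_particle_force_pN = f_particle)
    if (!is.null(cell_pg)) {
      n_cell <- particle_count_from_iron(cell_pg, m_fe, units = "pg")
      invitro$cell_iron_pg <- cell_pg
      invitro$particles_per_cell <- n_cell
      invitro$force_per_cell_pN <- ensemble_force(n_cell, f_particle)
    }
    report$invitro <- invitro
  }

  # --- in vivo: ring array, per-nerve dose over time ------------------
  if (!is.null(config$measurements$nerve_iron_csv)) {
    tab <- read_iron_measurements(config$measurements$nerve_iron_csv)
    tab <- tab[tab$compartment == "tissue", ]
    if (nrow(tab) == 0)
      stop("per-row error: no tissue rows in nerve iron table",
           call. = FALSE)
    if (any(tab$iron_mass <= 0)) {
      bad <- tab[tab$iron_mass <= 0, ]
      stop("per-row error: non-positive iron mass for subject ",
           bad$subject_id[1], " at day ", bad$time_days[1], call. = FALSE)
    }
    masses_ug <- ifelse(tab$iron_mass_units == "pg",
                        tab$iron_mass * 1e-6, tab$iron_mass)
    series <- iron_timeseries(tab$time_days, masses_ug, label = "nerve")
    moment <- config_moment(config, spec, "invivo")
    cal <- config$force_calibration$invivo
    grad <- if (!is.null(cal)) cal$gradient_T_m else NA_real_
    f_particle <- force_on_particle(moment, grad)
    tc <- force_timecourse(series, m_fe, f_particle)
    fit <- fit_clearance(series)
    report$invivo <- list(gradient_T_m = grad, moment_A_m2 = moment,
                          per_particle_force_pN = f_particle,
                          timecourse = tc,
                          clearance = list(
                            initial_mass_ug = fit$initial_mass_ug,
                            decay_rate_per_day = fit$decay_rate_per_day,
                            half_life_days = fit$half_life_days,
                            r_squared = fit$r_squared))
    report$.clearance_fit <- fit
  }

  # --- protocols and cumulative impulse -------------------------------
  report$protocols <- lapply(config$protocols, function(p) {
    proto <- if (identical(p$mode, "cyclic"))
      stim_protocol_cyclic(p$on_min, p$off_min, p$total_span_h)
    else stim_protocol_daily(p$session_start_hours, p$session_min, p$n_days)
    sched <- build_schedule(proto)
    c(schedule_summary(sched), list(.schedule = sched))
  })

  if (!is.null(report$invivo) && !is.null(report$protocols$invivo)) {
    fit <- report$.clearance_fit
    f_particle <- report$invivo$per_particle_force_pN
    force_fn <- function(t_s) {
      mass_ug <- predict(fit, t_s / 86400)
      ensemble_force(particle_count_from_iron(mass_ug, m_fe, units = "ug"),
                     f_particle)
    }
    report$invivo$cumulative_impulse_pN_s <-
      cumulative_impulse(report$protocols$invivo$.schedule, force_fn)
  }
  report$.clearance_fit <- NULL
  class(report) <- "dose_report"
  report
}

#' @export
print.dose_report <- function(x, ...) {
  cat("Magnetomechanical dose report (schema ", x$schema_version, ")\n",
      sep = "")
  cat(sprintf("  iron mass per particle : %.3g pg\n",
              x$particle$iron_mass_per_particle_pg))
  if (!is.null(x$invitro)) {
    iv <- x$invitro
    cat(sprintf("  in vitro  : %.3g T/m, F_particle = %s\n",
                iv$gradient_T_m, format_force(iv$per_particle_force_pN)))
    if (!is.null(iv$particles_per_cell))
      cat(sprintf("              n_cell = %.3g, F_cell = %s\n",
                  iv$particles_per_cell,
                  format_force(iv$force_per_cell_pN)))
  }
  if (!is.null(x$invivo)) {
    vv <- x$invivo
    cat(sprintf("  in vivo   : %.3g T/m, F_particle = %s\n",
                vv$gradient_T_m, format_force(vv$per_particle_force_pN)))
    for (i in seq_len(nrow(vv$timecourse)))
      cat(sprintf("              day %2g: n = %.3g, F = %s\n",
                  vv$timecourse$time_days[i],
                  vv$timecourse$particle_count[i],
                  vv$timecourse$ensemble_force_label[i]))
    cat(sprintf("              clearance half-life = %.3g days\n",
                vv$clearance$half_life_days))
    if (!is.null(vv$cumulative_impulse_pN_s))
      cat(sprintf("              cumulative impulse = %.3g pN s\n",
                  vv$cumulative_impulse_pN_s))
  }
  invisible(x)
}

#' Write a dose report to disk
#'
#' Writes `<prefix>.json` (the full report, schema-versioned, with
#' deterministic field ordering) and, when a force time-course is
#' present, `<prefix>_timecourse.csv` with units embedded in the column
#' names.
#'
#' @param report A `dose_report` from [run_config()].
#' @param prefix Output path prefix (directories are created).
#' @return Named vector of the written paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  out <- unclass(report)
  out$protocols <- lapply(out$protocols, function(p) {
    p$.schedule <- NULL
    p
  })
  json_path <- paste0(prefix, ".json")
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  paths <- c(json = json_path)
  if (!is.null(report$invivo$timecourse)) {
    csv_path <- paste0(prefix, "_timecourse.csv")
    utils::write.csv(report$invivo$timecourse, csv_path,
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, timecourse = csv_path)
  }
  invisible(paths)
}

#' Path of the bundled reference configuration
#'
#' A complete run configuration using the reference superparticle
#' geometry, the published electromagnet calibration and ring-array
#' geometry, both stimulation protocols, and the bundled nerve iron time
#' series.
#'
#' @return Path to the YAML file inside the installed package.
#' @export
reference_config <- function() {
  system.file("extdata", "reference_dosimetry.yaml",
              package = "magnetodose", mustWork = TRUE)
}
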