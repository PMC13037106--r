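# Clearance kinetics: fit an exponential decay to tissue iron time
# series, convert iron masses to particle counts and forces over time,
# and integrate force over a stimulation schedule into a cumulative
# mechanical impulse.

#' Iron time series
#'
#' Measured elemental-iron mass in a tissue compartment over time.
#'
#' @param times_days Measurement times (days), strictly increasing, >= 0.
#' @param masses_ug Iron masses (ug), same length as `times_days`.
#' @param label Optional label for the series.
#' @return An object of class `iron_timeseries`.
#' @export
iron_timeseries <- function(times_days, masses_ug, label = "") {
  if (length(times_days) != length(masses_ug))
    stop("times and masses must have equal length", call. = FALSE)
  if (any(!is.finite(times_days)) || any(times_days < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  if (any(diff(times_days) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(masses_ug)) || any(masses_ug < 0))
    stop("masses must be finite and >= 0", call. = FALSE)
  structure(list(times_days = as.numeric(times_days),
                 masses_ug = as.numeric(masses_ug),
                 label = label),
            class = "iron_timeseries")
}

#' Fit first-order clearance to an iron time series
#'
#' Ordinary least squares on (t, log m): the decay rate is minus the
#' slope, the initial mass is exp(intercept), and the half-life is
#' ln(2)/rate (infinite when the rate is <= 0). Log-linear OLS is the
#' default estimator: simple, reproducible, and adequate for the short
#' series this assay produces.
#'
#' @param series An [iron_timeseries()] with >= 2 strictly positive masses.
#' @return An object of class `clearance_fit` with fields
#'   `initial_mass_ug`, `decay_rate_per_day`, `half_life_days`,
#'   `r_squared`.
#' @examples
#' s <- iron_timeseries(c(1, 3, 7, 14), c(3.57, 2.13, 1.40, 0.34))
#' fit_clearance(s)   # rate ~0.175/day, half-life ~4 days
#' @export
fit_clearance <- function(series) {
  stopifnot(inherits(series, "iron_timeseries"))
  if (length(series$masses_ug) < 2)
    stop("clearance fit needs at least 2 time points", call. = FALSE)
  bad <- which(series$masses_ug <= 0)
  if (length(bad))
    stop("clearance fit requires positive masses; non-positive mass at ",
         "time ", series$times_days[bad[1]], " days", call. = FALSE)
  fit <- stats::lm(log(m) ~ t,
                   data = data.frame(t = series$times_days,
                                     m = series$masses_ug))
  slope <- unname(stats::coef(fit)[2])
  rate <- -slope
  # snap numerically-zero slopes (constant series) to an exact zero
  if (abs(rate) < 1e-12) rate <- 0
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    initial_mass_ug = exp(unname(stats::coef(fit)[1])),
    decay_rate_per_day = rate,
    half_life_days = if (rate > 0) log(2) / rate else Inf,
    r_squared = r2,
    label = series$label),
    class = "clearance_fit")
}

#' @export
print.clearance_fit <- function(x, ...) {
  cat("First-order clearance fit",
      if (nzchar(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  cat(sprintf("  initial mass : %.3g ug\n", x$initial_mass_ug))
  cat(sprintf("  decay rate   : %.4g /day\n", x$decay_rate_per_day))
  cat(sprintf("  half-life    : %.3g days\n", x$half_life_days))
  cat(sprintf("  R-squared    : %.4f\n", x$r_squared))
  invisible(x)
}

#' Predict tissue iron mass from a clearance fit
#'
#' @param object A `clearance_fit`.
#' @param times_days Times (days) at which to evaluate the fitted decay.
#' @param ... Unused.
#' @return Predicted masses (ug).
#' @export
predict.clearance_fit <- function(object, times_days, ...) {
  object$initial_mass_ug * exp(-object$decay_rate_per_day * times_days)
}

#' Force time-course from an iron time series
#'
#' At each measured time point, the particle count is the iron mass over
#' the per-particle iron mass, and the ensemble force is that count times
#' the per-particle force.
#'
#' @param series An [iron_timeseries()] (masses in ug).
#' @param per_particle_iron_pg Iron mass per particle (pg), > 0.
#' @param per_particle_force_pN Force per particle (pN), > 0.
#' @return A data.frame (one row per time point) with columns
#'   `time_days`, `iron_mass_ug`, `particle_count`, `per_particle_force_pN`,
#'   `ensemble_force_pN`, `ensemble_force_uN`, `ensemble_force_label`.
#' @examples
#' s <- iron_timeseries(c(1, 3, 7, 14), c(3.57, 2.13, 1.40, 0.34))
#' force_timecourse(s, 2.21e-4, 1.27e-4)
#' @export
force_timecourse <- function(series, per_particle_iron_pg,
                             per_particle_force_pN) {
  stopifnot(inherits(series, "iron_timeseries"))
  if (per_particle_iron_pg <= 0 || per_particle_force_pN <= 0)
    stop("per-particle iron mass and force must be > 0", call. = FALSE)
  count <- particle_count_from_iron(series$masses_ug, per_particle_iron_pg,
                                    units = "ug")
  f_pN <- ensemble_force(count, per_particle_force_pN)
  data.frame(time_days = series$times_days,
             iron_mass_ug = series$masses_ug,
             particle_count = count,
             per_particle_force_pN = per_particle_force_pN,
             ensemble_force_pN = f_pN,
             ensemble_force_uN = f_pN * 1e-6,
             ensemble_force_label = format_force(f_pN))
}

#' Cumulative mechanical impulse over a stimulation schedule
#'
#' Integrates a non-negative force function of time over the ON intervals
#' of a schedule, by adaptive quadrature per interval. An empty schedule
#' gives 0.
#'
#' @param intervals Schedule as returned by [build_schedule()]: a
#'   data.frame with `start_min` and `end_min` columns (minutes).
#' @param force_fn Function mapping time in seconds to force in pN; must
#'   be >= 0 on the schedule span.
#' @return Cumulative impulse in pN s.
#' @examples
#' sched <- data.frame(start_min = 0, end_min = 15)
#' cumulative_impulse(sched, function(t) rep(1, length(t)))   # 900 pN s
#' @export
cumulative_impulse <- function(intervals, force_fn) {
  if (is.null(intervals) || nrow(intervals) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(intervals))) {
    a <- intervals$start_min[i] * 60
    b <- intervals$end_min[i] * 60
    probe <- force_fn(seq(a, b, length.out = 11))
    if (any(probe < 0))
      stop("force function is negative inside an ON interval", call. = FALSE)
    total <- total + stats::integrate(force_fn, a, b,
                                      rel.tol = 1e-10)$value
  }
  total
}
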