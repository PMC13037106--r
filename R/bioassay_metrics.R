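# Outcome formulas for the nerve-regeneration bioassays: sciatic
# functional index, CCK-8 viability, orientation index, G-ratio,
# calcium-trace metrics, motor nerve conduction velocity, F/G-actin.

#' Sciatic functional index (Bain formula)
#'
#' SFI = -38.3 (EPL-NPL)/NPL + 109.5 (ETS-NTS)/NTS + 13.3 (EIT-NIT)/NIT
#'       - 8.8,
#' from bilateral footprint measurements: print length (PL), toe spread
#' (TS), and intermediary toe spread (ITS) on the experimental (E) and
#' contralateral normal (N) limbs. 0 is roughly normal function; -100 is
#' complete dysfunction.
#'
#' @param epl,npl Experimental / normal print length (mm), > 0.
#' @param ets,nts Experimental / normal toe spread (mm), > 0.
#' @param eit,nit Experimental / normal intermediary toe spread (mm), > 0.
#' @return SFI score (dimensionless). Vectorized.
#' @examples
#' sfi(2, 2, 1.5, 1.5, 1, 1)    # identical limbs: -8.8
#' @export
sfi <- function(epl, npl, ets, nts, eit, nit) {
  vals <- cbind(epl, npl, ets, nts, eit, nit)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all six footprint lengths must be finite and > 0", call. = FALSE)
  -38.3 * (epl - npl) / npl +
    109.5 * (ets - nts) / nts +
    13.3 * (eit - nit) / nit - 8.8
}

#' Cell viability from CCK-8 absorbances
#'
#' Viability (%) = 100 (A_sample - A_drug) / (A_control - A_blank), where
#' A_drug is the particle-only absorbance control that removes
#' nanomaterial interference and A_blank the reagent-only background.
#' Values above 100 or below 0 are reported as-is (with a warning when
#' negative).
#'
#' @param a_sample,a_control,a_blank,a_drug Absorbances (dimensionless);
#'   `a_control` must exceed `a_blank`.
#' @return Viability in percent.
#' @examples
#' viability_percent(0.95, 1.05, 0.05, 0.10)    # 85
#' @export
viability_percent <- function(a_sample, a_control, a_blank, a_drug) {
  if (any(a_control <= a_blank))
    stop("A_control must exceed A_blank", call. = FALSE)
  out <- 100 * (a_sample - a_drug) / (a_control - a_blank)
  if (any(out < 0))
    warning("negative viability: sample absorbance below the drug control",
            call. = FALSE)
  out
}

#' Orientation index of a cell relative to the field vector
#'
#' Oi = cos(theta) of the acute angle between the cell's long axis and the
#' field direction: 1 means fully aligned, 0 perpendicular. Angles outside
#' [0, pi/2] are folded to the acute equivalent first.
#'
#' @param theta Angle(s) in radians.
#' @return Oi in [0, 1]. Vectorized.
#' @examples
#' orientation_index(c(0, pi / 4, pi / 2))   # 1, 0.707, 0
#' @export
orientation_index <- function(theta) {
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  folded <- fold_acute(theta)
  cos(folded)
}

# Fold any angle to the acute angle between two undirected axes: reduce
# mod pi, then reflect (pi/2, pi] onto [0, pi/2).
fold_acute <- function(theta) {
  t <- abs(theta) %% pi
  ifelse(t > pi / 2, pi - t, t)
}

#' G-ratio of a myelinated fiber
#'
#' Axon diameter over total fiber (axon plus myelin) diameter; lower
#' values indicate thicker myelin.
#'
#' @param axon_um Axon diameter (um), > 0.
#' @param fiber_um Fiber diameter (um), >= axon diameter.
#' @return G-ratio in (0, 1]. Vectorized.
#' @export
g_ratio <- function(axon_um, fiber_um) {
  if (any(!is.finite(axon_um)) || any(axon_um <= 0))
    stop("axon diameter must be finite and > 0", call. = FALSE)
  if (any(fiber_um < axon_um))
    stop("validation error: axon diameter exceeds fiber diameter",
         call. = FALSE)
  axon_um / fiber_um
}

#' Calcium trace container
#'
#' @param times_s Time stamps (s), increasing.
#' @param intensities Fluorescence intensities (arbitrary units, >= 0).
#' @param stimulation_onset_s Stimulus onset (s); the baseline window is
#'   (0, onset). Default 50, the usual pre-stimulus imaging window.
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(times_s, intensities, stimulation_onset_s = 50) {
  if (length(times_s) != length(intensities))
    stop("times and intensities must have equal length", call. = FALSE)
  if (any(diff(times_s) <= 0))
    stop("times must be increasing", call. = FALSE)
  if (any(intensities < 0))
    stop("intensities must be >= 0", call. = FALSE)
  if (stimulation_onset_s <= min(times_s) ||
      stimulation_onset_s >= max(times_s))
    stop("stimulation onset must lie inside the time range", call. = FALSE)
  if (!any(times_s < stimulation_onset_s))
    stop("baseline window is empty", call. = FALSE)
  structure(list(times_s = times_s, intensities = intensities,
                 stimulation_onset_s = stimulation_onset_s),
            class = "calcium_trace")
}

#' Calcium-trace response metrics
#'
#' F0 is the mean intensity over the pre-onset baseline window.
#' dF/F0 = 100 (F_stim - F0)/F0 with F_stim the mean post-onset intensity
#' (reported percent-like, matching the scale these assays print);
#' Fmax/F0 is the post-onset maximum over F0, a plain ratio.
#'
#' @param trace A [calcium_trace()].
#' @return List with `dF_over_F0_percent` and `Fmax_over_F0`.
#' @examples
#' tr <- calcium_trace(1:100, c(rep(100, 50), rep(185, 50)), 50)
#' calcium_metrics(tr)    # dF/F0 = 85, Fmax/F0 = 1.85
#' @export
calcium_metrics <- function(trace) {
  stopifnot(inherits(trace, "calcium_trace"))
  pre <- trace$times_s < trace$stimulation_onset_s
  f0 <- mean(trace$intensities[pre])
  if (f0 <= 0) stop("baseline fluorescence F0 must be > 0", call. = FALSE)
  post <- trace$intensities[!pre]
  f_stim <- mean(post)
  list(dF_over_F0_percent = 100 * (f_stim - f0) / f0,
       Fmax_over_F0 = max(post) / f0)
}

#' Motor nerve conduction velocity
#'
#' Inter-electrode distance divided by the difference between proximal and
#' distal response latencies.
#'
#' @param distance_mm Distance between stimulation sites (mm), > 0.
#' @param latency_proximal_ms,latency_distal_ms Response latencies (ms);
#'   proximal must exceed distal.
#' @return Conduction velocity in m/s.
#' @examples
#' mncv(30, 2, 1)   # 30 m/s
#' @export
mncv <- function(distance_mm, latency_proximal_ms, latency_distal_ms) {
  if (any(distance_mm <= 0))
    stop("distance must be > 0", call. = FALSE)
  if (any(latency_distal_ms < 0) ||
      any(latency_proximal_ms <= latency_distal_ms))
    stop("proximal latency must exceed distal latency (both >= 0)",
         call. = FALSE)
  distance_mm / (latency_proximal_ms - latency_distal_ms)   # mm/ms = m/s
}

#' F-actin to G-actin ratio
#'
#' @param f_actin Filamentous actin amount (mass or band intensity), >= 0.
#' @param g_actin Globular actin amount in the same units, > 0.
#' @return The ratio. Vectorized.
#' @export
fg_ratio <- function(f_actin, g_actin) {
  if (any(g_actin <= 0)) stop("G-actin must be > 0", call. = FALSE)
  f_actin / g_actin
}

#' Median and interquartile range of a metric vector
#'
#' Aggregation used for the non-normally distributed morphology metrics
#' (cell length, Oi, G-ratio, calcium intensities), which are summarized
#' as median [Q1-Q3].
#'
#' @param x Numeric vector.
#' @return List with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}
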