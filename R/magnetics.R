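# Magnetization and force models, plus the two gradient-field generators
# used at the bench: a current-calibrated electromagnet and an annular
# (ring) permanent-magnet array evaluated on axis.

MU0 <- 4e-7 * pi          # vacuum permeability, T m/A
KB  <- 1.380649e-23       # Boltzmann constant, J/K

#' Superparamagnetic magnetization model
#'
#' Parameters of the classical Langevin description of a superparamagnetic
#' ensemble: the composite saturation magnetization sets the plateau, and
#' the moment of one crystallite (bulk crystallite magnetization times
#' crystallite volume) sets how fast the plateau is approached with field.
#'
#' @param saturation_magnetization_emu_g Saturation magnetization, emu per
#'   gram of magnetite (= A m^2/kg). Default 30 (SQUID, 300 K).
#' @param crystallite_diameter_nm Magnetite crystallite diameter (nm).
#' @param bulk_crystallite_magnetization_A_m Volume magnetization of bulk
#'   magnetite used in the Langevin argument (A/m). Default 4.8e5.
#' @param temperature_K Absolute temperature (K). Default 300 (the SQUID
#'   measurement condition); use 310 for physiological scenarios.
#' @return An object of class `magnetization_model`.
#' @export
magnetization_model <- function(saturation_magnetization_emu_g = 30,
                                crystallite_diameter_nm = 5.80,
                                bulk_crystallite_magnetization_A_m = 4.8e5,
                                temperature_K = 300) {
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("invalid magnetization model: temperature_K must be > 0",
         call. = FALSE)
  if (!is.finite(saturation_magnetization_emu_g) ||
      saturation_magnetization_emu_g < 0)
    stop("invalid magnetization model: saturation magnetization must be >= 0",
         call. = FALSE)
  if (!is.finite(crystallite_diameter_nm) || crystallite_diameter_nm <= 0)
    stop("invalid magnetization model: crystallite diameter must be > 0",
         call. = FALSE)
  if (!is.finite(bulk_crystallite_magnetization_A_m) ||
      bulk_crystallite_magnetization_A_m <= 0)
    stop("invalid magnetization model: bulk magnetization must be > 0",
         call. = FALSE)
  structure(
    list(saturation_magnetization_emu_g = saturation_magnetization_emu_g,
         crystallite_diameter_nm = crystallite_diameter_nm,
         bulk_crystallite_magnetization_A_m = bulk_crystallite_magnetization_A_m,
         temperature_K = temperature_K),
    class = "magnetization_model")
}

# L(x) = coth(x) - 1/x, evaluated stably: the small-|x| series
# x/3 - x^3/45 avoids catastrophic cancellation near zero.
langevin_function <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- x[small] / 3 - x[small]^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' Field-dependent magnetization (Langevin)
#'
#' M(B) = Ms * L(x) with L(x) = coth(x) - 1/x and
#' x = m_crystallite * B / (kB * T), where m_crystallite is the moment of
#' one crystallite. L(0) = 0 is handled analytically.
#'
#' @param field_T Magnetic flux density (T), >= 0. Vectorized.
#' @param model A [magnetization_model()].
#' @return Magnetization in emu/g (A m^2/kg), in [0, Ms).
#' @examples
#' langevin_magnetization(0, magnetization_model())    # 0
#' langevin_magnetization(1, magnetization_model())    # approaching 30
#' @export
langevin_magnetization <- function(field_T, model = magnetization_model()) {
  stopifnot(inherits(model, "magnetization_model"))
  if (any(!is.finite(field_T)) || any(field_T < 0))
    stop("field_T must be finite and >= 0", call. = FALSE)
  v_cryst <- (pi / 6) * (model$crystallite_diameter_nm * 1e-9)^3
  m_cryst <- model$bulk_crystallite_magnetization_A_m * v_cryst  # A m^2
  x <- m_cryst * field_T / (KB * model$temperature_K)
  model$saturation_magnetization_emu_g * langevin_function(x)
}

#' Magnetic moment of one superparticle
#'
#' Two modes. `"model"`: moment = Langevin magnetization at the local
#' field (A m^2/kg) times the magnetite mass per particle; requires the
#' local flux density B, which gradient-only field characterizations do
#' not provide. `"calibrated"`: moment = per-particle force / gradient,
#' taking a measured force-gradient pair as ground truth; this is the
#' default because per-particle forces are what bench calibrations report.
#'
#' @param spec A [particle_spec()].
#' @param mode `"calibrated"` or `"model"`.
#' @param field_T Local flux density (T); required in `"model"` mode.
#' @param model A [magnetization_model()]; used in `"model"` mode.
#' @param calibration List with `force_pN` and `gradient_T_m`, a measured
#'   per-particle force at a known gradient. Defaults to the in vivo
#'   reference pair (1.27e-4 pN at 16.0 T/m).
#' @return Magnetic moment in A m^2.
#' @examples
#' particle_moment(particle_spec())   # calibrated: ~7.94e-18 A m^2
#' @export
particle_moment <- function(spec,
                            mode = c("calibrated", "model"),
                            field_T = NULL,
                            model = magnetization_model(
                              saturation_magnetization_emu_g =
                                spec$saturation_magnetization_emu_g,
                              crystallite_diameter_nm =
                                spec$crystallite_diameter_nm),
                            calibration = list(force_pN = 1.27e-4,
                                               gradient_T_m = 16.0)) {
  stopifnot(inherits(spec, "particle_spec"))
  mode <- match.arg(mode)
  if (mode == "calibrated") {
    if (!is.finite(calibration$force_pN) || calibration$force_pN < 0 ||
        !is.finite(calibration$gradient_T_m) || calibration$gradient_T_m <= 0)
      stop("calibration needs force_pN >= 0 and gradient_T_m > 0",
           call. = FALSE)
    return(calibration$force_pN * 1e-12 / calibration$gradient_T_m)
  }
  if (is.null(field_T))
    stop("model mode requires the local flux density field_T", call. = FALSE)
  m_per_kg <- langevin_magnetization(field_T, model)   # A m^2/kg
  m_per_kg * magnetite_mass_per_particle(spec)
}

#' Force on one magnetized particle in a field gradient
#'
#' Scalar co-linear reduction of F = (m . grad) B: the moment is taken
#' aligned with the field, and only the axial gradient enters, so
#' F = m * dB/dz.
#'
#' @param moment_A_m2 Magnetic moment (A m^2).
#' @param gradient_T_m Flux density gradient (T/m), >= 0.
#' @return Force in pN. Vectorized over either argument.
#' @examples
#' force_on_particle(7.94e-18, 16.0)   # ~1.27e-4 pN
#' @export
force_on_particle <- function(moment_A_m2, gradient_T_m) {
  if (any(!is.finite(gradient_T_m)) || any(gradient_T_m < 0))
    stop("gradient_T_m must be finite and >= 0", call. = FALSE)
  moment_A_m2 * gradient_T_m * 1e12   # N -> pN
}

#' Ensemble force of many identical particles
#'
#' @param count Particle count (dimensionless, >= 0).
#' @param per_particle_force_pN Force per particle (pN, >= 0).
#' @return Total force in pN.
#' @seealso [format_force()] for the pN/uN display convention.
#' @export
ensemble_force <- function(count, per_particle_force_pN) {
  if (any(count < 0) || any(per_particle_force_pN < 0))
    stop("count and per-particle force must be >= 0", call. = FALSE)
  count * per_particle_force_pN
}

#' Format a force in pN, switching to uN above 1e6 pN
#'
#' @param force_pN Force in pN.
#' @param digits Significant digits (default 3, the usual reporting style).
#' @return Character vector like `"0.148 pN"` or `"2.06 uN"`.
#' @export
format_force <- function(force_pN, digits = 3) {
  vapply(force_pN, function(f) {
    if (f >= 1e6) sprintf("%s uN", signif(f * 1e-6, digits))
    else sprintf("%s pN", signif(f, digits))
  }, character(1))
}

#' Electromagnet calibration field source
#'
#' A gradient-field generator characterized by measured (current, gradient)
#' calibration points.
#'
#' @param calibration_points Two-column matrix or data.frame
#'   (current_A, gradient_T_per_m) with strictly increasing currents;
#'   at least two points.
#' @return An object of class `field_source`, kind `electromagnet`.
#' @examples
#' em <- electromagnet_source(cbind(c(1, 2, 3), c(1.25, 2.25, 3.25)))
#' electromagnet_gradient(3, em)   # 3.25 T/m
#' @export
electromagnet_source <- function(calibration_points) {
  pts <- as.matrix(calibration_points)
  if (ncol(pts) != 2 || nrow(pts) < 2)
    stop("calibration error: need >= 2 (current, gradient) points",
         call. = FALSE)
  if (any(diff(pts[, 1]) <= 0))
    stop("calibration error: currents must be strictly increasing",
         call. = FALSE)
  structure(list(kind = "electromagnet",
                 currents_A = pts[, 1],
                 gradients_T_m = pts[, 2]),
            class = "field_source")
}

#' Gradient of an electromagnet at a given current
#'
#' Linear least-squares fit through the calibration points, evaluated at
#' the requested current. Returns exactly 0 at zero current (no current,
#' no field). Extrapolation beyond the calibrated current range warns.
#'
#' @param current_A Drive current (A), >= 0. Vectorized.
#' @param source An `electromagnet` [electromagnet_source()].
#' @return Gradient in T/m.
#' @export
electromagnet_gradient <- function(current_A, source) {
  stopifnot(inherits(source, "field_source"))
  if (source$kind != "electromagnet")
    stop("source is not an electromagnet calibration", call. = FALSE)
  if (any(!is.finite(current_A)) || any(current_A < 0))
    stop("current_A must be finite and >= 0", call. = FALSE)
  fit <- stats::lm(g ~ i, data = data.frame(i = source$currents_A,
                                            g = source$gradients_T_m))
  rng <- range(source$currents_A)
  beyond <- current_A > 0 & (current_A < rng[1] | current_A > rng[2])
  if (any(beyond))
    warning("current outside the calibrated range [",
            rng[1], ", ", rng[2], "] A; extrapolating", call. = FALSE)
  out <- unname(stats::predict(fit, newdata = data.frame(i = current_A)))
  out[current_A == 0] <- 0
  out
}

#' Annular (ring) magnet array field source
#'
#' A stack of axially magnetized ring magnets, each described by inner and
#' outer radius, thickness, axial center position, polarity, and remanence.
#'
#' @param inner_radius_mm,outer_radius_mm,thickness_mm Per-magnet geometry
#'   (mm); recycled to the longest length. outer > inner > 0.
#' @param center_z_mm Axial position of each magnet's center (mm).
#' @param polarity +1 or -1 per magnet.
#' @param remanence_T Remanent flux density (T). Default 1.40 (typical
#'   N48-grade NdFeB) — an assumption, not a measured value.
#' @return An object of class `field_source`, kind `ring_array`.
#' @export
ring_array_source <- function(inner_radius_mm, outer_radius_mm, thickness_mm,
                              center_z_mm, polarity = 1, remanence_T = 1.40) {
  n <- max(length(inner_radius_mm), length(outer_radius_mm),
           length(thickness_mm), length(center_z_mm), length(polarity))
  g <- data.frame(inner_radius_mm = rep_len(inner_radius_mm, n),
                  outer_radius_mm = rep_len(outer_radius_mm, n),
                  thickness_mm = rep_len(thickness_mm, n),
                  center_z_mm = rep_len(center_z_mm, n),
                  polarity = rep_len(polarity, n))
  if (any(g$inner_radius_mm <= 0) ||
      any(g$outer_radius_mm <= g$inner_radius_mm))
    stop("ring geometry error: need outer_radius > inner_radius > 0",
         call. = FALSE)
  if (any(g$thickness_mm <= 0))
    stop("ring geometry error: thickness must be > 0", call. = FALSE)
  if (!all(g$polarity %in% c(-1, 1)))
    stop("ring geometry error: polarity must be +1 or -1", call. = FALSE)
  if (!is.finite(remanence_T) || remanence_T < 0)
    stop("ring geometry error: remanence must be >= 0", call. = FALSE)
  structure(list(kind = "ring_array", magnets = g,
                 remanence_T = remanence_T),
            class = "field_source")
}

# On-axis field of a uniformly axially magnetized solid cylinder of radius
# R (m) spanning [z1, z2] (m), remanence Br (T):
#   B(z) = (Br/2) [ (z - z1)/sqrt((z-z1)^2 + R^2)
#                 - (z - z2)/sqrt((z-z2)^2 + R^2) ]
# and its analytic z-derivative. Finite at the faces.
cylinder_axial <- function(z, z1, z2, R, Br) {
  u1 <- z - z1; u2 <- z - z2
  s1 <- sqrt(u1^2 + R^2); s2 <- sqrt(u2^2 + R^2)
  B <- (Br / 2) * (u1 / s1 - u2 / s2)
  dB <- (Br / 2) * (R^2 / s1^3 - R^2 / s2^3)
  list(B = B, dBdz = dB)
}

#' On-axis field profile of a ring-magnet array
#'
#' The on-axis field of one axially magnetized annulus is the closed-form
#' difference between two solid cylinders (outer radius minus inner
#' radius); magnets superpose with their polarity signs. The gradient is
#' the analytic derivative of the same expression.
#'
#' @param z_mm Axial evaluation positions (mm).
#' @param source A `ring_array` [ring_array_source()].
#' @return A data.frame with columns `z_mm`, `B_T`, `dBdz_T_per_m`.
#' @export
ring_axial_profile <- function(z_mm, source) {
  stopifnot(inherits(source, "field_source"))
  if (source$kind != "ring_array")
    stop("source is not a ring array", call. = FALSE)
  z <- z_mm * 1e-3
  B <- numeric(length(z)); dB <- numeric(length(z))
  for (i in seq_len(nrow(source$magnets))) {
    m <- source$magnets[i, ]
    z1 <- (m$center_z_mm - m$thickness_mm / 2) * 1e-3
    z2 <- (m$center_z_mm + m$thickness_mm / 2) * 1e-3
    Br <- m$polarity * source$remanence_T
    outer <- cylinder_axial(z, z1, z2, m$outer_radius_mm * 1e-3, Br)
    inner <- cylinder_axial(z, z1, z2, m$inner_radius_mm * 1e-3, Br)
    B <- B + (outer$B - inner$B)
    dB <- dB + (outer$dBdz - inner$dBdz)
  }
  data.frame(z_mm = z_mm, B_T = B, dBdz_T_per_m = dB)
}

#' Write a ring-array axial profile as CSV
#'
#' @param profile Output of [ring_axial_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_axial_profile <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
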