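# Superparticle geometry/composition -> per-particle iron mass and
# particle counts. Internal unit system is SI (kg, m, s, T, A m^2);
# boundary helpers accept/emit the bench units (nm, pg, ug, pN, uN, T/m).

# Fe3O4 stoichiometry: 3 Fe (55.845 g/mol) per formula unit (231.533 g/mol).
FE_MASS_FRACTION_MAGNETITE <- 3 * 55.845 / 231.533

#' Superparticle specification
#'
#' Describes one core-shell superparticle: a sphere of packed magnetite
#' crystallites (the magnetic, iron-bearing core) surrounded by an organic
#' shell treated as magnetically and elementally inert. Only the core
#' contributes iron and magnetic moment.
#'
#' @param core_diameter_nm Diameter of the magnetite core (nm).
#' @param crystallite_diameter_nm Diameter of the individual magnetite
#'   crystallites that assemble into the core (nm). Enters only the
#'   Langevin argument via the crystallite moment.
#' @param shell_thickness_nm Organic shell thickness (nm); metadata only.
#' @param packing_fraction Volume fraction of the core occupied by
#'   magnetite crystallites, in (0, 1]. Default 0.62, a calibrated
#'   constant chosen so the default geometry reproduces the reference
#'   per-particle iron mass of 2.21e-4 pg; override from config when an
#'   independent iron assay is available.
#' @param magnetite_density_g_cm3 Bulk magnetite density (g/cm^3).
#' @param fe_mass_fraction Mass fraction of elemental iron in magnetite;
#'   defaults to the Fe3O4 stoichiometric value 3*55.845/231.533 = 0.7236.
#' @param saturation_magnetization_emu_g Composite saturation
#'   magnetization, emu per gram of magnetite (1 emu/g = 1 A m^2/kg).
#'
#' @return An object of class `particle_spec`.
#' @examples
#' spec <- particle_spec()
#' iron_mass_per_particle(spec)  # ~2.21e-4 pg
#' @export
particle_spec <- function(core_diameter_nm = 56.60,
                          crystallite_diameter_nm = 5.80,
                          shell_thickness_nm = 5.79,
                          packing_fraction = 0.62,
                          magnetite_density_g_cm3 = 5.18,
                          fe_mass_fraction = FE_MASS_FRACTION_MAGNETITE,
                          saturation_magnetization_emu_g = 30) {
  stopifnot(is.numeric(core_diameter_nm), length(core_diameter_nm) == 1L)
  if (!is.finite(core_diameter_nm) || core_diameter_nm <= 0)
    stop("invalid particle spec: core_diameter_nm must be > 0", call. = FALSE)
  if (!is.finite(crystallite_diameter_nm) || crystallite_diameter_nm <= 0)
    stop("invalid particle spec: crystallite_diameter_nm must be > 0",
         call. = FALSE)
  if (!is.finite(shell_thickness_nm) || shell_thickness_nm < 0)
    stop("invalid particle spec: shell_thickness_nm must be >= 0",
         call. = FALSE)
  if (!is.finite(packing_fraction) ||
      packing_fraction <= 0 || packing_fraction > 1)
    stop("invalid particle spec: packing_fraction must be in (0, 1]",
         call. = FALSE)
  if (!is.finite(magnetite_density_g_cm3) || magnetite_density_g_cm3 <= 0)
    stop("invalid particle spec: magnetite_density_g_cm3 must be > 0",
         call. = FALSE)
  if (!is.finite(fe_mass_fraction) ||
      fe_mass_fraction <= 0 || fe_mass_fraction >= 1)
    stop("invalid particle spec: fe_mass_fraction must be in (0, 1)",
         call. = FALSE)
  if (!is.finite(saturation_magnetization_emu_g) ||
      saturation_magnetization_emu_g < 0)
    stop("invalid particle spec: saturation_magnetization_emu_g must be >= 0",
         call. = FALSE)
  structure(
    list(core_diameter_nm = core_diameter_nm,
         crystallite_diameter_nm = crystallite_diameter_nm,
         shell_thickness_nm = shell_thickness_nm,
         packing_fraction = packing_fraction,
         magnetite_density_g_cm3 = magnetite_density_g_cm3,
         fe_mass_fraction = fe_mass_fraction,
         saturation_magnetization_emu_g = saturation_magnetization_emu_g),
    class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat("Superparticle spec\n")
  cat(sprintf("  core diameter        : %.2f nm\n", x$core_diameter_nm))
  cat(sprintf("  crystallite diameter : %.2f nm\n", x$crystallite_diameter_nm))
  cat(sprintf("  shell thickness      : %.2f nm\n", x$shell_thickness_nm))
  cat(sprintf("  packing fraction     : %.3f\n", x$packing_fraction))
  cat(sprintf("  magnetite density    : %.2f g/cm^3\n",
              x$magnetite_density_g_cm3))
  cat(sprintf("  Fe mass fraction     : %.4f\n", x$fe_mass_fraction))
  cat(sprintf("  Ms                   : %.1f emu/g\n",
              x$saturation_magnetization_emu_g))
  invisible(x)
}

#' Magnetite mass per superparticle
#'
#' Core volume times packing fraction times bulk magnetite density.
#'
#' @param spec A [particle_spec()].
#' @return Magnetite mass per particle in kg.
#' @export
magnetite_mass_per_particle <- function(spec) {
  stopifnot(inherits(spec, "particle_spec"))
  d_m <- spec$core_diameter_nm * 1e-9
  rho <- spec$magnetite_density_g_cm3 * 1000      # kg/m^3
  (pi / 6) * d_m^3 * spec$packing_fraction * rho
}

#' Elemental iron mass per superparticle
#'
#' @param spec A [particle_spec()].
#' @return Iron mass per particle in pg.
#' @examples
#' iron_mass_per_particle(particle_spec())       # ~2.21e-4 pg
#' iron_mass_per_particle(particle_spec(packing_fraction = 1))  # ~3.56e-4 pg
#' @export
iron_mass_per_particle <- function(spec) {
  stopifnot(inherits(spec, "particle_spec"))
  kg <- magnetite_mass_per_particle(spec) * spec$fe_mass_fraction
  kg * 1e15   # kg -> pg
}

#' Particle count from a total elemental-iron mass
#'
#' Divides a measured iron mass by the per-particle iron mass. The count
#' is returned as a real number, not rounded: it is an estimate of an
#' ensemble size, and downstream force arithmetic uses it unrounded.
#'
#' @param total_iron Total iron mass, in the units named by `units`.
#' @param per_particle_iron Iron mass per particle, pg. Must be > 0.
#' @param units Units of `total_iron`: `"pg"` or `"ug"`.
#' @return Estimated particle count (dimensionless, >= 0).
#' @examples
#' particle_count_from_iron(2.05, 2.21e-4)          # ~9.28e3 per cell
#' particle_count_from_iron(3.57, 2.21e-4, "ug")    # ~1.62e10 per nerve
#' @export
particle_count_from_iron <- function(total_iron, per_particle_iron,
                                     units = c("pg", "ug")) {
  units <- match.arg(units)
  if (!is.numeric(per_particle_iron) || any(!is.finite(per_particle_iron)) ||
      any(per_particle_iron <= 0))
    stop("per_particle_iron must be a positive, finite mass (pg)",
         call. = FALSE)
  if (!is.numeric(total_iron) || any(!is.finite(total_iron)) ||
      any(total_iron < 0))
    stop("total_iron must be finite and >= 0", call. = FALSE)
  total_pg <- if (units == "ug") total_iron * 1e6 else total_iron
  total_pg / per_particle_iron
}

#' Read an iron-mass measurement table
#'
#' Expects columns `subject_id`, `compartment` (`cell` or `tissue`),
#' `time_days`, `iron_mass`, `iron_mass_units` (`pg` or `ug`), and
#' optionally `uncertainty`.
#'
#' @param path CSV file path.
#' @return A data.frame with validated columns.
#' @export
read_iron_measurements <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "compartment", "time_days",
                "iron_mass", "iron_mass_units")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("iron measurement table missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!all(x$compartment %in% c("cell", "tissue")))
    stop("compartment must be 'cell' or 'tissue'", call. = FALSE)
  if (!all(x$iron_mass_units %in% c("pg", "ug")))
    stop("iron_mass_units must be 'pg' or 'ug'", call. = FALSE)
  if (any(x$iron_mass < 0) || any(x$time_days < 0))
    stop("iron_mass and time_days must be >= 0", call. = FALSE)
  if (!"uncertainty" %in% names(x)) x$uncertainty <- NA_real_
  x
}

#' Write an iron-mass measurement table
#'
#' @param x Data frame in the schema of [read_iron_measurements()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_iron_measurements <- function(x, path) {
  cols <- c("subject_id", "compartment", "time_days",
            "iron_mass", "iron_mass_units", "uncertainty")
  if (!"uncertainty" %in% names(x)) x$uncertainty <- NA_real_
  utils::write.csv(x[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
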