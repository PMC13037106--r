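# Seeded generators that emulate the statistical structure of each
# measurement type consumed by the analysis, so every stage is testable
# without any external data.
#
# One global seed derives a fixed per-generator substream via a string
# hash, so adding a generator never perturbs the draws of existing ones.

substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1000003L
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483629)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

#' Generate per-cell iron uptake masses
#'
#' Normal draws truncated at zero (negative draws are clamped to 0, not
#' re-drawn); at the default mean/SD the clamping probability is ~7e-4,
#' so the induced mean bias is well below 1%.
#'
#' @param n Number of cells.
#' @param mean_pg Mean uptake (pg). Default 2.05.
#' @param sd_pg SD of uptake (pg). Default 0.64.
#' @param seed Integer seed.
#' @return Numeric vector of per-cell iron masses (pg).
#' @export
gen_uptake <- function(n, mean_pg = 2.05, sd_pg = 0.64, seed = 1) {
  if (mean_pg <= 0) stop("mean_pg must be > 0", call. = FALSE)
  if (sd_pg < 0) stop("sd_pg must be >= 0", call. = FALSE)
  with_substream(seed, "uptake",
                 pmax(0, stats::rnorm(n, mean_pg, sd_pg)))
}

#' Generate a tissue iron clearance time series
#'
#' m(t) = m0 exp(-k t) exp(eps), eps ~ Normal(0, noise_sigma^2)
#' (multiplicative lognormal noise).
#'
#' @param m0 Initial mass (ug), >= 0.
#' @param k Decay rate (1/day), >= 0.
#' @param times_days Sampling times (days).
#' @param noise_sigma SD of the log-scale noise.
#' @param seed Integer seed.
#' @param label Series label.
#' @return An [iron_timeseries()].
#' @export
gen_clearance_series <- function(m0, k, times_days = c(1, 3, 7, 14),
                                 noise_sigma = 0, seed = 1,
                                 label = "synthetic") {
  if (m0 < 0 || k < 0) stop("m0 and k must be >= 0", call. = FALSE)
  eps <- with_substream(seed, "clearance",
                        stats::rnorm(length(times_days), 0, noise_sigma))
  iron_timeseries(times_days, m0 * exp(-k * times_days) * exp(eps),
                  label = label)
}

# Nominal healthy-limb footprint lengths for an adult rat (mm).
FOOTPRINT_NOMINAL <- c(npl = 40, nts = 18, nit = 9)

#' Generate a footprint record with a prescribed noiseless SFI
#'
#' Holds the normal-limb lengths at nominal values and moves the
#' experimental limb along a one-parameter injury axis (print length up,
#' both toe spreads down) solved so that the noiseless record scores
#' exactly the target SFI; additive Gaussian noise is then applied to all
#' six lengths.
#'
#' @param target_sfi Target score of the noiseless record.
#' @param noise_mm SD of additive length noise (mm).
#' @param seed Integer seed.
#' @return A one-row data.frame with columns `epl,npl,ets,nts,eit,nit`.
#' @examples
#' r <- gen_footprints(-74.18, noise_mm = 0)
#' sfi(r$epl, r$npl, r$ets, r$nts, r$eit, r$nit)   # -74.18
#' @export
gen_footprints <- function(target_sfi, noise_mm = 0, seed = 1) {
  nom <- FOOTPRINT_NOMINAL
  # injury axis: epl = npl(1 + s/2), ets = nts(1 - s), eit = nit(1 - s)
  # => sfi = -8.8 - (38.3/2 + 109.5 + 13.3) s
  slope <- 38.3 / 2 + 109.5 + 13.3
  s <- (-8.8 - target_sfi) / slope
  if (s >= 1 || s <= -2)
    stop("target SFI ", target_sfi, " is infeasible with positive lengths",
         call. = FALSE)
  rec <- data.frame(epl = nom["npl"] * (1 + s / 2), npl = nom["npl"],
                    ets = nom["nts"] * (1 - s), nts = nom["nts"],
                    eit = nom["nit"] * (1 - s), nit = nom["nit"],
                    row.names = NULL)
  if (noise_mm > 0) {
    eps <- with_substream(seed, "footprints", stats::rnorm(6, 0, noise_mm))
    rec[1, ] <- pmax(as.numeric(rec[1, ]) + eps, 0.1)
  }
  rec
}

# von Mises(0, kappa) sampler (Best & Fisher 1979 rejection scheme);
# kappa = 0 falls back to uniform on (-pi, pi].
rvonmises0 <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      i <- i + 1
      out[i] <- sign(u3 - 0.5) * acos(f)
    }
  }
  out
}

#' Generate cell orientation angles
#'
#' von Mises draws centered on the field direction, folded to the acute
#' angle in [0, pi/2]. Concentration 0 reduces to a uniform angle.
#'
#' @param n Number of cells.
#' @param concentration von Mises concentration (kappa), >= 0.
#' @param seed Integer seed.
#' @return Angles in radians, in \[0, pi/2\].
#' @export
gen_orientations <- function(n, concentration = 0, seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  raw <- with_substream(seed, "orientations", rvonmises0(n, concentration))
  fold_acute(raw)
}

#' Generate a step-transient calcium trace
#'
#' Baseline until the stimulation onset, then a smooth transient: linear
#' rise over `rise_s`, plateau at baseline + amplitude for `plateau_s`,
#' then exponential relaxation with time constant `decay_tau_s`; Gaussian
#' noise on every sample. Defaults emulate a 50 s baseline within a 650 s
#' imaging span at 1 Hz.
#'
#' @param baseline Baseline fluorescence (> 0).
#' @param amplitude Plateau height above baseline (>= 0).
#' @param onset_s Stimulation onset (s). Default 50.
#' @param duration_s Total trace span (s). Default 650.
#' @param noise SD of additive Gaussian noise.
#' @param seed Integer seed.
#' @param dt_s Sampling interval (s). Default 1.
#' @param rise_s,plateau_s,decay_tau_s Transient shape parameters (s).
#' @return A [calcium_trace()].
#' @examples
#' tr <- gen_calcium_trace(100, 85, noise = 0)
#' calcium_metrics(tr)$Fmax_over_F0    # 1.85
#' @export
gen_calcium_trace <- function(baseline, amplitude, onset_s = 50,
                              duration_s = 650, noise = 0, seed = 1,
                              dt_s = 1, rise_s = 20, plateau_s = 300,
                              decay_tau_s = 150) {
  if (baseline <= 0) stop("baseline must be > 0", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  t <- seq(dt_s, duration_s, by = dt_s)
  u <- t - onset_s
  signal <- ifelse(u <= 0, 0,
            ifelse(u <= rise_s, u / rise_s,
            ifelse(u <= rise_s + plateau_s, 1,
                   exp(-(u - rise_s - plateau_s) / decay_tau_s))))
  y <- baseline + amplitude * signal
  if (noise > 0)
    y <- y + with_substream(seed, "calcium",
                            stats::rnorm(length(t), 0, noise))
  calcium_trace(t, pmax(y, 0), stimulation_onset_s = onset_s)
}

#' Generate myelinated-fiber diameter pairs around a target G-ratio
#'
#' Fiber diameters are lognormal; each axon diameter is the fiber
#' diameter times a G-ratio drawn Normal(target, spread) and clipped to
#' (0, 1].
#'
#' @param n Number of fibers.
#' @param target_g Target G-ratio in (0, 1].
#' @param spread SD of the per-fiber G-ratio draw.
#' @param seed Integer seed.
#' @param fiber_meanlog,fiber_sdlog Lognormal parameters of the fiber
#'   diameter (um); defaults center near 6 um.
#' @return Data frame with `axon_um`, `fiber_um`.
#' @export
gen_fibers <- function(n, target_g = 0.69, spread = 0.05, seed = 1,
                       fiber_meanlog = log(6), fiber_sdlog = 0.25) {
  if (target_g <= 0 || target_g > 1)
    stop("target_g must be in (0, 1]", call. = FALSE)
  with_substream(seed, "fibers", {
    fiber <- stats::rlnorm(n, fiber_meanlog, fiber_sdlog)
    g <- pmin(pmax(stats::rnorm(n, target_g, spread), 1e-3), 1)
    data.frame(axon_um = fiber * g, fiber_um = fiber)
  })
}

#' Materialize a demo dataset of every generator's output
#'
#' Writes one CSV per measurement type into `dir`, in the schemas the
#' consumer functions read.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    uptake = file.path(dir, "cell_iron_uptake.csv"),
    clearance = file.path(dir, "nerve_iron_timeseries.csv"),
    footprints = file.path(dir, "footprints.csv"),
    orientations = file.path(dir, "orientations.csv"),
    calcium = file.path(dir, "calcium_trace.csv"),
    fibers = file.path(dir, "fibers.csv"))

  up <- gen_uptake(100, seed = seed)
  write_iron_measurements(
    data.frame(subject_id = sprintf("cell_%03d", seq_along(up)),
               compartment = "cell", time_days = 1,
               iron_mass = up, iron_mass_units = "pg",
               uncertainty = NA_real_),
    paths["uptake"])

  ser <- gen_clearance_series(4.11, 0.1747, noise_sigma = 0.1, seed = seed)
  write_iron_measurements(
    data.frame(subject_id = "nerve_synth", compartment = "tissue",
               time_days = ser$times_days, iron_mass = ser$masses_ug,
               iron_mass_units = "ug", uncertainty = NA_real_),
    paths["clearance"])

  fp <- do.call(rbind, lapply(seq_len(10), function(i)
    gen_footprints(-50.94, noise_mm = 0.5, seed = seed + i)))
  fp$subject_id <- sprintf("rat_%02d", seq_len(nrow(fp)))
  utils::write.csv(fp, paths["footprints"], row.names = FALSE, quote = FALSE)

  th <- gen_orientations(200, concentration = 2, seed = seed)
  utils::write.csv(data.frame(theta_rad = th), paths["orientations"],
                   row.names = FALSE, quote = FALSE)

  tr <- gen_calcium_trace(100, 85, noise = 2, seed = seed)
  utils::write.csv(data.frame(time_s = tr$times_s,
                              intensity = tr$intensities),
                   paths["calcium"], row.names = FALSE, quote = FALSE)

  utils::write.csv(gen_fibers(200, seed = seed), paths["fibers"],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
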