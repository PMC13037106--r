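test_that("Langevin magnetization has the correct limits and values", {
  model <- magnetization_model()
  expect_identical(langevin_magnetization(0, model), 0)
  # construct the field giving Langevin argument x = 2
  kB <- 1.380649e-23
  m_cryst <- 4.8e5 * (pi / 6) * (5.80e-9)^3
  b2 <- 2 * kB * 300 / m_cryst
  expect_equal(langevin_magnetization(b2, model), 30 * (1 / tanh(2) - 0.5),
               tolerance = 1e-10)
  # saturation approached from below, never exceeded
  expect_lt(langevin_magnetization(100, model), 30)
  expect_equal(langevin_magnetization(100, model), 30, tolerance = 0.01)
})

test_that("Langevin function is odd, monotone, and bounded by min(1, x/3)", {
  model <- magnetization_model()
  b <- seq(0, 2, length.out = 200)
  m <- langevin_magnetization(b, model)
  expect_true(all(diff(m) > 0))
  expect_true(all(m >= 0 & m < 30))
  # small-argument linearity: L(x) ~ x/3 within 1e-6 relative at x <= 1e-3
  kB <- 1.380649e-23
  m_cryst <- 4.8e5 * (pi / 6) * (5.80e-9)^3
  for (x in c(1e-5, 1e-4, 1e-3)) {
    bx <- x * kB * 300 / m_cryst
    expect_equal(langevin_magnetization(bx, model), 30 * x / 3,
                 tolerance = 1e-6)
  }
})

test_that("particle moment works in calibrated and model modes", {
  spec <- ref_spec()
  # calibrated: F / grad arithmetic from the in vivo reference pair
  expect_equal(particle_moment(spec, calibration = ref_invivo_cal),
               7.94e-18, tolerance = 0.01)
  # model mode at saturating field: Ms x magnetite mass per particle
  m_sat <- particle_moment(spec, mode = "model", field_T = 1e3)
  expect_equal(m_sat, 9.15e-18, tolerance = 0.01)
  expect_identical(particle_moment(spec, mode = "model", field_T = 0), 0)
  expect_error(particle_moment(spec, mode = "model"), "field_T")
  expect_error(magnetization_model(temperature_K = -1), "temperature")
})

test_that("force on a particle reproduces both published per-particle forces", {
  m_invivo <- particle_moment(ref_spec(), calibration = ref_invivo_cal)
  expect_equal(force_on_particle(m_invivo, 16.0), 1.27e-4,
               tolerance = 1e-10)
  m_invitro <- particle_moment(ref_spec(), calibration = ref_invitro_cal)
  expect_equal(force_on_particle(m_invitro, 3.25), 1.59e-5,
               tolerance = 1e-10)
  expect_identical(force_on_particle(m_invivo, 0), 0)
})

test_that("force is bilinear in moment and gradient", {
  set.seed(7)
  for (i in 1:20) {
    m <- runif(1, 1e-18, 1e-16); g <- runif(1, 0, 20); a <- runif(1, 0, 5)
    expect_equal(force_on_particle(a * m, g), a * force_on_particle(m, g),
                 tolerance = 1e-12)
    expect_equal(force_on_particle(m, a * g), a * force_on_particle(m, g),
                 tolerance = 1e-12)
  }
})

test_that("ensemble forces match the per-cell and per-nerve dose numbers", {
  expect_equal(ensemble_force(9.30e3, 1.59e-5), 0.148, tolerance = 0.01)
  f_nerve <- ensemble_force(1.62e10, 1.27e-4)
  expect_equal(f_nerve * 1e-6, 2.05, tolerance = 0.01)
  expect_identical(ensemble_force(0, 1), 0)
  expect_match(format_force(f_nerve), "uN")
  expect_match(format_force(0.148), "pN")
})

test_that("electromagnet calibration fit reproduces the printed points", {
  em <- ref_em()
  expect_equal(electromagnet_gradient(3, em), 3.25, tolerance = 1e-9)
  expect_equal(electromagnet_gradient(2, em), 2.25, tolerance = 1e-9)
  expect_equal(electromagnet_gradient(1, em), 1.25, tolerance = 1e-9)
  expect_identical(electromagnet_gradient(0, em), 0)
  expect_warning(electromagnet_gradient(5, em), "extrapolat")
  expect_error(electromagnet_source(cbind(1, 1.25)), "calibration")
  expect_error(electromagnet_source(cbind(c(2, 1), c(1, 2))), "increasing")
})

test_that("ring-array axial profile obeys symmetry and degenerate cases", {
  # zero remanence: no field anywhere
  z <- seq(-50, 50, by = 5)
  off <- ring_array_source(35, 75, 15, c(-20, 20), c(1, 1), remanence_T = 0)
  p0 <- ring_axial_profile(z, off)
  expect_true(all(p0$B_T == 0) && all(p0$dBdz_T_per_m == 0))
  # co-oriented mirror pair: even B, zero gradient at center
  co <- ring_array_source(35, 75, 15, c(-20, 20), c(1, 1))
  pc <- ring_axial_profile(c(-10, 0, 10), co)
  expect_equal(pc$dBdz_T_per_m[2], 0, tolerance = 1e-12)
  expect_equal(pc$B_T[1], pc$B_T[3], tolerance = 1e-12)
  # opposed mirror pair: B(0) = 0 with a nonzero central gradient
  op <- ring_array_source(35, 75, 15, c(-20, 20), c(1, -1))
  po <- ring_axial_profile(0, op)
  expect_equal(po$B_T, 0, tolerance = 1e-15)
  expect_gt(abs(po$dBdz_T_per_m), 0)
  expect_error(ring_array_source(75, 35, 15, 0), "geometry")
})

test_that("ring far field matches a point dipole of equal total moment", {
  src <- ring_array_source(35, 75, 15, 0, 1, remanence_T = 1.40)
  V <- pi * (0.075^2 - 0.035^2) * 0.015
  mu0 <- 4e-7 * pi
  m_tot <- (1.40 / mu0) * V
  for (z_mm in c(400, 600, 1000)) {
    b <- ring_axial_profile(z_mm, src)$B_T
    b_dip <- mu0 * m_tot / (2 * pi * (z_mm / 1000)^3)
    expect_equal(b, b_dip, tolerance = 0.05)
  }
})

test_that("analytic gradient agrees with central finite differences", {
  src <- ring_array_source(35, 75, 15, c(-30, -15, 15, 30), c(1, 1, -1, -1))
  h_mm <- 0.01   # 10 um step
  for (z_mm in c(-40, -3, 0, 12, 35)) {
    p <- ring_axial_profile(c(z_mm - h_mm, z_mm, z_mm + h_mm), src)
    fd <- (p$B_T[3] - p$B_T[1]) / (2 * h_mm * 1e-3)
    expect_equal(p$dBdz_T_per_m[2], fd, tolerance = 1e-4)
  }
})
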