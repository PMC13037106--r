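test_that("SFI reproduces hand-computed and limit cases", {
  # identical limbs score the formula's constant term
  expect_equal(sfi(2, 2, 1.5, 1.5, 1, 1), -8.8)
  # term-by-term hand computation
  expect_equal(sfi(2.4, 2.0, 1.0, 2.0, 0.8, 1.5), -77.42, tolerance = 1e-3)
  # toe spread collapsing to zero drives the score toward -8.8 - 109.5
  near <- sfi(2, 2, 1e-9, 2, 1, 1)
  expect_equal(near, -8.8 - 109.5, tolerance = 1e-6)
  expect_error(sfi(2, 0, 1, 1, 1, 1), "> 0")
})

test_that("SFI is invariant under common rescaling of all lengths", {
  set.seed(5)
  for (i in 1:20) {
    v <- runif(6, 0.5, 3)
    k <- runif(1, 0.1, 10)
    expect_equal(do.call(sfi, as.list(v * k)), do.call(sfi, as.list(v)),
                 tolerance = 1e-9)
  }
})

test_that("viability percentage handles identity, arithmetic, and errors", {
  expect_equal(viability_percent(1.05 + 0.10 - 0.05, 1.05, 0.05, 0.10), 100)
  expect_equal(viability_percent(0.95, 1.05, 0.05, 0.10), 85)
  expect_equal(viability_percent(0.10, 1.05, 0.05, 0.10), 0)
  expect_warning(v <- viability_percent(0.05, 1.05, 0.05, 0.10), "negative")
  expect_lt(v, 0)
  expect_error(viability_percent(1, 0.5, 0.6, 0.1), "A_control")
  # the blank and drug corrections must both enter the formula: moving
  # either alone changes the result (guards against a naive A/A_control)
  base <- viability_percent(0.95, 1.05, 0.05, 0.10)
  expect_false(isTRUE(all.equal(
    base, viability_percent(0.95, 1.05, 0.15, 0.10))))
  expect_false(isTRUE(all.equal(
    base, viability_percent(0.95, 1.05, 0.05, 0.20))))
})

test_that("orientation index is the cosine of the folded acute angle", {
  expect_equal(orientation_index(0), 1)
  expect_equal(orientation_index(pi / 2), 0, tolerance = 1e-12)
  expect_equal(orientation_index(pi / 4), 0.7071, tolerance = 1e-4)
  # folding: obtuse and negative angles map to their acute equivalent
  expect_equal(orientation_index(3 * pi / 4), orientation_index(pi / 4))
  expect_equal(orientation_index(-pi / 6), orientation_index(pi / 6))
  expect_equal(orientation_index(pi + pi / 6), orientation_index(pi / 6))
  # monotone decreasing on [0, pi/2], bounded in [0, 1]
  th <- seq(0, pi / 2, length.out = 100)
  oi <- orientation_index(th)
  expect_true(all(diff(oi) < 0))
  expect_true(all(oi >= 0 & oi <= 1))
})

test_that("G-ratio is axon over fiber with validated ordering", {
  expect_equal(g_ratio(1, 1), 1)
  expect_equal(g_ratio(0.7, 1.0), 0.70)
  expect_error(g_ratio(1.1, 1.0), "exceeds")
  expect_error(g_ratio(0, 1), "> 0")
})

test_that("calcium metrics follow the baseline-normalized conventions", {
  flat <- calcium_trace(1:100, rep(100, 100), 50)
  m <- calcium_metrics(flat)
  expect_equal(m$dF_over_F0_percent, 0)
  expect_equal(m$Fmax_over_F0, 1)
  step <- calcium_trace(1:100, c(rep(100, 49), rep(185, 51)), 50)
  m2 <- calcium_metrics(step)
  expect_equal(m2$dF_over_F0_percent, 85)
  expect_equal(m2$Fmax_over_F0, 1.85)
  # post-onset dips below baseline give negative dF/F0
  dip <- calcium_trace(1:100, c(rep(100, 49), rep(90, 51)), 50)
  expect_equal(calcium_metrics(dip)$dF_over_F0_percent, -10)
})

test_that("calcium metrics are invariant under intensity rescaling", {
  tr <- gen_calcium_trace(100, 85, noise = 3, seed = 9)
  m1 <- calcium_metrics(tr)
  tr2 <- calcium_trace(tr$times_s, tr$intensities * 7.3,
                       tr$stimulation_onset_s)
  m2 <- calcium_metrics(tr2)
  expect_equal(m1$dF_over_F0_percent, m2$dF_over_F0_percent,
               tolerance = 1e-10)
  expect_equal(m1$Fmax_over_F0, m2$Fmax_over_F0, tolerance = 1e-10)
})

test_that("calcium trace construction validates its window", {
  expect_error(calcium_trace(1:10, rep(1, 10), 20), "inside")
  expect_error(calcium_trace(1:10, rep(-1, 10), 5), ">= 0")
  expect_error(calcium_metrics(calcium_trace(1:100,
    c(rep(0, 49), rep(2, 51)), 50)), "F0")
})

test_that("conduction velocity is distance over latency difference", {
  expect_equal(mncv(30, 2.0, 1.0), 30)
  # round trip through a constructed measurement at a realistic velocity
  v <- 34.17
  d <- 30
  expect_equal(mncv(d, 1.5 + d / v, 1.5), v, tolerance = 1e-9)
  expect_error(mncv(30, 1.0, 1.0), "exceed")
  expect_error(mncv(0, 2.0, 1.0), "> 0")
})

test_that("F/G-actin ratio is plain division with a guarded denominator", {
  expect_equal(fg_ratio(1, 1), 1)
  expect_equal(fg_ratio(0.105, 0.283), 0.371, tolerance = 1e-2)
  expect_equal(fg_ratio(0, 5), 0)
  expect_error(fg_ratio(1, 0), "> 0")
})

test_that("median_iqr summarizes skewed metric vectors", {
  x <- c(1, 2, 3, 4, 100)
  s <- median_iqr(x)
  expect_equal(s$median, 3)
  expect_lte(s$q1, s$median)
  expect_gte(s$q3, s$median)
})
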