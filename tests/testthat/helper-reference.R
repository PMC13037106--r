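# Shared reference objects: the default superparticle and the two
# published force calibrations used across test files.

ref_spec <- function() particle_spec()

ref_em <- function() {
  electromagnet_source(cbind(c(1, 2, 3), c(1.25, 2.25, 3.25)))
}

ref_invitro_cal <- list(force_pN = 1.59e-5, gradient_T_m = 3.25)
ref_invivo_cal <- list(force_pN = 1.27e-4, gradient_T_m = 16.0)

ref_nerve_series <- function() {
  iron_timeseries(c(1, 3, 7, 14), c(3.57, 2.13, 1.40, 0.34),
                  label = "nerve")
}

# Independent closed-form OLS on (t, log m): textbook normal equations,
# kept free of the package's own fitting path.
ols_log_fit <- function(t, m) {
  y <- log(m)
  beta <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  alpha <- mean(y) - beta * mean(t)
  list(rate = -beta, m0 = exp(alpha))
}
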