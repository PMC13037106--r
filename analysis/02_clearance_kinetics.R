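#!/usr/bin/env Rscript
# Fits first-order clearance to the bundled nerve iron time series and
# checks, by simulation, that the log-linear estimator recovers a known
# decay rate under multiplicative measurement noise.

library(magnetodose)

tab <- read_iron_measurements(
  system.file("extdata", "nerve_iron_timeseries.csv",
              package = "magnetodose"))
series <- iron_timeseries(tab$time_days, tab$iron_mass, label = "nerve")
fit <- fit_clearance(series)
print(fit)

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(
  initial_mass_ug = fit$initial_mass_ug,
  decay_rate_per_day = fit$decay_rate_per_day,
  half_life_days = fit$half_life_days,
  r_squared = fit$r_squared),
  "results/clearance_fit.csv", row.names = FALSE)

# recovery under noise: 200 synthetic series at the fitted rate
k <- fit$decay_rate_per_day
rates <- vapply(1:200, function(r) {
  s <- gen_clearance_series(fit$initial_mass_ug, k,
                            times_days = seq(1, 15, by = 2),
                            noise_sigma = 0.1, seed = 7000 + r)
  fit_clearance(s)$decay_rate_per_day
}, numeric(1))
cat(sprintf("\nRecovery over 200 noisy replicates: mean %.4f /day vs
truth %.4f /day (%.2f%% relative error)\n",
            mean(rates), k, 100 * abs(mean(rates) - k) / k))
write.csv(data.frame(replicate = seq_along(rates), fitted_rate = rates),
          "results/clearance_recovery.csv", row.names = FALSE)
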