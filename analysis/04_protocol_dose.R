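#!/usr/bin/env Rscript
# Summarizes both stimulation schedules and integrates the decaying
# nerve force over the 14-day session protocol into a cumulative
# mechanical impulse.

library(magnetodose)

invitro <- stim_protocol_cyclic(15, 15, 12)
invivo <- stim_protocol_daily(c(6, 12, 18), 15, 14)
s1 <- build_schedule(invitro); s2 <- build_schedule(invivo)
dir.create("results", showWarnings = FALSE)
write_schedule(s1, "results/schedule_invitro.csv")
write_schedule(s2, "results/schedule_invivo.csv")

a <- schedule_summary(s1); b <- schedule_summary(s2)
cat(sprintf("In vitro: %d ON intervals, %g min ON, duty cycle %.2f\n",
            a$n_on, a$total_on_min, a$duty_cycle))
cat(sprintf("In vivo : %d sessions, %g min ON, duty cycle %.4f\n",
            b$n_on, b$total_on_min, b$duty_cycle))

# force decays with the fitted clearance; integrate over ON time only
report <- run_config(reference_config())
cat(sprintf(
  "Cumulative impulse on the nerve over 14 days of sessions: %.3g pN s
(= %.3g uN h of sustained ON-time loading)\n",
  report$invivo$cumulative_impulse_pN_s,
  report$invivo$cumulative_impulse_pN_s * 1e-6 / 3600))
write.csv(data.frame(
  cumulative_impulse_pN_s = report$invivo$cumulative_impulse_pN_s),
  "results/cumulative_impulse.csv", row.names = FALSE)
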