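#!/usr/bin/env Rscript
# Simulate hourly pulse-positive frame counts with the study's estimated
# structure (period means 64.6/57.1/18.5/15.4 frames per hour, instrument
# SD 0.12, day-within-instrument SD 0.43, theta 6.22; 3 instruments over
# JD 156-218), fit the negative-binomial mixed model, and report marginal
# means, Tukey-adjusted period contrasts and residual diagnostics.

library(finpulse)

dir.create("results", showWarnings = FALSE)

counts <- simulate_counts(count_sim_config(seed = 20260101L))
utils::write.csv(counts, "results/hourly_counts.csv", row.names = FALSE)

fit <- fit_nb_glmm(counts)
print(fit)

em <- emm_periods(fit)
ct <- pairwise_contrasts(fit)
dg <- nb_glmm_diagnostics(fit)

utils::write.csv(em, "results/emm_periods.csv", row.names = FALSE)
utils::write.csv(ct, "results/period_contrasts.csv", row.names = FALSE)
jsonlite::write_json(
  list(theta = fit$theta, sigma_instrument = fit$sigma_instrument,
       sigma_day = fit$sigma_day, loglik = fit$loglik,
       diagnostics = dg[c("ks_p", "dispersion_ratio", "dispersion_p",
                          "zero_obs", "zero_sim_mean", "zero_p")]),
  "results/glmm_fit.json", auto_unbox = TRUE, digits = NA)

message("\nEstimated marginal means (detections per hour):")
print(as.data.frame(em))
message("\nPairwise contrasts (Tukey-adjusted):")
print(as.data.frame(ct[, c("contrast", "ratio", "z", "p_adj")]))
message(sprintf(
  "\ndiagnostics: KS uniformity p = %.2f, dispersion ratio = %.2f (p = %.2f), zeros %d obs vs %.1f expected (p = %.2f)",
  dg$ks_p, dg$dispersion_ratio, dg$dispersion_p, dg$zero_obs,
  dg$zero_sim_mean, dg$zero_p))
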