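#!/usr/bin/env Rscript
# Step 4 — validate the final model: subject-resampling bootstrap,
# visual predictive check, and normalized prediction distribution
# errors. Writes the diagnostic tables.

library(cipropk)
dataset <- read_pk_dataset("results/cohort.csv")
est <- read.csv("results/pop_estimates.csv")
g <- function(p) est$estimate[est$parameter == p]
final <- pop_model(clp = g("clp"), theta_clcr = g("theta_CLCR_cl"),
                   vdp = g("vdp"), omega_cl = g("omega_cl"),
                   omega_vd = g("omega_vd"), sigma_add = g("sigma_add"),
                   sigma_prop = g("sigma_prop"), covariate = "linear")

boot <- bootstrap_ci(dataset, terms = cov_effect("CL", "CLCR", "linear",
                                                 ref = 1.25),
                     n_boot = 200, seed = 77)
write.csv(boot$summary, "results/bootstrap.csv", row.names = FALSE)
message(sprintf("Bootstrap (%d replicates, %.0f%% failed):",
                200, 100 * boot$fail_rate))
print(boot$summary, row.names = FALSE, digits = 4)

v <- vpc(dataset, final, n_sim = 1000, seed = 78)
write.csv(v$bands, "results/vpc_bands.csv", row.names = FALSE)
print(v)

np <- npde(dataset, final, K = 1000, seed = 79)
write.csv(data.frame(npde = np$npde), "results/npde_values.csv",
          row.names = FALSE)
write.csv(data.frame(mean = np$mean, se_mean = np$se_mean,
                     p_mean = np$p_mean, var = np$var,
                     se_var = np$se_var, p_var = np$p_var),
          "results/npde_tests.csv", row.names = FALSE)
print(np)
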