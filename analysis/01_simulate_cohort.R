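#!/usr/bin/env Rscript
# Step 1 — build the virtual study: a cohort of critically ill adults
# on intravenous ciprofloxacin (30-min infusions of 400 or 600 mg q8h
# or q12h), sampled at 1 h, 4 h and trough after the end of the
# infusion on an early (within 36 h) and a delayed (72-96 h) occasion,
# with renal function and other covariates re-measured per occasion.
# Writes the long-format dataset and a covariate summary.

library(cipropk)
dir.create("results", showWarnings = FALSE)

n <- 30
cohort <- sample_cohort(n, seed = 2019)
regimens <- assign_regimen(n, policy = "random-mix", seed = 2020)
dataset <- simulate_dataset(cohort, regimens, model = reference_model(),
                            seed = 2021)

write_pk_dataset(dataset, "results/cohort.csv")
write.csv(cohort, "results/covariates.csv", row.names = FALSE)

summ <- do.call(rbind, lapply(c("CLCR", "AGE", "WT", "HT", "BILI"),
  function(v) {
    x <- cohort[cohort$OCC == "early", v]
    data.frame(covariate = v, median = median(x),
               min = min(x), max = max(x))
  }))
write.csv(summ, "results/covariate_summary.csv", row.names = FALSE)

obs <- dataset[dataset$EVID == 0, ]
message(sprintf("Simulated %d subjects, %d observations (%d doses/day regimens: %s)",
        n, nrow(obs), length(unique(regimens$DAILY)),
        paste(sort(unique(regimens$DAILY)), collapse = "/")))
message("Early-phase covariate medians (CLcr mL/s, age y, weight kg):")
print(summ, row.names = FALSE)
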