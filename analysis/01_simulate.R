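#!/usr/bin/env Rscript
# Simulate the study cohort: 1947 mothers across first-birth decades
# 1880s-1970s with the calibrated decade parameters, then mask offspring
# survival/breeding records to the calibrated completeness proportions.
# Writes results/data/{mothers,offspring,truth}.csv.

library(breedfail)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- default_calibration(seed = seed)
write_sim_config(cfg, file.path(out, "config.yaml"))

cohort <- generate_cohort(cfg, seed = seed)
masked <- apply_missingness(cohort, cfg$missingness, seed = seed + 1L)
write_cohort(masked, file.path(out, "mothers.csv"),
             file.path(out, "offspring.csv"))
write_truth(masked, file.path(out, "truth.csv"))

message(sprintf(
  "simulated %d mothers / %d offspring; %.1f%% of offspring survival records masked",
  nrow(masked$mothers), nrow(masked$offspring),
  100 * mean(masked$offspring$survival15 == "unknown")
))
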