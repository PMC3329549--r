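#!/usr/bin/env Rscript
# Derive per-mother life-history traits and the weighted estimates of
# offspring survival, breeding probability, lifetime reproductive success
# and breeding failure from the masked cohort.
# Reads results/data/, writes results/traits.tsv and results/estimates.tsv.

library(breedfail)

cohort <- read_cohort("results/data/mothers.csv",
                      "results/data/offspring.csv")
traits <- derive_traits(cohort)
estimates <- trait_estimates(cohort)

readr::write_tsv(traits, "results/traits.tsv")
readr::write_tsv(estimates, "results/estimates.tsv")

excl <- estimates |>
  dplyr::group_by(response) |>
  dplyr::summarise(excluded = mean(excluded), weight1 = mean(weight == 1))
message("per-response record completeness (share weight-1 / excluded):")
for (i in seq_len(nrow(excl))) {
  message(sprintf("  %-9s weight-1 %.3f, excluded %.3f",
                  excl$response[i], excl$weight1[i], excl$excluded[i]))
}
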