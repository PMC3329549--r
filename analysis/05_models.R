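#!/usr/bin/env Rscript
# Decade-stratified weighted GLMs for the five association families
# (fertility ~ AFR; survival, breeding, LRS and breeding failure each ~
# fertility and ~ AFR), simplified from maximum models with all
# focal x decade x class interactions by backward stepwise likelihood-ratio
# tests, with the middle/upper class-collapsing rule.
# Writes results/models/<response>_by_<focal>.json and a summary line each.

library(breedfail)

cohort <- read_cohort("results/data/mothers.csv",
                      "results/data/offspring.csv")
traits <- derive_traits(cohort)
estimates <- trait_estimates(cohort)
dir.create("results/models", showWarnings = FALSE, recursive = TRUE)

analyses <- default_analyses()
for (i in seq_len(nrow(analyses))) {
  a <- analyses[i, ]
  tag <- paste0(a$response, "_by_", a$focal)
  res <- suppressWarnings(
    run_association(traits, estimates, a$response, a$focal,
                    family = a$family, quadratic = a$quadratic)
  )
  focal_row <- res$fit$coefficients[res$fit$coefficients$term == a$focal, ]
  message(sprintf(
    "%-22s n=%4d min model: %s%s%s", tag, res$n,
    paste(res$terms_min, collapse = " + "),
    if (nrow(focal_row) == 1)
      sprintf(" | %s coef %.3f (%s %.2f)", a$focal, focal_row$estimate,
              res$fit$stat_label, focal_row$statistic) else "",
    if (!is.na(res$collapse)) paste0(" | ses: ", res$collapse) else ""
  ))
  jsonlite::write_json(
    list(response = res$response, focal = res$focal, family = res$family,
         n = res$n, boxcox = res$boxcox, terms_max = res$terms_max,
         terms_min = res$terms_min, ses_collapse = res$collapse,
         elimination = res$elimination,
         coefficients = res$fit$coefficients,
         logLik = res$fit$logLik, df = res$fit$df,
         converged = res$fit$converged),
    file.path("results/models", paste0(tag, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
}
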