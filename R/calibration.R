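#' Reference decade-level calibration table
#'
#' Descriptive statistics of the Finnish church-register study cohorts
#' (mothers with first births 1880--1979, three parishes, 1947 mothers),
#' one row per first-birth decade: sample size, mean and standard error of
#' maternal age at first reproduction (AFR), age at last reproduction
#' (ALR), reproductive span, mean birth interval, lifetime fertility
#' (offspring quantity q), offspring survival rate to age 15 (s), offspring
#' breeding probability, and maternal lifetime reproductive success (LRS).
#' These values both calibrate the synthetic generator and serve as inputs
#' for summary-level consistency checks.
#'
#' @return A tibble with 10 rows (decades 1880s--1970s).
#' @export
reference_decades <- function() {
  tibble::tibble(
    decade = factor(decade_labels(), levels = decade_labels()),
    n = c(291L, 271L, 246L, 195L, 266L, 257L, 173L, 78L, 79L, 91L),
    afr_mean = c(26.6, 25.1, 25.9, 25.8, 25.7, 26.2, 28.7, 25.7, 23.7, 25.6),
    afr_se = c(0.3, 0.3, 0.3, 0.4, 0.3, 0.3, 0.4, 0.6, 0.4, 0.5),
    alr_mean = c(38.0, 36.0, 35.9, 35.3, 33.8, 33.4, 33.8, 30.7, 28.7, 30.1),
    alr_se = c(0.4, 0.4, 0.4, 0.5, 0.4, 0.4, 0.5, 0.6, 0.5, 0.6),
    span_mean = c(11.4, 10.9, 10.1, 9.5, 8.1, 7.2, 5.1, 5.0, 5.0, 4.5),
    span_se = c(0.4, 0.4, 0.5, 0.5, 0.4, 0.4, 0.4, 0.6, 0.5, 0.5),
    bi_mean = c(2.3, 2.3, 2.3, 2.3, 2.6, 2.5, 2.2, 2.3, 2.4, 2.4),
    bi_se = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.2, 0.2, 0.2),
    fertility_mean = c(5.3, 5.0, 4.6, 4.5, 3.5, 3.2, 2.6, 2.4, 2.3, 2.1),
    fertility_se = c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1, 0.1, 0.2, 0.1, 0.1),
    survival_prob = c(0.73, 0.75, 0.83, 0.85, 0.89, 0.93, 0.93, 0.99, 0.99,
                      0.99),
    survival_se = c(0.03, 0.03, 0.02, 0.03, 0.02, 0.02, 0.02, 0.01, 0.01,
                    0.01),
    breeding_prob = c(0.37, 0.41, 0.50, 0.58, 0.67, 0.65, 0.56, 0.83, 0.93,
                      0.96),
    breeding_se = c(0.03, 0.03, 0.04, 0.04, 0.03, 0.04, 0.06, 0.05, 0.04,
                    0.04),
    lrs_mean = c(2.0, 2.2, 2.3, 2.4, 1.9, 1.9, 1.6, 2.0, 2.0, 1.8),
    lrs_se = c(0.1, 0.2, 0.1, 0.2, 0.1, 0.1, 0.2, 0.2, 0.1, 0.2)
  )
}

#' Reference record-completeness proportions
#'
#' Proportions of mothers whose offspring records allow a response variable
#' to be determined exactly ("complete": all offspring tracked), only
#' estimated ("incomplete": some but not all offspring tracked), or not at
#' all ("missing": no offspring tracked, mother excluded). One row per
#' response variable.
#'
#' @return A tibble with columns `variable`, `complete`, `incomplete`,
#'   `missing`.
#' @export
reference_completeness <- function() {
  tibble::tibble(
    variable = c("fertility", "survival", "breeding", "lrs", "failure"),
    complete = c(1, 0.8660, 0.3374, 0.3374, 0.9666),
    incomplete = c(0, 0.1145, 0.4505, 0.4505, 0.0139),
    missing = c(0, 0.0195, 0.2121, 0.2121, 0.0195)
  )
}

#' Pool decade means into a total mean
#'
#' Sample-size-weighted mean of decade-level means: the total-row
#' convention of the reference table, `sum(n * mean) / sum(n)`. For
#' weighted traits, pass the per-decade weight totals as `n`.
#'
#' @param n Per-decade contributions (sample sizes or weight sums).
#' @param means Per-decade means.
#' @return The pooled mean.
#' @export
pool_decade_means <- function(n, means) {
  stopifnot(length(n) == length(means), all(n >= 0))
  keep <- !is.na(means) & n > 0
  sum(n[keep] * means[keep]) / sum(n[keep])
}

#' Default synthetic-cohort calibration
#'
#' Builds the generator configuration reproducing the structure of the
#' Finnish study cohorts: per-decade sample sizes, AFR distributions
#' (truncated normal, SD recovered from the printed standard errors as
#' `SE * sqrt(n)`), zero-truncated Poisson fertility means, offspring
#' survival probabilities, and marginal offspring breeding probabilities;
#' plus socio-economic class proportions (lower class 569/1947, the
#' non-lower remainder split 2:1 middle:upper) and the record-completeness
#' proportions. Class effects and family frailty default to zero so that
#' decade-level marginals equal the calibration values; `afr_fertility_slope`
#' defaults to -0.15 children per year of delayed first reproduction,
#' reproducing the negative fertility-AFR association.
#'
#' @param frailty_sd Family-level survival frailty SD on the logit scale.
#' @param afr_fertility_slope Children per year of AFR delay (negative).
#' @param fertility_multiplier_nonlower Multiplier on the fertility mean
#'   for middle/upper-class mothers.
#' @param survival_logit_shift_nonlower Additive survival log-odds shift
#'   for offspring of middle/upper-class mothers.
#' @param seed Default seed stored in the configuration.
#' @return A `breedfail_simconfig` list with elements `decades` (tibble of
#'   per-decade parameters), `class_effects`, `missingness`, `survive45_prob`
#'   and `seed`.
#' @export
default_calibration <- function(frailty_sd = 0,
                                afr_fertility_slope = -0.15,
                                fertility_multiplier_nonlower = 1,
                                survival_logit_shift_nonlower = 0,
                                seed = 1L) {
  ref <- reference_decades()
  decades <- tibble::tibble(
    decade = ref$decade,
    n_mothers = ref$n,
    afr_mean = ref$afr_mean,
    afr_sd = ref$afr_se * sqrt(ref$n),
    fertility_mean = ref$fertility_mean,
    survival_prob = ref$survival_prob,
    breeding_prob = ref$breeding_prob,
    frailty_sd = frailty_sd,
    afr_fertility_slope = afr_fertility_slope
  )
  p_lower <- 569 / 1947
  comp <- reference_completeness()
  cfg <- list(
    decades = decades,
    class_effects = list(
      class_proportions = c(
        lower = p_lower,
        middle = (1 - p_lower) * 2 / 3,
        upper = (1 - p_lower) * 1 / 3
      ),
      fertility_multiplier_nonlower = fertility_multiplier_nonlower,
      survival_logit_shift_nonlower = survival_logit_shift_nonlower
    ),
    missingness = list(
      survival = unlist(comp[comp$variable == "survival",
                             c("complete", "incomplete", "missing")]),
      breeding = unlist(comp[comp$variable == "breeding",
                             c("complete", "incomplete", "missing")]),
      tracking_prob = 0.5
    ),
    survive45_prob = 0.9,
    seed = as.integer(seed)
  )
  class(cfg) <- "breedfail_simconfig"
  validate_simconfig(cfg)
}

validate_simconfig <- function(cfg) {
  d <- cfg$decades
  lab <- as.character(d$decade)
  if (length(lab) == 0L || anyDuplicated(lab) ||
      !all(lab %in% decade_labels()) ||
      is.unsorted(match(lab, decade_labels()))) {
    abort(
      "decades must be a non-empty ordered subset of 1880s-1970s",
      class = "breedfail_config_error"
    )
  }
  ok <- all(d$n_mothers >= 1) &&
    all(d$survival_prob > 0 & d$survival_prob <= 1) &&
    all(d$breeding_prob > 0 & d$breeding_prob <= 1) &&
    all(d$fertility_mean >= 1) &&
    all(d$frailty_sd >= 0) &&
    all(d$afr_sd > 0)
  if (!ok) {
    abort("invalid decade parameters (counts, rates or dispersions)",
      class = "breedfail_config_error"
    )
  }
  pr <- cfg$class_effects$class_proportions
  if (length(pr) != 3L || any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
    abort("class_proportions must be a 3-level simplex",
      class = "breedfail_config_error"
    )
  }
  for (v in c("survival", "breeding")) {
    tri <- cfg$missingness[[v]]
    if (length(tri) != 3L || any(tri < 0) || abs(sum(tri) - 1) > 1e-8) {
      abort(paste0(v, " completeness proportions must sum to 1"),
        class = "breedfail_config_error"
      )
    }
  }
  invisible(cfg)
}

#' Restrict a configuration to selected decades
#'
#' Keeps only the given first-birth decades (e.g. `"1880s"`), for
#' single-decade replicate studies.
#'
#' @param cfg A `breedfail_simconfig`.
#' @param decades Character vector of decade labels to keep.
#' @return The restricted configuration.
#' @export
subset_decades <- function(cfg, decades) {
  stopifnot(all(decades %in% decade_labels()))
  cfg$decades <- cfg$decades[as.character(cfg$decades$decade) %in% decades, ]
  validate_simconfig(cfg)
}

#' @export
print.breedfail_simconfig <- function(x, ...) {
  cat("<breedfail_simconfig> ", sum(x$decades$n_mothers),
      " mothers across ", nrow(x$decades), " decades; seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Read / write a simulation configuration
#'
#' YAML serialization of a `breedfail_simconfig`, so runs are reproducible
#' from a plain-text file.
#'
#' @param cfg A `breedfail_simconfig`.
#' @param path File path.
#' @return `write_sim_config` returns `cfg` invisibly; `read_sim_config`
#'   returns the validated configuration.
#' @export
write_sim_config <- function(cfg, path) {
  validate_simconfig(cfg)
  out <- list(
    decades = lapply(seq_len(nrow(cfg$decades)), function(i) {
      row <- as.list(cfg$decades[i, ])
      row$decade <- as.character(row$decade)
      row
    }),
    class_effects = list(
      class_proportions = as.list(cfg$class_effects$class_proportions),
      fertility_multiplier_nonlower =
        cfg$class_effects$fertility_multiplier_nonlower,
      survival_logit_shift_nonlower =
        cfg$class_effects$survival_logit_shift_nonlower
    ),
    missingness = list(
      survival = as.list(setNames(cfg$missingness$survival,
                                  c("complete", "incomplete", "missing"))),
      breeding = as.list(setNames(cfg$missingness$breeding,
                                  c("complete", "incomplete", "missing"))),
      tracking_prob = cfg$missingness$tracking_prob
    ),
    survive45_prob = cfg$survive45_prob,
    seed = cfg$seed
  )
  yaml::write_yaml(out, path)
  invisible(cfg)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  decades <- dplyr::bind_rows(lapply(raw$decades, tibble::as_tibble))
  decades$decade <- factor(decades$decade, levels = decade_labels())
  cfg <- list(
    decades = decades,
    class_effects = list(
      class_proportions = unlist(raw$class_effects$class_proportions),
      fertility_multiplier_nonlower =
        raw$class_effects$fertility_multiplier_nonlower,
      survival_logit_shift_nonlower =
        raw$class_effects$survival_logit_shift_nonlower
    ),
    missingness = list(
      survival = unlist(raw$missingness$survival),
      breeding = unlist(raw$missingness$breeding),
      tracking_prob = raw$missingness$tracking_prob
    ),
    survive45_prob = raw$survive45_prob,
    seed = as.integer(raw$seed)
  )
  class(cfg) <- "breedfail_simconfig"
  validate_simconfig(cfg)
}
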