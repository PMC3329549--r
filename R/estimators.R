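#' Per-mother weighted trait estimates
#'
#' The unit of analysis is a per-mother `(value, weight)` pair. For a
#' mother with lifetime fertility `q`:
#'
#' * **survival** — value is the proportion survived to 15 among offspring
#'   with known survival status; weight is the proportion of her `q`
#'   offspring whose status is known.
#' * **breeding** — value is the proportion who bred among offspring with
#'   known breeding census; weight is the proportion with a known census.
#' * **lrs** — lifetime reproductive success, `q` times the breeding value
#'   (possibly non-integer), with the breeding weight.
#' * **failure** — breeding failure indicator: 0 with weight 1 as soon as
#'   one offspring is known to have survived (success is then certain);
#'   otherwise 1 with weight equal to the proportion of offspring with
#'   known survival status.
#'
#' Mothers whose relevant statuses are all unknown get weight 0 and an
#' `NA` value: they are retained and flagged, not dropped, so the
#' "missing records" accounting stays auditable; weighted summaries and
#' fits exclude them through the zero weight.
#'
#' @param cohort A `breedfail_cohort`.
#' @return A tibble with one row per mother per response: `mother_id`,
#'   `response` (`survival`, `breeding`, `lrs`, `failure`), `value`,
#'   `weight`, `excluded` (`weight == 0`).
#' @export
trait_estimates <- function(cohort) {
  stopifnot(inherits(cohort, "breedfail_cohort"))
  per <- cohort$offspring |>
    dplyr::group_by(.data$mother_id) |>
    dplyr::summarise(
      q = dplyr::n(),
      s_known = sum(.data$survival15 != "unknown"),
      s_surv = sum(.data$survival15 == "survived"),
      b_known = sum(.data$breeding != "unknown"),
      b_bred = sum(.data$breeding == "bred"),
      .groups = "drop"
    )

  survival <- per |>
    dplyr::transmute(
      .data$mother_id,
      response = "survival",
      value = ifelse(.data$s_known > 0, .data$s_surv / .data$s_known,
                     NA_real_),
      weight = .data$s_known / .data$q
    )
  breeding <- per |>
    dplyr::transmute(
      .data$mother_id,
      response = "breeding",
      value = ifelse(.data$b_known > 0, .data$b_bred / .data$b_known,
                     NA_real_),
      weight = .data$b_known / .data$q
    )
  lrs <- per |>
    dplyr::transmute(
      .data$mother_id,
      response = "lrs",
      value = ifelse(.data$b_known > 0,
                     .data$q * .data$b_bred / .data$b_known, NA_real_),
      weight = .data$b_known / .data$q
    )
  failure <- per |>
    dplyr::transmute(
      .data$mother_id,
      response = "failure",
      value = dplyr::case_when(
        .data$s_surv > 0 ~ 0,
        .data$s_known > 0 ~ 1,
        TRUE ~ NA_real_
      ),
      weight = dplyr::case_when(
        .data$s_surv > 0 ~ 1,
        TRUE ~ .data$s_known / .data$q
      )
    )

  dplyr::bind_rows(survival, breeding, lrs, failure) |>
    dplyr::mutate(excluded = .data$weight == 0)
}

#' Weighted mean of trait estimates
#'
#' `sum(w * v) / sum(w)` over estimates with positive weight. Errors if
#' every weight is zero (nothing to estimate).
#'
#' @param value,weight Numeric vectors.
#' @return The weighted mean.
#' @export
weighted_mean_est <- function(value, weight) {
  keep <- weight > 0 & !is.na(value)
  if (!any(keep)) {
    abort("all weights are zero: weighted mean undefined",
      class = "breedfail_undefined_mean_error"
    )
  }
  sum(weight[keep] * value[keep]) / sum(weight[keep])
}

#' Standard error of the weighted mean
#'
#' Uses the Kish effective sample size `n_eff = (sum w)^2 / sum(w^2)`:
#' `SE = sqrt( sum(w (v - vbar)^2) / sum(w) / (n_eff - 1) )`. Reduces to
#' the classical SE of the mean when all weights are 1, and is invariant
#' to a uniform rescaling of the weights.
#'
#' @param value,weight Numeric vectors.
#' @return The standard error.
#' @export
weighted_se_est <- function(value, weight) {
  keep <- weight > 0 & !is.na(value)
  w <- weight[keep]
  v <- value[keep]
  n_eff <- sum(w)^2 / sum(w^2)
  if (length(v) < 2L || n_eff <= 1) {
    abort("effective sample size <= 1: weighted SE undefined",
      class = "breedfail_undefined_se_error"
    )
  }
  vbar <- sum(w * v) / sum(w)
  sqrt(sum(w * (v - vbar)^2) / sum(w) / (n_eff - 1))
}

summary_cell <- function(value, weight = NULL) {
  if (is.null(weight)) weight <- rep(1, length(value))
  keep <- weight > 0 & !is.na(value)
  if (sum(keep) == 0L) {
    return(list(mean = NA_real_, se = NA_real_, wsum = 0))
  }
  m <- weighted_mean_est(value, weight)
  s <- if (sum(keep) >= 2L) weighted_se_est(value, weight) else NA_real_
  list(mean = m, se = s, wsum = sum(weight[keep]))
}

#' Decade-stratified cohort summary
#'
#' Reproduces the layout of the reference decade table: one row per
#' first-birth decade plus a pooled `Total` row, with mean and standard
#' error of AFR, ALR, reproductive span, mean birth interval and fertility
#' (unweighted) and of offspring survival, breeding probability and
#' lifetime reproductive success (weighted by the record-completeness
#' weights, Kish SE). The total row pools decade contributions — sample
#' sizes for unweighted traits, weight sums for weighted traits — which
#' equals computing directly on the pooled mothers.
#'
#' @param traits Output of [derive_traits()].
#' @param estimates Output of [trait_estimates()].
#' @return A tibble with columns `decade`, `n`, then `<trait>_mean` and
#'   `<trait>_se` for each trait column.
#' @export
decade_summary <- function(traits, estimates) {
  wide <- estimates |>
    dplyr::select("mother_id", "response", "value", "weight") |>
    tidyr::pivot_wider(
      names_from = "response",
      values_from = c("value", "weight")
    )
  df <- dplyr::left_join(traits, wide, by = "mother_id")

  one_block <- function(d, label) {
    tibble::tibble(
      decade = label,
      n = nrow(d),
      afr_mean = summary_cell(d$afr)$mean,
      afr_se = summary_cell(d$afr)$se,
      alr_mean = summary_cell(d$alr)$mean,
      alr_se = summary_cell(d$alr)$se,
      span_mean = summary_cell(d$span)$mean,
      span_se = summary_cell(d$span)$se,
      bi_mean = summary_cell(d$mean_birth_interval)$mean,
      bi_se = summary_cell(d$mean_birth_interval)$se,
      fertility_mean = summary_cell(d$fertility)$mean,
      fertility_se = summary_cell(d$fertility)$se,
      survival_mean = summary_cell(d$value_survival, d$weight_survival)$mean,
      survival_se = summary_cell(d$value_survival, d$weight_survival)$se,
      breeding_mean = summary_cell(d$value_breeding, d$weight_breeding)$mean,
      breeding_se = summary_cell(d$value_breeding, d$weight_breeding)$se,
      lrs_mean = summary_cell(d$value_lrs, d$weight_lrs)$mean,
      lrs_se = summary_cell(d$value_lrs, d$weight_lrs)$se
    )
  }

  rows <- lapply(decade_labels(), function(lab) {
    d <- df[df$decade == lab, , drop = FALSE]
    if (nrow(d) == 0L) {
      tibble::tibble(decade = lab, n = 0L)
    } else {
      one_block(d, lab)
    }
  })
  dplyr::bind_rows(dplyr::bind_rows(rows), one_block(df, "Total"))
}

#' Time-trend correlations of the cohort traits
#'
#' Pearson correlation of each trait with the year of first birth. For
#' the weighted traits (survival, breeding, LRS) only mothers with weight
#' exactly 1 — fully tracked records — contribute, so the correlation is
#' computed on exact values; `df = n - 2`.
#'
#' @inheritParams decade_summary
#' @return A tibble with `trait`, `rho`, `t`, `df`, `p`, `n`.
#' @export
trend_correlations <- function(traits, estimates) {
  wide <- estimates |>
    dplyr::select("mother_id", "response", "value", "weight") |>
    tidyr::pivot_wider(
      names_from = "response",
      values_from = c("value", "weight")
    )
  df <- dplyr::left_join(traits, wide, by = "mother_id")

  plain <- list(
    afr = df$afr, alr = df$alr, span = df$span,
    mean_birth_interval = df$mean_birth_interval,
    fertility = df$fertility
  )
  weighted <- list(
    survival = list(v = df$value_survival, w = df$weight_survival),
    breeding = list(v = df$value_breeding, w = df$weight_breeding),
    lrs = list(v = df$value_lrs, w = df$weight_lrs)
  )

  one <- function(trait, x, y) {
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3L) {
      abort(paste0("fewer than 3 usable mothers for trait ", trait),
        class = "breedfail_undefined_correlation_error"
      )
    }
    ct <- pearson_test(x[keep], y[keep])
    tibble::tibble(trait = trait, rho = ct$rho, t = ct$t, df = ct$df,
                   p = ct$p, n = sum(keep))
  }

  out <- lapply(names(plain), function(tr) {
    one(tr, plain[[tr]], df$first_birth_year)
  })
  out_w <- lapply(names(weighted), function(tr) {
    v <- weighted[[tr]]$v
    w <- weighted[[tr]]$w
    keep <- !is.na(w) & w == 1
    one(tr, ifelse(keep, v, NA_real_), df$first_birth_year)
  })
  dplyr::bind_rows(c(out, out_w))
}
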