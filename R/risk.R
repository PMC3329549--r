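#' Maternal risk of breeding failure
#'
#' The probability that none of a mother's `q` offspring survives to
#' adulthood when each survives independently with probability `s`:
#' `(1 - s)^q`. With `q = 0` the risk is 1 (no offspring, failure
#' certain); it is strictly decreasing in both `q` and `s`.
#'
#' @param q Offspring counts (non-negative integers, vectorized).
#' @param s Offspring survival probabilities in `[0, 1]` (vectorized).
#' @return Failure probabilities in `[0, 1]`.
#' @examples
#' failure_risk(3, 0.73) # 0.27^3
#' @export
failure_risk <- function(q, s) {
  stopifnot(all(q >= 0), all(q == floor(q)), all(s >= 0), all(s <= 1))
  (1 - s)^q
}

#' Required fertility for a given failure-risk ceiling
#'
#' The smallest family size `q >= 1` whose breeding-failure risk
#' `(1 - s)^q` does not exceed `alpha`. Satisfies the bracketing
#' `(1-s)^q <= alpha < (1-s)^(q-1)` whenever `q >= 2`.
#'
#' @param s Offspring survival probability in `(0, 1]` (vectorized).
#' @param alpha Risk ceiling in `(0, 1)`; default 0.05.
#' @return Integer fertilities.
#' @examples
#' required_fertility(0.73) # 3 children at the 5% ceiling
#' @export
required_fertility <- function(s, alpha = 0.05) {
  stopifnot(all(s <= 1), all(alpha > 0), all(alpha < 1))
  if (any(s <= 0)) {
    abort("s = 0: no finite fertility attains the risk ceiling",
      class = "breedfail_unattainable_risk_error"
    )
  }
  k <- max(length(s), length(alpha))
  s <- rep_len(s, k)
  alpha <- rep_len(alpha, k)
  q <- ifelse(s == 1, 1, ceiling(log(alpha) / log(1 - s)))
  # guard against floating-point edge at the boundary
  q <- pmax(as.integer(q), 1L)
  over <- failure_risk(q, s) > alpha
  q[over] <- q[over] + 1L
  down <- q > 1L & failure_risk(q - 1L, s) <= alpha
  q[down] <- q[down] - 1L
  q
}

#' Expected breeding-failure proportion under zero-truncated Poisson fertility
#'
#' Cohort-level expected failure `E[(1-s)^q | q >= 1]` when fertility
#' follows a zero-truncated Poisson with mean `mu`:
#' `(exp(-lambda * s) - exp(-lambda)) / (1 - exp(-lambda))` with `lambda`
#' solving `lambda / (1 - exp(-lambda)) = mu`.
#'
#' @param mu Mean fertility, `>= 1`.
#' @param s Offspring survival probability in `(0, 1]`.
#' @return Expected failure proportion.
#' @export
cohort_expected_failure <- function(mu, s) {
  stopifnot(all(s > 0), all(s <= 1))
  if (any(mu < 1)) {
    abort("mean fertility must be >= 1",
      class = "breedfail_config_error"
    )
  }
  lam <- ztp_lambda(mu)
  ifelse(lam <= 0, 1 - s,
         (exp(-lam * s) - exp(-lam)) / (1 - exp(-lam)))
}

#' Per-decade risk table
#'
#' Breeding-failure risk summary for each decade of a calibration: the
#' analytic risk at the decade's mean fertility, the cohort-level expected
#' failure under the zero-truncated Poisson fertility law, and the
#' required fertility at the `alpha` ceiling.
#'
#' @param config A `breedfail_simconfig`.
#' @param alpha Risk ceiling; default 0.05.
#' @return A tibble with one row per decade.
#' @export
risk_table <- function(config, alpha = 0.05) {
  d <- config$decades
  tibble::tibble(
    decade = d$decade,
    fertility_mean = d$fertility_mean,
    survival_prob = d$survival_prob,
    risk_at_mean_fertility = failure_risk(round(d$fertility_mean),
                                          d$survival_prob),
    expected_failure = cohort_expected_failure(d$fertility_mean,
                                               d$survival_prob),
    required_fertility = required_fertility(d$survival_prob, alpha),
    alpha = alpha
  )
}
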