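logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Zero-truncated Poisson rate for a given mean
#'
#' Solves `lambda / (1 - exp(-lambda)) = mu` (vectorized Newton iteration).
#' The zero-truncated Poisson is the fertility law of the generator: every
#' mother has at least one child, and `mu` is the mean family size.
#'
#' @param mu Target means, all `>= 1`. A mean of exactly 1 corresponds to
#'   the degenerate limit `lambda = 0` (fertility always 1).
#' @return Rates `lambda >= 0` of the underlying Poisson.
#' @export
ztp_lambda <- function(mu) {
  if (any(mu < 1)) {
    abort("zero-truncated Poisson mean must be >= 1",
      class = "breedfail_config_error"
    )
  }
  lam <- pmax(mu - 1, 1e-6)
  for (i in 1:100) {
    den <- -expm1(-lam) # 1 - e^-lam, stable for small lam
    em <- exp(-lam)
    f <- lam / den - mu
    # d/dlam [lam / (1 - e^-lam)]
    fp <- (den - lam * em) / den^2
    step <- f / fp
    lam <- pmax(lam - step, lam / 10) # damped: stay positive
    if (max(abs(step)) < 1e-12) break
  }
  lam[mu <= 1 + 1e-12] <- 0
  lam
}

#' Sample from the zero-truncated Poisson
#'
#' Exact inversion sampler: uniform draws on `(P(X = 0), 1)` pushed through
#' the Poisson quantile function.
#'
#' @param n Number of draws (ignored if `lambda` has length `n`).
#' @param lambda Poisson rates (length 1 or `n`); `lambda = 0` gives the
#'   degenerate value 1.
#' @return Integer draws `>= 1`.
#' @export
rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  out <- rep(1L, n)
  pos <- lambda > 0
  if (any(pos)) {
    p0 <- exp(-lambda[pos])
    u <- runif(sum(pos), min = p0, max = 1)
    out[pos] <- as.integer(qpois(u, lambda[pos]))
  }
  out
}

#' Closed-form mean of the zero-truncated Poisson
#' @param lambda Poisson rates.
#' @return `lambda / (1 - exp(-lambda))`, with the `lambda = 0` limit 1.
#' @keywords internal
ztp_mean <- function(lambda) {
  ifelse(lambda <= 0, 1, lambda / (1 - exp(-lambda)))
}

#' Generate a fully observed synthetic cohort
#'
#' Simulates mother and offspring tables with the statistical structure
#' assumed by the downstream analyses. Per decade: `n_mothers` mothers;
#' age at first reproduction (AFR) from a normal truncated below at 15
#' (rounded to whole years); lifetime fertility from a zero-truncated
#' Poisson whose mean is `fertility_mean` shifted by
#' `afr_fertility_slope * (AFR - afr_mean)`, multiplied by the class
#' fertility effect and floored at 1; offspring birth years start at the
#' first birth with subsequent gaps uniform on 1--4 whole years; offspring
#' survival to 15 is Bernoulli with log-odds
#' `logit(survival_prob) + class shift + family frailty` (frailty normal
#' with SD `frailty_sd`, shared within a family); among survivors,
#' breeding is Bernoulli with the conditional probability
#' `breeding_prob / survival_prob` (capped at 1) so that `breeding_prob`
#' is the marginal per-offspring breeding probability; offspring who died
#' before 15 are confirmed childless. The result is fully observed; use
#' [apply_missingness()] to emulate incomplete record tracking.
#'
#' @param config A `breedfail_simconfig`, e.g. [default_calibration()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A `breedfail_cohort`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_simconfig(config)
  withr::local_seed(as.integer(seed))

  pr <- config$class_effects$class_proportions
  mult <- config$class_effects$fertility_multiplier_nonlower
  shift <- config$class_effects$survival_logit_shift_nonlower
  if (mult <= 0) {
    abort("fertility multiplier must be positive",
      class = "breedfail_config_error"
    )
  }

  mother_list <- list()
  off_list <- list()
  for (i in seq_len(nrow(config$decades))) {
    d <- config$decades[i, ]
    n <- d$n_mothers
    dec_start <- as.integer(sub("s$", "", as.character(d$decade)))

    # truncated-normal AFR via inversion, min 15 years
    lo <- pnorm(15, mean = d$afr_mean, sd = d$afr_sd)
    afr <- round(qnorm(runif(n, lo, 1), mean = d$afr_mean, sd = d$afr_sd))
    afr <- pmax(afr, 15L)

    first_birth_year <- dec_start + sample.int(10L, n, replace = TRUE) - 1L
    birth_year <- as.integer(first_birth_year - afr)
    ses <- sample(ses_levels(), n, replace = TRUE, prob = pr)
    parish <- sample(c("Hiittinen", "Kustavi", "Ikaalinen"), n,
                     replace = TRUE)

    mu <- d$fertility_mean + d$afr_fertility_slope * (afr - d$afr_mean)
    mu <- mu * ifelse(ses == "lower", 1, mult)
    mu <- pmax(mu, 1)
    q <- rztpois(n, ztp_lambda(mu))

    frailty <- if (d$frailty_sd > 0) rnorm(n, 0, d$frailty_sd) else numeric(n)
    eta <- logit(d$survival_prob) +
      ifelse(ses == "lower", 0, shift) + frailty
    p_surv <- expit(eta)
    p_breed_cond <- min(d$breeding_prob / d$survival_prob, 1)

    mid <- sprintf("M%s_%04d", dec_start, seq_len(n))
    mother_list[[i]] <- tibble::tibble(
      mother_id = mid,
      parish = parish,
      ses_class = ses,
      birth_year = birth_year,
      death_year = NA_integer_,
      first_birth_year = first_birth_year
    )

    tot <- sum(q)
    momx <- rep.int(seq_len(n), q)
    # birth years: first at the first birth, then gaps uniform on 1..4
    gaps <- sample.int(4L, tot, replace = TRUE)
    ord <- sequence(q)
    gaps[ord == 1L] <- 0L
    byear <- first_birth_year[momx] +
      as.integer(unlist(lapply(split(gaps, momx), cumsum), use.names = FALSE))

    surv <- rbinom(tot, 1L, p_surv[momx]) == 1L
    breed <- rep("childless", tot)
    breed[surv] <- ifelse(rbinom(sum(surv), 1L, p_breed_cond) == 1L,
                          "bred", "childless")

    off_list[[i]] <- tibble::tibble(
      offspring_id = sprintf("%s_o%02d", mid[momx], ord),
      mother_id = mid[momx],
      birth_year = byear,
      survival15 = ifelse(surv, "survived", "died"),
      breeding = breed,
      sex = sample(c("F", "M"), tot, replace = TRUE)
    )
  }

  as_cohort(dplyr::bind_rows(mother_list), dplyr::bind_rows(off_list))
}

draw_strata <- function(n, triple, exact) {
  labels <- c("complete", "incomplete", "missing")
  if (exact) {
    # largest-remainder apportionment of n mothers to the three strata
    raw <- n * triple
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    sample(rep(labels, times = base))
  } else {
    sample(labels, n, replace = TRUE, prob = triple)
  }
}

mask_variable <- function(offspring, mothers_id, stratum, col, tracking_prob) {
  q <- tabulate(match(offspring$mother_id, mothers_id),
                nbins = length(mothers_id))
  # incomplete tracking needs >= 2 offspring: swap labels with a complete
  # q >= 2 mother, else fall back to complete
  inc1 <- which(stratum == "incomplete" & q < 2L)
  for (j in inc1) {
    cand <- which(stratum == "complete" & q >= 2L)
    if (length(cand) > 0L) {
      k <- cand[sample.int(length(cand), 1L)]
      stratum[k] <- "incomplete"
    }
    stratum[j] <- "complete"
  }

  momstr <- stratum[match(offspring$mother_id, mothers_id)]
  masked <- momstr == "missing"
  inc <- which(stratum == "incomplete")
  for (j in inc) {
    rows <- which(offspring$mother_id == mothers_id[j])
    m <- rbinom(length(rows), 1L, 1 - tracking_prob) == 1L
    # guarantee at least one observed and at least one masked
    if (all(m)) m[sample.int(length(rows), 1L)] <- FALSE
    if (!any(m)) m[sample.int(length(rows), 1L)] <- TRUE
    masked[rows[m]] <- TRUE
  }
  offspring[[col]][masked] <- "unknown"
  list(offspring = offspring, stratum = stratum)
}

#' Mask a cohort to emulate incomplete record tracking
#'
#' Assigns each mother, independently for the survival and breeding
#' variables, to a completeness stratum — complete (all offspring
#' observed), incomplete (some observed, some not), or missing (none
#' observed) — with the configured proportions, and masks statuses to
#' `"unknown"` accordingly. Masking is completely at random (MCAR): the
#' stratum draw and the per-offspring tracking draws are independent of
#' the true statuses, which is what makes the weighted estimators
#' unbiased. Within an incomplete family each offspring is masked
#' independently with probability `1 - tracking_prob`, constrained to
#' leave at least one observed and at least one masked offspring; mothers
#' with a single offspring cannot be "incomplete" and exchange stratum
#' labels with a multi-offspring complete family. The true pre-masking
#' statuses are preserved in audit columns `.survival15_true` and
#' `.breeding_true`, and the per-mother strata in `.survival_stratum` /
#' `.breeding_stratum` on the mother table.
#'
#' @param cohort A fully observed `breedfail_cohort`.
#' @param params Missingness parameters (a list with elements `survival`,
#'   `breeding` — each a (complete, incomplete, missing) probability
#'   triple — and `tracking_prob`), e.g. `default_calibration()$missingness`.
#' @param seed Integer seed.
#' @param exact If `TRUE`, stratum counts are fixed at their
#'   largest-remainder apportionment instead of multinomial draws.
#' @return The masked `breedfail_cohort`.
#' @export
apply_missingness <- function(cohort, params, seed = 1L, exact = FALSE) {
  stopifnot(inherits(cohort, "breedfail_cohort"))
  for (v in c("survival", "breeding")) {
    tri <- params[[v]]
    if (length(tri) != 3L || any(tri < 0) || abs(sum(tri) - 1) > 1e-8) {
      abort(paste0(v, " completeness proportions must sum to 1"),
        class = "breedfail_config_error"
      )
    }
  }
  withr::local_seed(as.integer(seed))

  o <- cohort$offspring
  o$.survival15_true <- o$survival15
  o$.breeding_true <- o$breeding
  ids <- cohort$mothers$mother_id
  n <- length(ids)

  s_str <- draw_strata(n, params$survival, exact)
  res <- mask_variable(o, ids, s_str, "survival15", params$tracking_prob)
  o <- res$offspring
  s_str <- res$stratum

  b_str <- draw_strata(n, params$breeding, exact)
  res <- mask_variable(o, ids, b_str, "breeding", params$tracking_prob)
  o <- res$offspring
  b_str <- res$stratum

  m <- cohort$mothers
  m$.survival_stratum <- s_str
  m$.breeding_stratum <- b_str
  out <- as_cohort(m, o)
  out
}

#' Simulate an offspring-generation breeding census
#'
#' Emulates the census used for the childlessness rate: `n` females, each
#' surviving to age 45 with probability `survive45_prob`; survivors are
#' childless with probability `childless_rate`, otherwise bred (placed on
#' the time axis by [hypothetical_first_birth_year()] when childless).
#'
#' @param n Number of females.
#' @param childless_rate Probability a survivor to 45 never has children.
#' @param survive45_prob Probability of surviving to age 45.
#' @param birth_years Optional birth years (recycled); default 1900.
#' @param seed Integer seed.
#' @return A tibble with `birth_year`, `survived45`, `breeding`,
#'   `first_birth_year` (hypothetical for the childless).
#' @export
simulate_breeding_census <- function(n, childless_rate = 0.25,
                                     survive45_prob = 0.9,
                                     birth_years = 1900L, seed = 1L) {
  stopifnot(childless_rate >= 0, childless_rate <= 1,
            survive45_prob > 0, survive45_prob <= 1)
  withr::local_seed(as.integer(seed))
  by <- rep_len(as.integer(birth_years), n)
  surv <- rbinom(n, 1L, survive45_prob) == 1L
  breeding <- ifelse(surv & rbinom(n, 1L, 1 - childless_rate) == 1L,
                     "bred", "childless")
  obs_fby <- by + sample(20:35, n, replace = TRUE)
  tibble::tibble(
    birth_year = by,
    survived45 = surv,
    breeding = breeding,
    first_birth_year = ifelse(breeding == "childless",
                              hypothetical_first_birth_year(by), obs_fby)
  )
}
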