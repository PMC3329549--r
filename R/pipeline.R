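#' Default association analyses
#'
#' The five association families over both focal covariates: fertility ~
#' AFR (Poisson); offspring survival, breeding probability and breeding
#' failure ~ fertility and ~ AFR (binomial); lifetime reproductive success
#' ~ fertility and ~ AFR (Gaussian on the Box-Cox scale).
#'
#' @return A tibble with columns `response`, `focal`, `family`,
#'   `quadratic`.
#' @export
default_analyses <- function() {
  tibble::tribble(
    ~response, ~focal, ~family, ~quadratic,
    "fertility", "afr", "poisson", TRUE,
    "survival", "fertility", "binomial", TRUE,
    "survival", "afr", "binomial", TRUE,
    "breeding", "fertility", "binomial", TRUE,
    "breeding", "afr", "binomial", TRUE,
    "lrs", "fertility", "gaussian", TRUE,
    "lrs", "afr", "gaussian", TRUE,
    "failure", "fertility", "binomial", TRUE,
    "failure", "afr", "binomial", TRUE
  )
}

#' Build the analysis table for one response/focal pair
#'
#' Joins per-mother traits and weighted estimates into a modelling frame:
#' the response value and weight, the focal covariate, its centred
#' quadratic `<focal>_sq`, decade, class and parish factors. `fertility`
#' as a response uses the raw count with weight 1 (fertility records are
#' complete); `lrs` is Box-Cox transformed (shift 1, exponent selected by
#' profile likelihood unless given). Mothers with first births in the
#' 1960s--1970s can be excluded from offspring-breeding responses
#' (`breeding`, `lrs`), whose censuses are still incomplete for those
#' decades.
#'
#' @param traits Output of [derive_traits()].
#' @param estimates Output of [trait_estimates()].
#' @param response One of `fertility`, `survival`, `breeding`, `lrs`,
#'   `failure`.
#' @param focal Focal covariate: `fertility` or `afr`.
#' @param exclude_recent_breeding Drop 1960s/1970s mothers for breeding
#'   responses (default `TRUE`).
#' @param boxcox_lambda Exponent for the `lrs` transform; `NULL` selects
#'   it by profile likelihood.
#' @return A list with `data` (the modelling frame with columns `y`,
#'   `w`, the focal columns and factors) and `boxcox` (the transform used,
#'   or `NULL`).
#' @export
build_model_frame <- function(traits, estimates, response, focal,
                              exclude_recent_breeding = TRUE,
                              boxcox_lambda = NULL) {
  stopifnot(response %in% c("fertility", "survival", "breeding", "lrs",
                            "failure"),
            focal %in% c("fertility", "afr"))
  df <- traits
  if (response == "fertility") {
    df$y <- df$fertility
    df$w <- 1
  } else {
    est <- estimates[estimates$response == response,
                     c("mother_id", "value", "weight")]
    df <- dplyr::inner_join(df, est, by = "mother_id")
    df$y <- df$value
    df$w <- df$weight
  }
  if (response %in% c("breeding", "lrs") && exclude_recent_breeding) {
    df <- df[!df$decade %in% c("1960s", "1970s"), , drop = FALSE]
    df$decade <- droplevels(df$decade)
  }
  df <- df[df$w > 0 & !is.na(df$y), , drop = FALSE]

  bc <- NULL
  if (response == "lrs") {
    lambda <- boxcox_lambda %||% boxcox_select(df$y, shift = 1)$lambda
    bc <- list(lambda = lambda, shift = 1)
    df$y <- boxcox_transform(df$y, lambda, shift = 1)
  }

  df$decade <- factor(df$decade)
  df$ses_class <- factor(df$ses_class, levels = ses_levels())
  df$parish <- factor(df$parish)
  df[[focal]] <- as.numeric(df[[focal]])
  df[[paste0(focal, "_sq")]] <- center(df[[focal]])^2
  list(data = df, boxcox = bc)
}

#' Run one decade-stratified association analysis
#'
#' Builds the maximum model for a response/focal pair (focal covariate,
#' optional centred quadratic, decade, class, their interactions, parish
#' as additive control), simplifies it by backward stepwise
#' likelihood-ratio tests, and applies the class-collapsing rule whenever
#' `ses_class` is retained.
#'
#' @inheritParams build_model_frame
#' @param family GLM family for the response (see [fit_weighted_glm()]).
#' @param quadratic Include the centred quadratic of the focal covariate.
#' @param alpha Stepwise retention threshold.
#' @return A list with the model frame metadata, stepwise result,
#'   class-collapse decision (if applicable) and the final fit.
#' @export
run_association <- function(traits, estimates, response, focal,
                            family = "binomial", quadratic = TRUE,
                            alpha = 0.05, exclude_recent_breeding = TRUE,
                            boxcox_lambda = NULL) {
  mf <- build_model_frame(traits, estimates, response, focal,
                          exclude_recent_breeding, boxcox_lambda)
  d <- mf$data
  use_decade <- nlevels(d$decade) > 1L
  factors <- c(if (use_decade) "decade", "ses_class")
  terms <- max_model_terms(focal, quadratic = quadratic, factors = factors)
  step <- backward_stepwise(d, "y", terms, family = family, weights = d$w,
                            alpha = alpha)
  collapse <- NULL
  final_fit <- step$fit
  final_terms <- step$terms
  has_ses_inter <- any(vapply(step$terms, function(t) {
    t != "ses_class" && "ses_class" %in% term_components(t)
  }, logical(1)))
  if ("ses_class" %in% step$terms && !has_ses_inter) {
    collapse <- ses_collapse_check(d, "y", step$terms, family = family,
                                   weights = d$w, alpha = alpha)
    if (collapse$decision == "collapsed") {
      final_fit <- collapse$fit_collapsed
      final_terms <- replace(step$terms, step$terms == "ses_class",
                             "ses_collapsed")
    }
  }
  list(
    response = response, focal = focal, family = family,
    boxcox = mf$boxcox, n = nrow(d),
    terms_max = terms, terms_min = final_terms,
    elimination = step$log,
    collapse = if (!is.null(collapse)) collapse$decision else NA_character_,
    fit = final_fit
  )
}

analysis_to_json <- function(res) {
  list(
    response = res$response,
    focal = res$focal,
    family = res$family,
    n = res$n,
    boxcox = res$boxcox,
    terms_max = res$terms_max,
    terms_min = res$terms_min,
    ses_collapse = res$collapse,
    elimination = res$elimination,
    coefficients = res$fit$coefficients,
    logLik = res$fit$logLik,
    df = res$fit$df,
    converged = res$fit$converged
  )
}

#' Run the full simulate-to-models pipeline
#'
#' End-to-end driver: generate (or read) a cohort, apply record masking,
#' derive traits and weighted estimates, write the decade summary, the
#' risk table and one model JSON per association analysis, with a run log
#' stamped by the configuration hash and seed.
#'
#' @param config A `breedfail_simconfig` (cohort simulated), or `NULL`
#'   with `mother_path`/`offspring_path` given (cohort read from CSV).
#' @param out_dir Output directory, created if needed.
#' @param seed Integer seed for generation and masking.
#' @param analyses Tibble of analyses (`response`, `focal`, `family`,
#'   `quadratic`); default [default_analyses()] — the five association
#'   families over both focal covariates.
#' @param exclude_recent_breeding Drop 1960s/1970s mothers from breeding
#'   and LRS analyses.
#' @param mother_path,offspring_path Input CSVs when `config` is `NULL`.
#' @param mask If `TRUE` (default, simulated cohorts only) apply the
#'   configured missingness.
#' @return Invisibly, a list with the cohort, traits, estimates, summary,
#'   risk table and analysis results.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = 1L,
                         analyses = default_analyses(),
                         exclude_recent_breeding = TRUE,
                         mother_path = NULL, offspring_path = NULL,
                         mask = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }

  stamp <- list(seed = as.integer(seed),
                config_hash = rlang::hash(config %||% list(mother_path,
                                                           offspring_path)))
  say("run: seed ", stamp$seed, " config ", stamp$config_hash)

  if (!is.null(config)) {
    say("stage simulate: generating cohort")
    cohort <- generate_cohort(config, seed = seed)
    if (mask) {
      say("stage mask: applying record missingness")
      cohort <- apply_missingness(cohort, config$missingness,
                                  seed = seed + 1L)
      write_truth(cohort, file.path(out_dir, "truth.csv"))
    }
    write_cohort(cohort, file.path(out_dir, "mothers.csv"),
                 file.path(out_dir, "offspring.csv"))
  } else {
    say("stage read: loading cohort from CSV")
    cohort <- read_cohort(mother_path, offspring_path)
  }

  say("stage estimate: deriving traits and weighted estimates")
  traits <- derive_traits(cohort)
  estimates <- trait_estimates(cohort)
  readr::write_tsv(estimates, file.path(out_dir, "estimates.tsv"))

  say("stage summarize: decade summary")
  summ <- decade_summary(traits, estimates)
  readr::write_tsv(summ, file.path(out_dir, "table1.tsv"))

  risk <- NULL
  if (!is.null(config)) {
    say("stage risk: per-decade failure risk")
    risk <- risk_table(config)
    readr::write_tsv(risk, file.path(out_dir, "risk.tsv"))
  }

  results <- list()
  for (i in seq_len(nrow(analyses))) {
    a <- analyses[i, ]
    tag <- paste0(a$response, "_by_", a$focal)
    say("stage analyze: ", tag, " (", a$family, ")")
    res <- tryCatch(
      run_association(traits, estimates, a$response, a$focal,
                      family = a$family, quadratic = a$quadratic,
                      exclude_recent_breeding = exclude_recent_breeding),
      error = function(e) {
        abort(paste0("stage analyze(", tag, ") failed: ",
                     conditionMessage(e)),
          class = "breedfail_stage_error"
        )
      }
    )
    for (j in seq_len(nrow(res$elimination))) {
      say("  eliminated ", res$elimination$term[j],
          " chi2=", format(res$elimination$chi2[j], digits = 4),
          " df=", res$elimination$df[j],
          " p=", format(res$elimination$p[j], digits = 3))
    }
    out <- c(stamp, analysis_to_json(res))
    jsonlite::write_json(out, file.path(out_dir, "models",
                                        paste0(tag, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results[[tag]] <- res
  }
  say("done")

  invisible(list(cohort = cohort, traits = traits, estimates = estimates,
                 summary = summ, risk = risk, analyses = results,
                 stamp = stamp))
}
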