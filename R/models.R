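#' Pearson correlation test
#'
#' Sample Pearson coefficient with the exact t statistic
#' `t = rho * sqrt(n - 2) / sqrt(1 - rho^2)` and two-sided p-value on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, non-constant.
#' @return A list with `rho`, `t`, `df`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    abort("need at least 3 paired observations",
      class = "breedfail_undefined_correlation_error"
    )
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant input: correlation undefined",
      class = "breedfail_undefined_correlation_error"
    )
  }
  rho <- cor(x, y)
  df <- n - 2L
  t <- pearson_t_from_rho(rho, df)
  list(rho = rho, t = t, df = df,
       p = 2 * pt(-abs(t), df), n = n)
}

#' t statistic implied by a correlation coefficient
#'
#' Recovers `t = rho * sqrt(df) / sqrt(1 - rho^2)` from a (possibly
#' rounded, e.g. printed) correlation and its degrees of freedom; infinite
#' when `|rho| = 1`.
#'
#' @param rho Pearson coefficient in `[-1, 1]`.
#' @param df Degrees of freedom (`n - 2`).
#' @return The t statistic.
#' @export
pearson_t_from_rho <- function(rho, df) {
  stopifnot(all(abs(rho) <= 1), all(df >= 1))
  ifelse(abs(rho) == 1, sign(rho) * Inf,
         rho * sqrt(df) / sqrt(1 - rho^2))
}

#' Centre a covariate at its mean
#'
#' Quadratic model terms are computed on mean-centred covariates, which
#' decorrelates them from the linear term without changing fitted values.
#'
#' @param x Numeric vector.
#' @return `x - mean(x)` (NAs ignored in the mean).
#' @export
center <- function(x) {
  stopifnot(length(x) > 0)
  x - mean(x, na.rm = TRUE)
}

#' Box-Cox power transformation
#'
#' `(y^lambda - 1) / lambda` for `lambda != 0` and `log(y)` at
#' `lambda = 0` (the continuous limit), applied to `y + shift`.
#'
#' @param y Numeric vector; `y + shift` must be positive.
#' @param lambda Transform exponent.
#' @param shift Constant added before transforming (default 0). Lifetime
#'   reproductive success can be 0, so it is transformed with `shift = 1`.
#' @return The transformed vector.
#' @export
boxcox_transform <- function(y, lambda, shift = 0) {
  z <- y + shift
  bad <- which(!is.na(z) & z <= 0)
  if (length(bad) > 0L) {
    abort(
      paste0("non-positive values after shift at row(s): ",
             paste(head(bad, 10L), collapse = ", ")),
      class = "breedfail_domain_error"
    )
  }
  if (lambda == 0) log(z) else (z^lambda - 1) / lambda
}

#' Select a Box-Cox exponent by profile likelihood
#'
#' Maximizes the profile Gaussian log-likelihood
#' `-n/2 log(sigma^2(lambda)) + (lambda - 1) * sum(log(y + shift))` over a
#' grid of exponents (default -2 to 2 in steps of 0.01), for an
#' intercept-only model.
#'
#' @inheritParams boxcox_transform
#' @param grid Candidate exponents.
#' @return A list with `lambda` (the maximizer), `shift`, and `profile`
#'   (a tibble of `lambda`, `loglik`).
#' @export
boxcox_select <- function(y, shift = 0, grid = seq(-2, 2, by = 0.01)) {
  y <- y[!is.na(y)]
  n <- length(y)
  slog <- sum(log(y + shift))
  ll <- vapply(grid, function(l) {
    z <- boxcox_transform(y, l, shift)
    s2 <- mean((z - mean(z))^2)
    -n / 2 * log(s2) + (l - 1) * slog
  }, numeric(1))
  list(
    lambda = grid[which.max(ll)],
    shift = shift,
    profile = tibble::tibble(lambda = grid, loglik = ll)
  )
}

glm_family_funs <- function(family) {
  switch(family,
    binomial = list(
      linkinv = expit,
      eta0 = function(y, w) logit(pmin(pmax((w * y + 0.25) / (w + 0.5),
                                            0.02), 0.98)),
      irls_w = function(mu, w) w * mu * (1 - mu),
      z = function(eta, y, mu) eta + (y - mu) / (mu * (1 - mu)),
      loglik = function(y, mu, w) sum(w * (y * log(mu) +
                                           (1 - y) * log(1 - mu)))
    ),
    poisson = list(
      linkinv = exp,
      eta0 = function(y, w) log(y + 0.1),
      irls_w = function(mu, w) w * mu,
      z = function(eta, y, mu) eta + (y - mu) / mu,
      loglik = function(y, mu, w) sum(w * (y * log(mu) - mu -
                                           lgamma(y + 1)))
    ),
    abort(paste0("unsupported family: ", family),
      class = "breedfail_config_error"
    )
  )
}

#' Fit a weighted generalized linear model
#'
#' Maximizes the weight-multiplied log-likelihood
#' `sum_i w_i * log f(y_i | x_i, beta)` by iteratively reweighted least
#' squares (IRLS). The weights are the record-completeness weights of the
#' trait estimators — probabilities of a fully informative record, in
#' `(0, 1]` — which downweight mothers whose response value is itself an
#' estimate from partial offspring tracking. Supported families:
#' `binomial` (logit link; the response may be a fractional proportion),
#' `poisson` (log link) and `gaussian` (identity; dispersion estimated).
#' Convergence when the largest coefficient change drops below `1e-8`,
#' with at most 100 iterations (non-convergence is flagged, not hidden).
#'
#' @param formula Model formula; factor covariates use treatment contrasts.
#' @param data A data frame.
#' @param family `"binomial"`, `"poisson"` or `"gaussian"`.
#' @param weights Numeric vector of per-row weights in `[0, 1]`; rows with
#'   zero weight or missing response are excluded from the fit.
#' @return A `breedfail_fit`: coefficient table (estimate, SE, Wald z or
#'   t, p), `logLik`, `df` (estimated parameters, + 1 for the Gaussian
#'   scale), `n`, `converged`, `dispersion`.
#' @export
fit_weighted_glm <- function(formula, data, family = "binomial",
                             weights = NULL) {
  family <- match.arg(family, c("binomial", "poisson", "gaussian"))
  w <- weights %||% rep(1, nrow(data))
  if (length(w) != nrow(data)) {
    abort("weights must have one entry per data row",
      class = "breedfail_config_error"
    )
  }
  if (any(w < 0 | w > 1, na.rm = TRUE)) {
    abort("weights must lie in [0, 1]", class = "breedfail_config_error")
  }
  vars <- intersect(all.vars(formula), names(data))
  keep <- stats::complete.cases(data[vars]) & !is.na(w) & w > 0
  data <- data[keep, , drop = FALSE]
  w <- w[keep]
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- model.matrix(stats::terms(mf), mf)
  n <- length(y)
  p <- ncol(X)

  if (qr(X)$rank < p) {
    abort("design matrix is rank deficient after dropping reference levels",
      class = "breedfail_fit_error"
    )
  }

  if (family == "gaussian") {
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    mu <- drop(X %*% beta)
    rss_w <- sum(w * (y - mu)^2)
    sigma2_ml <- rss_w / sum(w)
    ll <- -0.5 * sum(w) * (log(2 * pi * sigma2_ml) + 1)
    dispersion <- rss_w / (n - p)
    cov <- dispersion * solve(crossprod(X, X * w))
    se <- sqrt(diag(cov))
    stat <- beta / se
    pv <- 2 * pt(-abs(stat), df = n - p)
    converged <- TRUE
    iter <- 0L
    stat_label <- "t"
    df_model <- p + 1L
  } else {
    ff <- glm_family_funs(family)
    eta <- ff$eta0(y, w)
    beta <- rep(0, p)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      mu <- ff$linkinv(eta)
      mu <- pmin(pmax(mu, 1e-10), if (family == "binomial") 1 - 1e-10 else
        Inf)
      W <- ff$irls_w(mu, w)
      z <- ff$z(eta, y, mu)
      fit <- stats::lm.wfit(X, z, W)
      beta_new <- fit$coefficients
      delta <- max(abs(beta_new - beta))
      beta <- beta_new
      eta <- drop(X %*% beta)
      if (delta < 1e-8) {
        converged <- TRUE
        break
      }
      if (iter >= 100L) break
    }
    mu <- ff$linkinv(eta)
    mu <- pmin(pmax(mu, 1e-10), if (family == "binomial") 1 - 1e-10 else Inf)
    ll <- ff$loglik(y, mu, w)
    W <- ff$irls_w(mu, w)
    XtWX <- crossprod(X, X * W)
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov)) {
      # quasi-separation: some cells fitted at the boundary; the Wald SEs
      # are stabilized (the likelihood and LRTs are unaffected)
      warn("ill-conditioned information matrix (separation?); SEs stabilized")
      cov <- solve(XtWX + diag(1e-8 * max(diag(XtWX)), ncol(XtWX)))
      converged <- FALSE
    }
    se <- sqrt(pmax(diag(cov), 0))
    stat <- beta / se
    pv <- 2 * pnorm(-abs(stat))
    dispersion <- 1
    stat_label <- "z"
    df_model <- p
  }

  structure(
    list(
      coefficients = tibble::tibble(
        term = colnames(X),
        estimate = unname(beta),
        se = unname(se),
        statistic = unname(stat),
        p = unname(pv)
      ),
      stat_label = stat_label,
      logLik = ll,
      df = df_model,
      n = n,
      sum_w = sum(w),
      converged = converged,
      iterations = iter,
      dispersion = dispersion,
      family = family,
      formula = formula
    ),
    class = "breedfail_fit"
  )
}

#' @export
print.breedfail_fit <- function(x, ...) {
  cat("<breedfail_fit> ", x$family, " weighted GLM, n = ", x$n,
      ", logLik = ", format(x$logLik, digits = 6),
      ", df = ", x$df,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between nested weighted fits
#'
#' `chi2 = 2 * (logLik_full - logLik_reduced)` on `df_full - df_reduced`
#' degrees of freedom, both fits on the same rows, weights and family.
#'
#' @param full,reduced `breedfail_fit` objects, `reduced` nested in `full`.
#' @return A list with `chi2`, `df`, `p`.
#' @export
lr_test <- function(full, reduced) {
  if (!identical(full$family, reduced$family) ||
      full$n != reduced$n ||
      abs(full$sum_w - reduced$sum_w) > 1e-8) {
    abort("models must be fitted to the same data, weights and family",
      class = "breedfail_protocol_error"
    )
  }
  df <- full$df - reduced$df
  if (df < 0) {
    abort("'reduced' has more parameters than 'full': not nested",
      class = "breedfail_protocol_error"
    )
  }
  chi2 <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

term_components <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  extra <- sub("_sq$", "", parts[grepl("_sq$", parts)])
  unique(c(parts, extra))
}

term_contains <- function(a, b) {
  # does term a strictly contain term b (hierarchy sense)?
  ca <- term_components(a)
  cb <- term_components(b)
  !identical(sort(ca), sort(cb)) && all(cb %in% ca)
}

#' Terms removable under marginality
#'
#' Of a set of term labels, returns those not contained in any retained
#' higher-order term: an interaction protects its constituent main
#' effects, and a quadratic `<x>_sq` protects the linear `<x>`.
#'
#' @param terms Character vector of term labels.
#' @return The removable subset.
#' @export
removable_terms <- function(terms) {
  terms[vapply(terms, function(t) {
    !any(vapply(setdiff(terms, t), term_contains, logical(1), b = t))
  }, logical(1))]
}

#' Maximum-model term set for one association analysis
#'
#' Builds the term list of a maximum model: the focal covariate (with an
#' optional centred quadratic named `<focal>_sq`), the first-birth decade,
#' socio-economic class, all interactions among them, and additive control
#' terms (parish, by default).
#'
#' @param focal Name of the focal covariate column.
#' @param quadratic Include the centred quadratic term `<focal>_sq`
#'   (the column must exist in the data, e.g. `center(x)^2`).
#' @param factors Stratification factors entering all interactions.
#' @param controls Additive control covariates kept out of interactions.
#' @return Character vector of term labels.
#' @export
max_model_terms <- function(focal, quadratic = FALSE,
                            factors = c("decade", "ses_class"),
                            controls = "parish") {
  focals <- c(focal, if (quadratic) paste0(focal, "_sq"))
  inter <- character(0)
  subsets <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, simplify = FALSE)
  }), recursive = FALSE)
  for (f in focals) {
    for (s in subsets) inter <- c(inter, paste(c(f, s), collapse = ":"))
  }
  if (length(factors) > 1L) {
    inter <- c(inter, paste(factors, collapse = ":"))
  }
  c(focals, factors, controls, inter)
}

#' Backward stepwise simplification by likelihood-ratio tests
#'
#' Starting from a maximum model, repeatedly refits and removes the least
#' significant removable term — one whose removal respects marginality (a
#' main effect is only removable once no retained interaction or
#' quadratic involves it) — while its likelihood-ratio p-value exceeds
#' `alpha`, until every removable term tests significant. Ties on the
#' p-value are broken deterministically by reverse lexicographic term
#' name, so elimination logs replay identically.
#'
#' @param data Data frame with all model columns.
#' @param response Response column name.
#' @param terms Character vector of term labels of the maximum model,
#'   e.g. from [max_model_terms()].
#' @param family GLM family (see [fit_weighted_glm()]).
#' @param weights Per-row weights.
#' @param alpha Retention threshold (default 0.05). With `alpha = 1` no
#'   term can be removed and the maximum model is returned.
#' @param protected Terms never dropped (default none).
#' @return A list with `terms` (minimum adequate model), `fit`, and
#'   `log` — a tibble of eliminated terms with their `chi2`, `df`, `p`.
#' @export
backward_stepwise <- function(data, response, terms, family = "binomial",
                              weights = NULL, alpha = 0.05,
                              protected = character(0)) {
  fit_terms <- function(tms) {
    f <- stats::reformulate(if (length(tms) == 0L) "1" else tms,
                            response = response)
    fit_weighted_glm(f, data, family = family, weights = weights)
  }
  current <- terms
  fit <- fit_terms(current)
  log_rows <- list()
  step <- 0L
  repeat {
    cands <- setdiff(removable_terms(current), protected)
    if (length(cands) == 0L) break
    tests <- lapply(cands, function(tm) {
      red <- fit_terms(setdiff(current, tm))
      c(list(term = tm, fit = red), lr_test(fit, red))
    })
    pvals <- vapply(tests, function(t) t$p, numeric(1))
    worst <- max(pvals)
    if (worst <= alpha) break
    tied <- which(abs(pvals - worst) < 1e-12)
    names_tied <- vapply(tests[tied], function(t) t$term, character(1))
    pick <- tied[order(names_tied, decreasing = TRUE)][1]
    chosen <- tests[[pick]]
    step <- step + 1L
    log_rows[[step]] <- tibble::tibble(
      step = step, term = chosen$term, chi2 = chosen$chi2,
      df = chosen$df, p = chosen$p
    )
    current <- setdiff(current, chosen$term)
    fit <- chosen$fit
  }
  list(
    terms = current,
    fit = fit,
    log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
      tibble::tibble(step = integer(), term = character(),
                     chi2 = numeric(), df = integer(), p = numeric())
  )
}

#' Socio-economic class collapsing decision
#'
#' Tests whether the three-level socio-economic classification can be
#' collapsed to lower vs non-lower (middle + upper merged): fits the model
#' with both codings and keeps three levels only when the likelihood-ratio
#' test between them is significant at `alpha`. If a class level is absent
#' from the data the collapse is automatic (with a warning).
#'
#' @param data Data frame containing `ses_class`.
#' @param response Response column name.
#' @param terms Model terms including `"ses_class"`.
#' @param family GLM family.
#' @param weights Per-row weights.
#' @param alpha Significance threshold (default 0.05).
#' @return A list with `decision` (`"three-level"` or `"collapsed"`),
#'   `lrt`, and the two fits.
#' @export
ses_collapse_check <- function(data, response, terms, family = "binomial",
                               weights = NULL, alpha = 0.05) {
  stopifnot("ses_class" %in% names(data), "ses_class" %in% terms)
  present <- intersect(ses_levels(), unique(as.character(data$ses_class)))
  data$ses_class <- factor(data$ses_class, levels = ses_levels())
  data$ses_collapsed <- factor(
    ifelse(data$ses_class == "lower", "lower", "nonlower"),
    levels = c("lower", "nonlower")
  )
  if (length(present) < 3L) {
    warn("a socio-economic class level is absent; collapsing automatically")
    terms2 <- replace(terms, terms == "ses_class", "ses_collapsed")
    f2 <- stats::reformulate(terms2, response = response)
    fit2 <- fit_weighted_glm(f2, data, family = family, weights = weights)
    return(list(decision = "collapsed", lrt = NULL, fit_three = NULL,
                fit_collapsed = fit2))
  }
  f3 <- stats::reformulate(terms, response = response)
  terms2 <- replace(terms, terms == "ses_class", "ses_collapsed")
  f2 <- stats::reformulate(terms2, response = response)
  fit3 <- fit_weighted_glm(f3, data, family = family, weights = weights)
  fit2 <- fit_weighted_glm(f2, data, family = family, weights = weights)
  lrt <- lr_test(fit3, fit2)
  list(
    decision = if (lrt$p < alpha) "three-level" else "collapsed",
    lrt = lrt,
    fit_three = fit3,
    fit_collapsed = fit2
  )
}
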