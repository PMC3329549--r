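test_that("pearson test reproduces the t identity and matches cor.test", {
  withr::local_seed(1)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  mine <- pearson_test(x, y)
  ref <- cor.test(x, y)
  expect_equal(mine$rho, unname(ref$estimate))
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
  expect_equal(mine$df, 28L)

  # perfect correlation: infinite t
  perf <- pearson_test(1:3, 2 * (1:3) + 1)
  expect_equal(perf$rho, 1)
  expect_true(is.infinite(perf$t))

  expect_error(pearson_test(rep(1, 5), rnorm(5)),
               class = "breedfail_undefined_correlation_error")
  expect_error(pearson_test(1:2, 2:3),
               class = "breedfail_undefined_correlation_error")
})

test_that("printed correlation/t pairs are internally consistent", {
  expect_lt(abs(pearson_t_from_rho(-0.39, 1945) - (-18.71)) / 18.71, 0.01)
  expect_lt(abs(pearson_t_from_rho(0.62, 1945) - 34.77) / 34.77, 0.01)
  expect_lt(abs(pearson_t_from_rho(0.85, 1945) - 70.66) / 70.66, 0.01)
})

test_that("centring behaves as a reparameterization", {
  expect_equal(center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(center(center(c(4, 8))), center(c(4, 8)))

  # fitted values of a quadratic fit are invariant to centring
  withr::local_seed(2)
  d <- data.frame(x = runif(60, 0, 10))
  d$y <- rbinom(60, 1, plogis(-1 + 0.4 * d$x - 0.03 * d$x^2))
  d$xc <- center(d$x)
  f_raw <- fit_weighted_glm(y ~ x + I(x^2), d, "binomial")
  f_cen <- fit_weighted_glm(y ~ xc + I(xc^2), d, "binomial")
  X_raw <- cbind(1, d$x, d$x^2)
  X_cen <- cbind(1, d$xc, d$xc^2)
  mu_raw <- plogis(drop(X_raw %*% f_raw$coefficients$estimate))
  mu_cen <- plogis(drop(X_cen %*% f_cen$coefficients$estimate))
  expect_lt(max(abs(mu_raw - mu_cen)), 1e-8)
  # and so is the likelihood, hence any LRT
  expect_equal(f_raw$logLik, f_cen$logLik, tolerance = 1e-10)
})

test_that("Box-Cox transform has the right limits and recovers lambda", {
  y <- c(0.5, 1, 2, 10)
  expect_equal(boxcox_transform(y, 1), y - 1)
  expect_lt(max(abs(boxcox_transform(y, 1e-6) - log(y))), 1e-4)
  expect_equal(boxcox_transform(c(0, 3), 0, shift = 1), log(c(1, 4)))
  expect_error(boxcox_transform(c(1, -2), 0.5),
               class = "breedfail_domain_error")

  withr::local_seed(3)
  y_ln <- exp(rnorm(2000))
  sel <- boxcox_select(y_ln)
  expect_lt(abs(sel$lambda), 0.1)

  # cross-check the profile maximizer against MASS::boxcox
  mass <- MASS::boxcox(y_ln ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_equal(sel$lambda, mass$x[which.max(mass$y)], tolerance = 0.011)
})

test_that("intercept-only weighted fits hit their closed forms", {
  withr::local_seed(4)
  d <- data.frame(y = runif(50), k = rpois(50, 3))
  w <- runif(50, 0.1, 1)
  wm <- sum(w * d$y) / sum(w)
  fb <- fit_weighted_glm(y ~ 1, d, "binomial", weights = w)
  expect_equal(fb$coefficients$estimate, log(wm / (1 - wm)),
               tolerance = 1e-8)
  km <- sum(w * d$k) / sum(w)
  fp <- fit_weighted_glm(k ~ 1, d, "poisson", weights = w)
  expect_equal(fp$coefficients$estimate, log(km), tolerance = 1e-8)
})

test_that("IRLS agrees with a gradient-based likelihood maximizer", {
  withr::local_seed(5)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    family <- sample(c("binomial", "poisson"), 1)
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    if (family == "binomial") {
      d$y <- rbinom(n, 2, plogis(0.3 + 0.6 * d$x1 - 0.4 * d$x2)) / 2
    } else {
      d$y <- rpois(n, exp(0.2 + 0.4 * d$x1 - 0.2 * d$x2))
    }
    w <- runif(n, 0.2, 1)
    fit <- fit_weighted_glm(y ~ x1 + x2, d, family, weights = w)
    oracle <- fit_by_optim(cbind(1, d$x1, d$x2), d$y, w, family)
    expect_lt(max(abs(fit$coefficients$estimate - oracle)), 1e-6)
  }
})

test_that("unit weights reproduce unweighted glm fits exactly", {
  withr::local_seed(6)
  n <- 120
  d <- data.frame(x = rnorm(n), g = factor(sample(letters[1:3], n, TRUE)))
  d$y <- rbinom(n, 1, plogis(0.5 * d$x + 0.8 * (d$g == "b")))
  fit <- fit_weighted_glm(y ~ x + g, d, "binomial")
  ref <- glm(y ~ x + g, data = d, family = binomial)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-7)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-7)

  d$yc <- rnorm(n, 1 + d$x)
  fg <- fit_weighted_glm(yc ~ x, d, "gaussian")
  rg <- lm(yc ~ x, data = d)
  expect_equal(fg$coefficients$estimate, unname(coef(rg)))
  expect_equal(fg$coefficients$se,
               unname(sqrt(diag(vcov(rg)))), tolerance = 1e-10)
})

test_that("degenerate designs raise fit errors", {
  d <- data.frame(y = c(0, 1, 1, 0), x = c(1, 1, 1, 1), z = c(2, 2, 2, 2))
  expect_error(fit_weighted_glm(y ~ x + z, d, "binomial"),
               class = "breedfail_fit_error")
  expect_error(
    fit_weighted_glm(y ~ x, d, "binomial", weights = c(2, 1, 1, 1)),
    class = "breedfail_config_error"
  )
})

test_that("likelihood-ratio tests behave under identity and the null", {
  withr::local_seed(7)
  n <- 80
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, 0.4)
  f1 <- fit_weighted_glm(y ~ x, d, "binomial")
  same <- lr_test(f1, f1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  f0 <- fit_weighted_glm(y ~ 1, d, "binomial")
  lt <- lr_test(f1, f0)
  expect_equal(lt$df, 1L)
  expect_gte(lt$chi2, 0)
  expect_error(lr_test(f0, f1), class = "breedfail_protocol_error")

  d2 <- d[1:40, ]
  f2 <- fit_weighted_glm(y ~ x, d2, "binomial")
  expect_error(lr_test(f2, f0), class = "breedfail_protocol_error")
})

test_that("LRT type-I error is calibrated under the null", {
  withr::local_seed(8)
  reps <- 1000
  reject <- logical(reps)
  for (r in seq_len(reps)) {
    n <- 200
    d <- data.frame(x = rnorm(n))
    d$y <- rbinom(n, 1, 0.5) # independent of x
    w <- runif(n, 0.5, 1)
    f1 <- fit_weighted_glm(y ~ x, d, "binomial", weights = w)
    f0 <- fit_weighted_glm(y ~ 1, d, "binomial", weights = w)
    reject[r] <- lr_test(f1, f0)$p < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("decade-wise failure fits are monotone decreasing in fertility", {
  cfg <- subset_decades(default_calibration(), c("1880s", "1900s"))
  cfg$decades$n_mothers <- c(3000L, 3000L)
  co <- generate_cohort(cfg, seed = 23)
  tr <- derive_traits(co)
  est <- estimate_for(co, "failure")
  df <- dplyr::inner_join(tr, est, by = "mother_id")
  for (dec in c("1880s", "1900s")) {
    sub <- df[df$decade == dec, ]
    fit <- fit_weighted_glm(value ~ fertility, sub, "binomial",
                            weights = sub$weight)
    slope <- fit$coefficients$estimate[2]
    expect_lt(slope, 0)
    pred <- plogis(fit$coefficients$estimate[1] + slope * (1:10))
    expect_true(all(diff(pred) < 0))
  }
})
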