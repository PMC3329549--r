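test_that("default calibration matches the reference cohort structure", {
  cfg <- default_calibration()
  expect_equal(sum(cfg$decades$n_mothers), 1947L)
  d80 <- cfg$decades[cfg$decades$decade == "1880s", ]
  expect_equal(d80$survival_prob, 0.73)
  expect_equal(d80$breeding_prob, 0.37)
  expect_equal(d80$fertility_mean, 5.3)
  # SD recovered from the printed standard error: 0.3 * sqrt(291)
  expect_equal(d80$afr_sd, 0.3 * sqrt(291), tolerance = 1e-12)
  expect_equal(unname(cfg$class_effects$class_proportions["lower"]),
               569 / 1947)
  expect_equal(unname(cfg$missingness$survival),
               c(0.8660, 0.1145, 0.0195))
  expect_equal(unname(cfg$missingness$breeding),
               c(0.3374, 0.4505, 0.2121))
})

test_that("simulation configs survive YAML round-trips", {
  cfg <- default_calibration(frailty_sd = 0.5, afr_fertility_slope = -0.2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$decades, cfg$decades)
  expect_equal(back$missingness$survival, cfg$missingness$survival)
  expect_equal(back$seed, cfg$seed)
})

test_that("zero-truncated Poisson tools match brute-force oracles", {
  # rate solver vs uniroot on the mean identity
  for (mu in c(1.001, 1.5, 2.1, 3.9, 5.3, 8)) {
    lam <- ztp_lambda(mu)
    oracle <- uniroot(function(l) l / (1 - exp(-l)) - mu, c(1e-9, 30),
                      tol = 1e-13)$root
    expect_equal(lam, oracle, tolerance = 1e-8)
  }
  expect_equal(ztp_lambda(1), 0)
  expect_error(ztp_lambda(0.9), class = "breedfail_config_error")

  withr::local_seed(7)
  q <- rztpois(2e5, ztp_lambda(5.3))
  expect_true(all(q >= 1))
  expect_lt(abs(mean(q) - 5.3), 3 * sd(q) / sqrt(length(q)))
  # degenerate limit: mean 1 is always one child
  expect_true(all(rztpois(100, 0) == 1L))
})

test_that("generation is deterministic given the seed", {
  cfg <- subset_decades(default_calibration(), c("1880s", "1890s"))
  a <- generate_cohort(cfg, seed = 99)
  b <- generate_cohort(cfg, seed = 99)
  expect_identical(a$mothers, b$mothers)
  expect_identical(a$offspring, b$offspring)
  c <- generate_cohort(cfg, seed = 100)
  expect_false(identical(a$offspring, c$offspring))
})

test_that("generated cohorts match their decade parameters", {
  cfg <- subset_decades(default_calibration(), "1880s")
  surv <- fert <- afr_cor <- numeric(50)
  for (r in 1:50) {
    co <- generate_cohort(cfg, seed = 300 + r)
    tr <- derive_traits(co)
    surv[r] <- mean(co$offspring$survival15 == "survived")
    fert[r] <- mean(tr$fertility)
    afr_cor[r] <- cor(tr$afr, tr$fertility)
  }
  expect_lt(abs(mean(surv) - 0.73), 3 * sd(surv) / sqrt(50))
  expect_lt(abs(mean(fert) - 5.3), 3 * sd(fert) / sqrt(50))
  # the built-in negative fertility-AFR association
  expect_true(all(afr_cor < 0))

  # conservation: offspring per mother equals the fertility trait
  co <- generate_cohort(cfg, seed = 1)
  tr <- derive_traits(co)
  counts <- table(co$offspring$mother_id)
  expect_equal(unname(c(counts[tr$mother_id])), tr$fertility)
})

test_that("marginal breeding probability tracks the calibration value", {
  cfg <- subset_decades(default_calibration(), "1880s")
  bred <- numeric(50)
  for (r in 1:50) {
    co <- generate_cohort(cfg, seed = 700 + r)
    bred[r] <- mean(co$offspring$breeding == "bred")
  }
  expect_lt(abs(mean(bred) - 0.37), 3 * sd(bred) / sqrt(50))
  # offspring dying before 15 are confirmed childless, never bred
  co <- generate_cohort(cfg, seed = 2)
  dead <- co$offspring[co$offspring$survival15 == "died", ]
  expect_true(all(dead$breeding == "childless"))
})

test_that("frailty-free failure proportions match the closed form, frailty inflates them", {
  cfg0 <- subset_decades(default_calibration(), "1880s")
  cfg0$decades$n_mothers <- 1e5L
  cfg0$decades$afr_fertility_slope <- 0 # constant ZTP mean for the oracle
  co0 <- generate_cohort(cfg0, seed = 5)
  est0 <- estimate_for(co0, "failure")
  p0 <- weighted_mean_est(est0$value, est0$weight)
  closed <- cohort_expected_failure(5.3, 0.73)
  se0 <- sqrt(closed * (1 - closed) / nrow(est0))
  expect_lt(abs(p0 - closed), 3 * se0)

  cfg1 <- cfg0
  cfg1$decades$frailty_sd <- 1
  co1 <- generate_cohort(cfg1, seed = 5)
  est1 <- estimate_for(co1, "failure")
  p1 <- weighted_mean_est(est1$value, est1$weight)
  # family-level frailty correlates sibling deaths: more whole-family losses
  expect_gt(p1, closed + 3 * se0)
})

test_that("all-complete masking is the identity", {
  co <- generate_cohort(subset_decades(default_calibration(), "1900s"),
                        seed = 3)
  params <- list(survival = c(1, 0, 0), breeding = c(1, 0, 0),
                 tracking_prob = 0.5)
  masked <- apply_missingness(co, params, seed = 4)
  expect_equal(masked$offspring$survival15, co$offspring$survival15)
  expect_equal(masked$offspring$breeding, co$offspring$breeding)
})

test_that("masking hits the configured stratum proportions and keeps an audit trail", {
  cfg <- default_calibration()
  co <- generate_cohort(cfg, seed = 8)
  masked <- apply_missingness(co, cfg$missingness, seed = 9)

  n <- nrow(masked$mothers)
  counts <- table(masked$mothers$.survival_stratum)
  expected <- c(complete = 1686, incomplete = 223, missing = 38)
  for (s in names(expected)) {
    se <- sqrt(n * cfg$missingness$survival[
      match(s, c("complete", "incomplete", "missing"))
    ] * (1 - cfg$missingness$survival[
      match(s, c("complete", "incomplete", "missing"))
    ]))
    expect_lt(abs(counts[[s]] - expected[[s]]), 4 * se)
  }

  # audit columns preserve the pre-masking truth
  expect_true(all(
    masked$offspring$.survival15_true == co$offspring$survival15
  ))
  unknowns <- masked$offspring$survival15 == "unknown"
  expect_true(any(unknowns))
  expect_true(all(masked$offspring$.survival15_true != "unknown"))

  # incomplete families have at least one observed and one masked offspring
  ids <- masked$mothers$mother_id[
    masked$mothers$.survival_stratum == "incomplete"
  ]
  per <- split(masked$offspring$survival15[
    masked$offspring$mother_id %in% ids
  ], masked$offspring$mother_id[masked$offspring$mother_id %in% ids])
  expect_true(all(vapply(per, function(s) {
    any(s == "unknown") && any(s != "unknown")
  }, logical(1))))

  # missing families are fully unknown
  mids <- masked$mothers$mother_id[
    masked$mothers$.survival_stratum == "missing"
  ]
  expect_true(all(
    masked$offspring$survival15[masked$offspring$mother_id %in% mids] ==
      "unknown"
  ))
})

test_that("exact stratification hits largest-remainder counts", {
  cfg <- default_calibration()
  co <- generate_cohort(cfg, seed = 10)
  masked <- apply_missingness(co, cfg$missingness, seed = 11, exact = TRUE)
  counts <- table(masked$mothers$.survival_stratum)
  expect_equal(counts[["complete"]], 1686L)
  expect_equal(counts[["incomplete"]], 223L)
  expect_equal(counts[["missing"]], 38L)
})

test_that("masked weighted estimates recover the generating survival rate", {
  cfg <- subset_decades(default_calibration(), "1880s")
  R <- 60
  means <- numeric(R)
  for (r in seq_len(R)) {
    co <- generate_cohort(cfg, seed = 2000 + r)
    masked <- apply_missingness(co, cfg$missingness, seed = 4000 + r)
    est <- estimate_for(masked, "survival")
    means[r] <- weighted_mean_est(est$value, est$weight)
  }
  expect_lt(abs(mean(means) - 0.73), 3 * sd(means) / sqrt(R))
})
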