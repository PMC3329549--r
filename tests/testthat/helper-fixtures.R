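# small in-code fixtures shared across test files

tiny_mothers <- function() {
  tibble::tibble(
    mother_id = c("m1", "m2"),
    parish = c("Hiittinen", "Ikaalinen"),
    ses_class = c("lower", "upper"),
    birth_year = c(1854L, 1890L),
    death_year = c(1920L, NA_integer_),
    first_birth_year = c(1880L, 1915L)
  )
}

tiny_offspring <- function() {
  tibble::tibble(
    offspring_id = c("o1", "o2", "o3", "o4", "o5"),
    mother_id = c("m1", "m1", "m1", "m2", "m2"),
    birth_year = c(1880L, 1883L, 1886L, 1915L, 1917L),
    survival15 = c("survived", "died", "unknown", "survived", "survived"),
    breeding = c("bred", "childless", "unknown", "unknown", "childless"),
    sex = c("F", "M", "unknown", "F", "M")
  )
}

tiny_cohort <- function() as_cohort(tiny_mothers(), tiny_offspring())

# the worked example: 4 offspring, 2 tracked for breeding, 1 of them bred
worked_example_cohort <- function() {
  mothers <- tibble::tibble(
    mother_id = "w1", parish = "Kustavi", ses_class = "middle",
    birth_year = 1870L, death_year = NA_integer_, first_birth_year = 1895L
  )
  offspring <- tibble::tibble(
    offspring_id = paste0("w1_o", 1:4),
    mother_id = "w1",
    birth_year = c(1895L, 1897L, 1900L, 1903L),
    survival15 = c("survived", "survived", "unknown", "unknown"),
    breeding = c("bred", "childless", "unknown", "unknown"),
    sex = c("F", "M", "F", "M")
  )
  as_cohort(mothers, offspring)
}

# one-mother cohort from explicit offspring statuses
one_mother_cohort <- function(survival15,
                              breeding = rep("unknown", length(survival15))) {
  q <- length(survival15)
  mothers <- tibble::tibble(
    mother_id = "a", parish = "Kustavi", ses_class = "lower",
    birth_year = 1860L, death_year = NA_integer_, first_birth_year = 1885L
  )
  offspring <- tibble::tibble(
    offspring_id = paste0("a_o", seq_len(q)),
    mother_id = "a",
    birth_year = 1885L + seq_len(q) - 1L,
    survival15 = survival15,
    breeding = breeding,
    sex = "unknown"
  )
  as_cohort(mothers, offspring)
}

estimate_for <- function(cohort, resp) {
  est <- trait_estimates(cohort)
  est[est$response == resp, ]
}

# weighted log-likelihood and gradient for the optim oracle (canonical links)
oracle_nll <- function(beta, X, y, w, family) {
  eta <- drop(X %*% beta)
  if (family == "binomial") {
    mu <- 1 / (1 + exp(-eta))
    -sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  } else {
    mu <- exp(eta)
    -sum(w * (y * log(mu) - mu - lgamma(y + 1)))
  }
}

oracle_grad <- function(beta, X, y, w, family) {
  eta <- drop(X %*% beta)
  mu <- if (family == "binomial") 1 / (1 + exp(-eta)) else exp(eta)
  -drop(crossprod(X, w * (y - mu)))
}

fit_by_optim <- function(X, y, w, family) {
  o <- optim(rep(0, ncol(X)), oracle_nll, oracle_grad,
             X = X, y = y, w = w, family = family,
             method = "BFGS", control = list(maxit = 2000, reltol = 1e-15))
  o$par
}
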