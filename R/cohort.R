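#' @keywords internal
decade_labels <- function() paste0(seq(1880, 1970, by = 10), "s")

ses_levels <- function() c("lower", "middle", "upper")
survival_tokens <- function() c("survived", "died", "unknown")
breeding_tokens <- function() c("bred", "childless", "unknown")
sex_tokens <- function() c("F", "M", "unknown")

#' Assign a first-birth decade label
#'
#' Mothers are stratified by the calendar decade of their first birth
#' (period analysis): 1880--1889 is `"1880s"` and so on through `"1970s"`.
#' Mothers starting reproduction outside 1880--1979 fall outside the study
#' window and raise an error.
#'
#' @param first_birth_year Integer vector of calendar years of first birth.
#' @return A factor with the ten decade levels `"1880s"` ... `"1970s"`.
#' @examples
#' assign_decade(c(1880, 1925, 1979))
#' @export
assign_decade <- function(first_birth_year) {
  bad <- !is.na(first_birth_year) &
    (first_birth_year < 1880 | first_birth_year > 1979)
  if (any(bad)) {
    abort(
      paste0(
        "first_birth_year outside the 1880-1979 study window: ",
        paste(unique(first_birth_year[bad]), collapse = ", ")
      ),
      class = "breedfail_window_error"
    )
  }
  idx <- (first_birth_year - 1880) %/% 10 + 1L
  factor(decade_labels()[idx], levels = decade_labels())
}

#' Hypothetical first-birth year for childless females
#'
#' Trend analyses that include confirmed-childless females need a first-birth
#' year to place them on the time axis; the convention used is the female's
#' own birth year plus 26 years (about the long-run mean age at first
#' reproduction). Bred females keep their observed first-birth year.
#'
#' @param birth_year Integer vector of birth years.
#' @return `birth_year + 26`.
#' @export
hypothetical_first_birth_year <- function(birth_year) {
  birth_year + 26L
}

#' Childlessness rate among survivors to age 45
#'
#' Proportion of offspring-generation females who survived to age 45 but
#' never had children of their own.
#'
#' @param census A data frame with columns `survived45` (logical) and
#'   `breeding` (`"bred"` or `"childless"`).
#' @return Proportion in `[0, 1]`.
#' @export
childlessness_rate <- function(census) {
  stopifnot(all(c("survived45", "breeding") %in% names(census)))
  surv <- census[census$survived45, , drop = FALSE]
  if (nrow(surv) == 0L) {
    abort("no survivors to age 45: childlessness rate undefined",
      class = "breedfail_undefined_rate_error"
    )
  }
  if (!all(surv$breeding %in% c("bred", "childless"))) {
    abort("breeding status must be 'bred' or 'childless' for all survivors",
      class = "breedfail_schema_error"
    )
  }
  mean(surv$breeding == "childless")
}

mother_cols <- function() {
  c("mother_id", "parish", "ses_class", "birth_year", "death_year",
    "first_birth_year")
}
offspring_cols <- function() {
  c("offspring_id", "mother_id", "birth_year", "survival15", "breeding",
    "sex")
}

check_tokens <- function(x, allowed, what) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0L) {
    abort(
      paste0("invalid ", what, " value(s): ", paste(bad, collapse = ", "),
             " (allowed: ", paste(allowed, collapse = "|"), ")"),
      class = "breedfail_schema_error"
    )
  }
  invisible(x)
}

#' Assemble and validate a linked cohort
#'
#' A cohort is a pair of tables: one row per mother and one row per
#' offspring, linked by `mother_id`. Validation enforces the schema,
#' categorical tokens, referential integrity and the life-history
#' invariants (first birth at age 12 or later; offspring born no earlier
#' than the mother's first birth; a bred offspring cannot have died before
#' age 15).
#'
#' @param mothers,offspring Data frames with the documented columns.
#' @return An object of class `breedfail_cohort`: a list with tibbles
#'   `mothers` and `offspring`.
#' @export
as_cohort <- function(mothers, offspring) {
  mothers <- tibble::as_tibble(mothers)
  offspring <- tibble::as_tibble(offspring)

  miss_m <- setdiff(mother_cols(), names(mothers))
  miss_o <- setdiff(offspring_cols(), names(offspring))
  if (length(miss_m) || length(miss_o)) {
    abort(
      paste0("missing column(s): ",
             paste(c(miss_m, miss_o), collapse = ", ")),
      class = "breedfail_schema_error"
    )
  }

  check_tokens(mothers$ses_class, ses_levels(), "ses_class")
  check_tokens(offspring$survival15, survival_tokens(), "survival15")
  check_tokens(offspring$breeding, breeding_tokens(), "breeding")
  check_tokens(offspring$sex, sex_tokens(), "sex")

  if (anyDuplicated(mothers$mother_id)) {
    abort("duplicated mother_id in mother table",
      class = "breedfail_schema_error"
    )
  }
  orphans <- setdiff(offspring$mother_id, mothers$mother_id)
  if (length(orphans) > 0L) {
    abort(
      paste0("offspring reference unknown mother_id(s): ",
             paste(head(orphans, 10L), collapse = ", ")),
      class = "breedfail_integrity_error"
    )
  }

  early <- mothers$first_birth_year < mothers$birth_year + 12L
  if (any(early)) {
    abort(
      paste0("first_birth_year before age 12 for mother(s): ",
             paste(head(mothers$mother_id[early], 10L), collapse = ", ")),
      class = "breedfail_schema_error"
    )
  }
  dead_early <- !is.na(mothers$death_year) &
    mothers$death_year < mothers$first_birth_year - 1L
  if (any(dead_early)) {
    abort(
      paste0("death_year more than a year before first birth for: ",
             paste(head(mothers$mother_id[dead_early], 10L), collapse = ", ")),
      class = "breedfail_schema_error"
    )
  }

  fby <- mothers$first_birth_year[match(offspring$mother_id,
                                        mothers$mother_id)]
  too_early <- offspring$birth_year < fby
  if (any(too_early)) {
    abort(
      paste0("offspring born before mother's first birth: ",
             paste(head(offspring$offspring_id[too_early], 10L),
                   collapse = ", ")),
      class = "breedfail_schema_error"
    )
  }

  bred_dead <- offspring$breeding == "bred" & offspring$survival15 == "died"
  if (any(bred_dead)) {
    abort(
      paste0("offspring marked bred but died before 15: ",
             paste(head(offspring$offspring_id[bred_dead], 10L),
                   collapse = ", ")),
      class = "breedfail_schema_error"
    )
  }

  structure(list(mothers = mothers, offspring = offspring),
            class = "breedfail_cohort")
}

#' @export
print.breedfail_cohort <- function(x, ...) {
  cat("<breedfail_cohort> ", nrow(x$mothers), " mothers, ",
      nrow(x$offspring), " offspring\n", sep = "")
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' Expects the documented schemas: `mothers.csv` with columns
#' `mother_id,parish,ses_class,birth_year,death_year,first_birth_year`
#' (`death_year` may be `NA`) and `offspring.csv` with
#' `offspring_id,mother_id,birth_year,survival15,breeding,sex`, where the
#' categorical columns use the explicit tokens `survived|died|unknown`,
#' `bred|childless|unknown` and `F|M|unknown`. Unknown statuses are always
#' an explicit token, never an empty cell, so missingness stays auditable.
#'
#' @param mother_path,offspring_path Paths to the two CSV files.
#' @return A validated `breedfail_cohort`.
#' @export
read_cohort <- function(mother_path, offspring_path) {
  mothers <- readr::read_csv(
    mother_path,
    col_types = readr::cols(
      mother_id = readr::col_character(),
      parish = readr::col_character(),
      ses_class = readr::col_character(),
      birth_year = readr::col_integer(),
      death_year = readr::col_integer(),
      first_birth_year = readr::col_integer()
    )
  )
  offspring <- readr::read_csv(
    offspring_path,
    col_types = readr::cols(
      offspring_id = readr::col_character(),
      mother_id = readr::col_character(),
      birth_year = readr::col_integer(),
      survival15 = readr::col_character(),
      breeding = readr::col_character(),
      sex = readr::col_character()
    )
  )
  as_cohort(mothers, offspring)
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]; audit columns (names starting with a dot,
#' e.g. the pre-masking truth kept by [apply_missingness()]) are not part
#' of the schema and are dropped. Use [write_truth()] to keep them.
#'
#' @param cohort A `breedfail_cohort`.
#' @param mother_path,offspring_path Output paths.
#' @return The cohort, invisibly.
#' @export
write_cohort <- function(cohort, mother_path, offspring_path) {
  stopifnot(inherits(cohort, "breedfail_cohort"))
  readr::write_csv(cohort$mothers[mother_cols()], mother_path, na = "NA")
  readr::write_csv(cohort$offspring[offspring_cols()], offspring_path,
                   na = "NA")
  invisible(cohort)
}

#' Write the pre-masking audit table
#'
#' After [apply_missingness()] the offspring table carries the true
#' (pre-masking) statuses in `.survival15_true` / `.breeding_true`; this
#' writes them with the offspring ids for downstream auditing.
#'
#' @param cohort A masked `breedfail_cohort`.
#' @param path Output CSV path.
#' @export
write_truth <- function(cohort, path) {
  stopifnot(inherits(cohort, "breedfail_cohort"))
  keep <- intersect(
    c("offspring_id", "mother_id", ".survival15_true", ".breeding_true"),
    names(cohort$offspring)
  )
  readr::write_csv(cohort$offspring[keep], path, na = "NA")
  invisible(cohort)
}

#' Derive per-mother life-history traits
#'
#' Computes, for each mother with at least one offspring, the traits the
#' cohort analyses work with: age at first reproduction (AFR), age at last
#' reproduction (ALR), reproductive span (ALR - AFR), lifetime fertility
#' (offspring count, q), and the mean birth interval span / (q - 1),
#' defined only when the span is positive. All ages are in whole calendar
#' years. Mothers without offspring are excluded with a warning (the
#' analyses concern mothers only).
#'
#' @param cohort A `breedfail_cohort`.
#' @return A tibble with one row per mother: `mother_id`, `decade`, `afr`,
#'   `alr`, `span`, `mean_birth_interval`, `fertility`, plus `parish`,
#'   `ses_class` and `first_birth_year` carried along for modelling.
#' @export
derive_traits <- function(cohort) {
  stopifnot(inherits(cohort, "breedfail_cohort"))
  m <- cohort$mothers
  o <- cohort$offspring

  childless <- setdiff(m$mother_id, o$mother_id)
  if (length(childless) > 0L) {
    warn(paste0(
      length(childless),
      " mother(s) without offspring excluded from trait derivation"
    ))
  }

  per <- o |>
    dplyr::group_by(.data$mother_id) |>
    dplyr::summarise(
      first_by = min(.data$birth_year),
      last_by = max(.data$birth_year),
      fertility = dplyr::n(),
      .groups = "drop"
    )

  m |>
    dplyr::inner_join(per, by = "mother_id") |>
    dplyr::mutate(
      decade = assign_decade(.data$first_birth_year),
      afr = .data$first_by - .data$birth_year,
      alr = .data$last_by - .data$birth_year,
      span = .data$alr - .data$afr,
      mean_birth_interval = dplyr::if_else(
        .data$span > 0,
        .data$span / (.data$fertility - 1),
        NA_real_
      )
    ) |>
    dplyr::select(
      "mother_id", "decade", "afr", "alr", "span",
      "mean_birth_interval", "fertility",
      "parish", "ses_class", "first_birth_year"
    )
}
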