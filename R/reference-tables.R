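# Packaged copies of published pediatric ED reference tables: heart-rate and
# respiratory-rate centiles for 40 age categories (24 monthly + 16 yearly)
# and the age-group encounter frequencies of the source cohort.

#' Published reference centile table
#'
#' Returns the packaged age-by-centile reference table for a vital sign:
#' 40 age rows (monthly under 2 years, yearly to 18) by 11 centile levels
#' (C1, C2.5, C5, C10, C25, C50, C75, C90, C95, C97.5, C99).
#'
#' @param vital `"hr"` (bpm) or `"rr"` (breaths/min).
#' @return Data frame with columns `age_years`, `age_units`, `description`
#'   and `C1` ... `C99`.
#' @export
reference_centile_table <- function(vital = c("hr", "rr")) {
  vital <- match.arg(vital)
  f <- system.file("extdata", paste0(vital, "_centiles_by_age.tsv"),
                   package = "pedcentiles", mustWork = TRUE)
  utils::read.delim(f, check.names = FALSE)
}

#' Source-cohort age mix
#'
#' Encounter counts and percentages by age category in the source cohort
#' (1,203,042 emergency-department encounters), used as the default age-mix
#' weights of the synthetic-data generator.
#'
#' @return Data frame with columns `age_years`, `description`, `n`,
#'   `percent`.
#' @export
reference_age_mix <- function() {
  f <- system.file("extdata", "age_group_counts.tsv",
                   package = "pedcentiles", mustWork = TRUE)
  utils::read.delim(f, check.names = FALSE)
}

#' Canonical age grid of the reference tables
#'
#' The 40 age categories used throughout: 24 one-month bins under 2 years,
#' then 16 one-year bins, each represented by its midpoint in years.
#'
#' @return Data frame with columns `age_years` (midpoint), `age_units`,
#'   `description`.
#' @export
age_grid <- function() {
  reference_centile_table("hr")[, c("age_years", "age_units", "description")]
}

# centile levels of the published tables
.CENTILE_LEVELS <- c(1, 2.5, 5, 10, 25, 50, 75, 90, 95, 97.5, 99)
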