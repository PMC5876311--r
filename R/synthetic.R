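# Synthetic encounter generator.
#
# Emulates the statistical structure of the source ED database: per-age
# BCPE-distributed heart rates and log-scale BCT respiratory rates whose
# parameters are recovered by inverting the published centile tables,
# age-group frequencies matching the published cohort mix, even-digit
# preference in recorded RR, simultaneous duplicate measurements (~7% of
# encounters), implausible outliers, and trauma/chronic exclusion flags
# (~0.4%).  Nothing here touches the (inaccessible) source records.

.pkg_cache <- new.env(parent = emptyenv())

#' Distribution parameters anchored to the published tables
#'
#' Inverts each of the 40 published age rows into four-parameter
#' distribution models: BCPE on the raw scale for HR, BCT on the
#' natural-log scale for RR.  Every printed centile must be reproduced
#' within 1 unit (integer-rounding tolerance), otherwise an error names
#' the offending age row.  Results are cached for the session.
#'
#' @param vital `"hr"` or `"rr"`.
#' @return List of 40 [family_params()] (one per age row, in age order),
#'   with attributes `age_years` and `max_residual`.
#' @export
build_reference_params <- function(vital = c("hr", "rr")) {
  vital <- match.arg(vital)
  key <- paste0("ref_", vital)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  tab <- reference_centile_table(vital)
  family <- if (vital == "hr") "BCPE" else "BCT"
  log_scale <- vital == "rr"
  cols <- paste0("C", .CENTILE_LEVELS)
  out <- vector("list", nrow(tab))
  worst <- 0
  for (i in seq_len(nrow(tab))) {
    pts <- data.frame(p = .CENTILE_LEVELS, value = as.numeric(tab[i, cols]))
    fit <- fit_params_to_centiles(pts, family, log_scale = log_scale)
    r <- max(abs(attr(fit, "residuals")))
    if (r > 1)
      stop(sprintf("reference fit residual %.3f > 1 for %s age row \"%s\"",
                   r, toupper(vital), tab$description[i]))
    worst <- max(worst, r)
    out[[i]] <- fit
  }
  attr(out, "age_years") <- tab$age_years
  attr(out, "max_residual") <- worst
  .pkg_cache[[key]] <- out
  out
}

#' Even-digit preference for recorded respiratory rates
#'
#' With probability `strength` a value is rounded to the nearest even
#' integer, otherwise to the nearest integer — reproducing the excess mass
#' on even terminal digits seen in charted RR (the phenomenon the
#' modeling dither must smooth away).
#'
#' @param rr Positive respiratory rates.
#' @param strength Probability of even-integer rounding, in `[0, 1]`.
#' @return Integer-valued rates.
#' @export
inject_digit_bias <- function(rr, strength = 0.6) {
  stopifnot(all(rr > 0), strength >= 0, strength <= 1)
  even <- stats::runif(length(rr)) < strength
  out <- .round_half_away(rr)
  out[even] <- 2 * .round_half_away(rr[even] / 2)
  out
}

#' Generator configuration
#'
#' Defaults restate the source cohort's documented structure: age mix from
#' the published encounter frequencies, ~7% of encounters carrying
#' simultaneous duplicate measurements, ~0.4% trauma/chronic exclusions.
#'
#' @param n Number of encounters.
#' @param seed Integer seed; the generator is fully reproducible.
#' @param age_mix Probability weights over the 40 age categories (default:
#'   published cohort proportions).
#' @param duplicate_frac Fraction of encounters with a duplicated
#'   simultaneous measurement.
#' @param discordant_frac Fraction of those duplicates that are discordant
#'   (range beyond the 10%/3% tolerance).
#' @param outlier_frac Fraction of encounters given a physiologically
#'   implausible vital value.
#' @param trauma_chronic_frac Combined fraction flagged trauma or
#'   chronic-condition (split evenly).
#' @param digit_bias Even-digit preference strength for RR.
#' @param tmp_mean,tmp_sd,tmp_bounds Truncated-normal body-temperature
#'   marginal (degrees C).
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(n = 10000, seed = 1, age_mix = NULL,
                             duplicate_frac = 0.07, discordant_frac = 0.10,
                             outlier_frac = 0.002,
                             trauma_chronic_frac = 0.004,
                             digit_bias = 0.6,
                             tmp_mean = 37.2, tmp_sd = 0.8,
                             tmp_bounds = c(34, 42)) {
  if (is.null(age_mix)) {
    mix <- reference_age_mix()
    age_mix <- mix$n / sum(mix$n)
  }
  stopifnot(length(age_mix) == 40, all(age_mix >= 0),
            duplicate_frac >= 0, duplicate_frac <= 1,
            outlier_frac >= 0, outlier_frac <= 1,
            trauma_chronic_frac >= 0, trauma_chronic_frac <= 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 age_mix = age_mix / sum(age_mix),
                 duplicate_frac = duplicate_frac,
                 discordant_frac = discordant_frac,
                 outlier_frac = outlier_frac,
                 trauma_chronic_frac = trauma_chronic_frac,
                 digit_bias = digit_bias,
                 tmp_mean = tmp_mean, tmp_sd = tmp_sd,
                 tmp_bounds = tmp_bounds),
            class = "generator_config")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate an ED encounter data set
#'
#' Produces the two interchange tables consumed by [clean_vitals()]:
#' `encounters` (one row per encounter with age category, sex and
#' exclusion flags) and `measurements` (one row per recorded vital
#' value with its minute offset).
#'
#' @param config A [generator_config()].
#' @param dir Optional directory: when given, `encounters.csv` and
#'   `measurements.csv` are written there.
#' @return List with `encounters`, `measurements` and `truth` (per-
#'   encounter injected-anomaly bookkeeping for tests).
#' @export
simulate_encounters <- function(config = generator_config(), dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n
  hr_ref <- build_reference_params("hr")
  rr_ref <- build_reference_params("rr")
  ages <- attr(hr_ref, "age_years")

  cat_idx <- sample.int(40, n, replace = TRUE, prob = config$age_mix)
  # age category -> recorded integer age
  months <- round(ages * 12 - 0.5)  # 0..23 for the monthly bins
  years <- floor(ages)
  is_month <- ages < 2
  age_value <- ifelse(is_month[cat_idx], months[cat_idx], years[cat_idx])
  age_unit <- ifelse(is_month[cat_idx], "months", "years")

  # vitals drawn category-wise from the table-anchored models
  hr <- rr <- numeric(n)
  for (k in sort(unique(cat_idx))) {
    ix <- which(cat_idx == k)
    hr[ix] <- bc_sample(hr_ref[[k]], length(ix))
    rr[ix] <- exp(bc_sample(rr_ref[[k]], length(ix)))
  }
  hr <- .round_half_away(hr)
  rr <- inject_digit_bias(rr, config$digit_bias)
  rr <- pmax(rr, 1)
  tmp <- round(.rtruncnorm(n, config$tmp_mean, config$tmp_sd,
                           config$tmp_bounds[1], config$tmp_bounds[2]), 1)

  # implausible outliers (always beyond the hard exclusion bounds)
  outlier <- stats::runif(n) < config$outlier_frac
  if (any(outlier)) {
    ix <- which(outlier)
    pick <- sample.int(3, length(ix), replace = TRUE)
    hr[ix[pick == 1]] <- sample(c(10, 320, 400), sum(pick == 1), replace = TRUE)
    rr[ix[pick == 2]] <- sample(c(0, 125, 150), sum(pick == 2), replace = TRUE)
    tmp[ix[pick == 3]] <- sample(c(25, 48), sum(pick == 3), replace = TRUE)
  }

  flagged <- stats::runif(n) < config$trauma_chronic_frac
  which_flag <- stats::runif(n) < 0.5
  trauma <- flagged & which_flag
  chronic <- flagged & !which_flag

  sex <- ifelse(stats::runif(n) < 0.521, "M", "F")
  enc_id <- sprintf("E%07d", seq_len(n))
  encounters <- data.frame(encounter_id = enc_id, age_value = age_value,
                           age_unit = age_unit, sex = sex,
                           trauma_flag = as.integer(trauma),
                           chronic_dx_flag = as.integer(chronic))

  t_hr <- sample(0:5, n, replace = TRUE)
  t_rr <- t_hr + sample(0:5, n, replace = TRUE)
  t_tmp <- t_hr + sample(0:9, n, replace = TRUE)
  measurements <- data.frame(
    encounter_id = rep(enc_id, 3),
    vital = rep(c("HR", "RR", "TMP"), each = n),
    value = c(hr, rr, tmp),
    time_offset_min = c(t_hr, t_rr, t_tmp))

  # simultaneous duplicates: a second value for one vital at the same time
  dup <- stats::runif(n) < config$duplicate_frac
  if (any(dup)) {
    ix <- which(dup)
    vt <- sample(c("HR", "RR", "TMP"), length(ix), replace = TRUE)
    disc <- stats::runif(length(ix)) < config$discordant_frac
    base <- c(hr[ix][vt == "HR"], rr[ix][vt == "RR"], tmp[ix][vt == "TMP"])
    ord <- c(which(vt == "HR"), which(vt == "RR"), which(vt == "TMP"))
    tol <- ifelse(vt[ord] == "TMP", 0.03, 0.10)
    # concordant: within half the allowed range; discordant: 2x beyond it
    mult <- ifelse(disc[ord], 1.5, 0.25)
    second <- base * (1 + mult * tol)
    second[vt[ord] != "TMP"] <- .round_half_away(second[vt[ord] != "TMP"])
    second[vt[ord] == "TMP"] <- round(second[vt[ord] == "TMP"], 1)
    t0 <- c(t_hr[ix][vt == "HR"], t_rr[ix][vt == "RR"], t_tmp[ix][vt == "TMP"])
    measurements <- rbind(measurements, data.frame(
      encounter_id = enc_id[ix][ord], vital = vt[ord], value = second,
      time_offset_min = t0))
    discordant <- logical(n)
    discordant[ix[ord[disc[ord]]]] <- TRUE
  } else discordant <- logical(n)

  truth <- data.frame(encounter_id = enc_id, age_category = cat_idx,
                      age_years = ages[cat_idx], outlier = outlier,
                      trauma = trauma, chronic = chronic,
                      duplicated = dup, discordant = discordant)
  out <- list(encounters = encounters, measurements = measurements,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(encounters, file.path(dir, "encounters.csv"),
                     row.names = FALSE)
    utils::write.csv(measurements, file.path(dir, "measurements.csv"),
                     row.names = FALSE)
  }
  out
}
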