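# Cleaning: raw measurement-level records -> one (age, HR, RR, TMP)
# observation per encounter.
#
# Rules applied, in stage order:
#   1. missing_vital          - HR, RR or TMP never recorded
#   2. discordant_duplicates  - simultaneous duplicates whose range exceeds
#                               10% of the largest value (HR/RR) or 3% (TMP);
#                               such an encounter is excluded outright
#   3. not_within_15min       - no (HR, RR, TMP) triple with all pairwise
#                               time gaps <= 15 min
#   4. extreme_value          - HR < 30 or > 300 bpm; RR = 0 or >= 120
#                               breaths/min; TMP < 30 or > 46 C
#   5. trauma                 - trauma-center encounter
#   6. chronic_dx             - chronic heart/respiratory diagnosis

.EXCLUSION_REASONS <- c("missing_vital", "discordant_duplicates",
                        "not_within_15min", "extreme_value",
                        "trauma", "chronic_dx")

#' Age-category midpoint in years
#'
#' Ages are categorical: integer months for children under 2 years,
#' integer years otherwise.  Each category is represented by its midpoint
#' (0-1 month becomes 0.5 months = 0.042 years; 17 years becomes 17.5).
#'
#' @param age_value Integer age value(s).
#' @param age_unit `"months"` or `"years"` (recycled).
#' @return Age midpoint(s) in years.
#' @examples
#' age_midpoint(0, "months")   # 0.042
#' age_midpoint(17, "years")   # 17.5
#' @export
age_midpoint <- function(age_value, age_unit) {
  age_unit <- match.arg(age_unit, c("months", "years"), several.ok = TRUE)
  age_unit <- rep_len(age_unit, length(age_value))
  if (any(age_value < 0)) stop("age must be non-negative")
  if (any(age_unit == "months" & age_value > 23))
    stop("ages of 24 months or more must be recorded in years")
  if (any(age_unit == "years" & age_value < 2))
    stop("ages under 2 years must be recorded in months")
  if (any(age_unit == "years" & age_value >= 18))
    stop("age must be under 18 years")
  ifelse(age_unit == "months", (age_value + 0.5) / 12, age_value + 0.5)
}

# range tolerance, as a fraction of the largest simultaneous value
.range_tol <- function(vital) ifelse(vital == "TMP", 0.03, 0.10)

#' Resolve simultaneous duplicate measurements
#'
#' Two or more values recorded for the same vital at the same time are
#' replaced by their mean, provided their range does not exceed 10% of the
#' largest value (HR, RR) or 3% (TMP); otherwise the set is discordant and
#' the encounter is excluded.
#'
#' @param values Numeric values recorded at one timestamp for one vital.
#' @param vital `"HR"`, `"RR"` or `"TMP"`.
#' @return List with `value` (the resolved value, or `NA` if discordant)
#'   and `discordant` (logical).
#' @examples
#' resolve_simultaneous(c(150, 160), "HR")  # mean 155
#' resolve_simultaneous(c(150, 170), "HR")  # discordant
#' @export
resolve_simultaneous <- function(values, vital = c("HR", "RR", "TMP")) {
  vital <- match.arg(vital)
  if (length(values) == 0L) stop("no values supplied")
  if (length(values) == 1L) return(list(value = values, discordant = FALSE))
  rng <- max(values) - min(values)
  if (rng > .range_tol(vital) * max(values))
    return(list(value = NA_real_, discordant = TRUE))
  list(value = mean(values), discordant = FALSE)
}

#' Assemble the initial vital-sign triple of an encounter
#'
#' Finds the earliest (HR, RR, TMP) triple whose three measurement times
#' lie within 15 minutes of one another, after duplicate resolution at each
#' timestamp.  "Earliest" means smallest latest-member time, ties broken by
#' input order.
#'
#' @param measurements Data frame with columns `vital`, `value`,
#'   `time_offset_min` for a single encounter.
#' @return List with `hr`, `rr`, `tmp`, `discordant` (TRUE if any
#'   simultaneous duplicate set was discordant) and `missing` (one of
#'   `"none"`, `"missing_vital"`, `"not_within_15min"`).
#' @export
assemble_initial_vitals <- function(measurements) {
  stopifnot(all(c("vital", "value", "time_offset_min") %in% names(measurements)))
  m <- measurements
  m$t <- round(m$time_offset_min)
  res <- list()
  discordant <- FALSE
  for (vt in c("HR", "RR", "TMP")) {
    mv <- m[m$vital == vt, , drop = FALSE]
    if (nrow(mv) == 0L) { res[[vt]] <- NULL; next }
    out <- lapply(split(mv$value, mv$t), function(v) {
      r <- resolve_simultaneous(v, vt)
      if (r$discordant) discordant <<- TRUE
      r$value
    })
    tt <- as.numeric(names(out))
    vv <- unlist(out, use.names = FALSE)
    keep <- !is.na(vv)
    res[[vt]] <- data.frame(t = tt[keep], value = vv[keep])[order(tt[keep]), ]
  }
  empty <- list(hr = NA_real_, rr = NA_real_, tmp = NA_real_,
                discordant = discordant)
  if (discordant) return(c(empty, missing = "none"))
  if (any(vapply(c("HR", "RR", "TMP"),
                 function(v) is.null(res[[v]]) || nrow(res[[v]]) == 0L,
                 logical(1))))
    return(c(empty, missing = "missing_vital"))
  # enumerate triples; pick smallest latest-member time satisfying the rule
  best <- NULL
  for (i in seq_len(nrow(res$HR))) for (j in seq_len(nrow(res$RR)))
    for (k in seq_len(nrow(res$TMP))) {
      ts <- c(res$HR$t[i], res$RR$t[j], res$TMP$t[k])
      if (max(ts) - min(ts) <= 15) {
        cand <- list(hr = res$HR$value[i], rr = res$RR$value[j],
                     tmp = res$TMP$value[k], latest = max(ts))
        if (is.null(best) || cand$latest < best$latest) best <- cand
      }
    }
  if (is.null(best)) return(c(empty, missing = "not_within_15min"))
  list(hr = best$hr, rr = best$rr, tmp = best$tmp,
       discordant = FALSE, missing = "none")
}

#' Apply record-level exclusions to an assembled triple
#'
#' @param encounter One-row data frame (or list) with logical/0-1 fields
#'   `trauma_flag` and `chronic_dx_flag`.
#' @param vitals List or vector with `hr`, `rr`, `tmp`.
#' @return `"kept"` or the first matching exclusion reason
#'   (`"extreme_value"`, `"trauma"`, `"chronic_dx"`).
#' @details Boundary semantics are those of the source rules: HR of exactly
#'   30 or 300 bpm is kept (exclusion is strict `<30` / `>300`); RR of 120
#'   is dropped (`>= 120`); TMP bounds 30-46 C are inclusive.
#' @export
apply_exclusions <- function(encounter, vitals) {
  hr <- vitals[["hr"]]; rr <- vitals[["rr"]]; tmp <- vitals[["tmp"]]
  if (hr < 30 || hr > 300 || rr <= 0 || rr >= 120 || tmp < 30 || tmp > 46)
    return("extreme_value")
  if (isTRUE(as.logical(encounter[["trauma_flag"]]))) return("trauma")
  if (isTRUE(as.logical(encounter[["chronic_dx_flag"]]))) return("chronic_dx")
  "kept"
}

#' Clean a raw encounter/measurement data set
#'
#' Runs the full cleaning pipeline: duplicate resolution, initial-triple
#' assembly under the 15-minute rule, and the extreme-value / trauma /
#' chronic-condition exclusions.  Vectorized for large inputs; encounters
#' with multiple candidate measurement times fall back to the exhaustive
#' per-encounter rule in [assemble_initial_vitals()].
#'
#' @param encounters Data frame with columns `encounter_id`, `age_value`,
#'   `age_unit`, `sex`, `trauma_flag`, `chronic_dx_flag`.
#' @param measurements Data frame with columns `encounter_id`, `vital`,
#'   `value`, `time_offset_min`.
#' @return List with `observations` (data frame `encounter_id`,
#'   `age_years`, `hr`, `rr`, `tmp`) and `exclusions` (one row per input
#'   encounter: `encounter_id`, `disposition` = kept/dropped, `reason`).
#' @export
clean_vitals <- function(encounters, measurements) {
  stopifnot(!anyDuplicated(encounters$encounter_id))
  enc <- data.table::as.data.table(encounters)
  mea <- data.table::as.data.table(measurements)
  if (any(mea$value < 0)) stop("negative measurement values are invalid")
  if (any(mea$time_offset_min < 0)) stop("negative time offsets are invalid")
  mea <- mea[mea$encounter_id %in% enc$encounter_id]
  mea[, t := round(time_offset_min)]

  # duplicate resolution per (encounter, vital, minute)
  value <- t <- vital <- encounter_id <- NULL  # NSE notes
  grp <- mea[, .(v = mean(value),
                 disc = (max(value) - min(value)) > .range_tol(vital[1]) * max(value),
                 n = .N),
             by = .(encounter_id, vital, t)]

  disc_enc <- unique(grp$encounter_id[grp$disc])
  nvit <- data.table::dcast(grp, encounter_id ~ vital, fun.aggregate = length,
                            value.var = "v")
  for (vt in c("HR", "RR", "TMP")) if (!vt %in% names(nvit)) nvit[[vt]] <- 0L

  reason <- rep(NA_character_, nrow(enc))
  names(reason) <- as.character(enc$encounter_id)
  miss_enc <- nvit$encounter_id[nvit$HR == 0L | nvit$RR == 0L | nvit$TMP == 0L]
  miss_enc <- union(miss_enc, setdiff(enc$encounter_id, nvit$encounter_id))
  reason[as.character(miss_enc)] <- "missing_vital"
  ok <- is.na(reason[as.character(disc_enc)])
  reason[as.character(disc_enc)[ok]] <- "discordant_duplicates"

  pending <- enc$encounter_id[is.na(reason[as.character(enc$encounter_id)])]
  g <- grp[encounter_id %in% pending & !disc]

  # fast path: exactly one resolved time per vital
  ntimes <- g[, .(m = .N), by = .(encounter_id, vital)]
  simple <- ntimes[, .(simple = all(m == 1L)), by = encounter_id]
  simple_ids <- simple$encounter_id[simple$simple]

  wide <- data.table::dcast(g[encounter_id %in% simple_ids],
                            encounter_id ~ vital, value.var = c("v", "t"))
  span <- pmax(wide$t_HR, wide$t_RR, wide$t_TMP) -
    pmin(wide$t_HR, wide$t_RR, wide$t_TMP)
  late <- wide$encounter_id[span > 15]
  reason[as.character(late)] <- "not_within_15min"
  triples <- wide[span <= 15, .(encounter_id, hr = v_HR, rr = v_RR, tmp = v_TMP)]

  # slow path: several candidate times for some vital
  complex_ids <- setdiff(pending, simple_ids)
  if (length(complex_ids)) {
    sub <- mea[encounter_id %in% complex_ids]
    extra <- lapply(split(sub, by = "encounter_id", keep.by = TRUE), function(d) {
      a <- assemble_initial_vitals(d)
      data.frame(encounter_id = d$encounter_id[1], hr = a$hr, rr = a$rr,
                 tmp = a$tmp, missing = a$missing)
    })
    extra <- data.table::rbindlist(extra)
    bad <- extra[extra$missing != "none"]
    reason[as.character(bad$encounter_id)] <- bad$missing
    triples <- rbind(triples,
                     extra[extra$missing == "none",
                           c("encounter_id", "hr", "rr", "tmp")])
  }

  # record-level exclusions, vectorized with the documented precedence
  ek <- enc[match(triples$encounter_id, enc$encounter_id), ]
  extreme <- triples$hr < 30 | triples$hr > 300 |
    triples$rr <= 0 | triples$rr >= 120 |
    triples$tmp < 30 | triples$tmp > 46
  r3 <- ifelse(extreme, "extreme_value",
               ifelse(as.logical(ek$trauma_flag), "trauma",
                      ifelse(as.logical(ek$chronic_dx_flag), "chronic_dx", NA)))
  reason[as.character(triples$encounter_id)] <- r3

  kept <- triples[is.na(r3)]
  ek <- ek[is.na(r3)]
  obs <- data.frame(encounter_id = kept$encounter_id,
                    age_years = age_midpoint(ek$age_value, as.character(ek$age_unit)),
                    hr = kept$hr, rr = kept$rr, tmp = kept$tmp)
  obs <- obs[order(match(obs$encounter_id, enc$encounter_id)), ]
  rownames(obs) <- NULL

  reason_vec <- reason[as.character(enc$encounter_id)]
  log <- data.frame(encounter_id = enc$encounter_id,
                    disposition = ifelse(is.na(reason_vec), "kept", "dropped"),
                    reason = ifelse(is.na(reason_vec), "", reason_vec))
  list(observations = obs, exclusions = log)
}

#' Read / write the delimited interchange files
#'
#' `read_encounters()` and `read_measurements()` read the two comma-separated
#' input files (UTF-8, header row); `write_clean()` writes
#' `clean_observations.csv` and `exclusion_log.csv` to a directory.
#'
#' @param path File (readers) or directory (writer) path.
#' @param cleaned Result of [clean_vitals()].
#' @return The data frame(s) read, or (invisibly) the output paths.
#' @name cleaning_io
#' @export
read_encounters <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname cleaning_io
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname cleaning_io
#' @export
write_clean <- function(cleaned, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(path, "clean_observations.csv")
  f2 <- file.path(path, "exclusion_log.csv")
  utils::write.csv(cleaned$observations, f1, row.names = FALSE)
  utils::write.csv(cleaned$exclusions, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
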