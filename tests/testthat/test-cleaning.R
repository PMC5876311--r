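# Cleaning rules: age midpoints, duplicate resolution, triple assembly,
# exclusions, and the vectorized pipeline

test_that("age categories map to their midpoints", {
  expect_equal(round(age_midpoint(0, "months"), 3), 0.042)
  expect_equal(round(age_midpoint(23, "months"), 3), 1.958)
  expect_equal(age_midpoint(17, "years"), 17.5)
  expect_equal(age_midpoint(0, "months"), 0.5 / 12)
  expect_error(age_midpoint(18, "years"), "under 18")
  expect_error(age_midpoint(-1, "months"), "non-negative")
  expect_error(age_midpoint(30, "months"), "in years")
  expect_error(age_midpoint(1, "years"), "in months")
})

test_that("simultaneous duplicates are averaged or flagged discordant", {
  expect_equal(resolve_simultaneous(c(150, 160), "HR"),
               list(value = 155, discordant = FALSE))
  r <- resolve_simultaneous(c(150, 170), "HR")   # range 20 > 10% of 170
  expect_true(r$discordant)
  expect_equal(resolve_simultaneous(37.0, "TMP"),
               list(value = 37.0, discordant = FALSE))
  # TMP tolerance is 3%: range 1.0 vs 0.03 * 37.8 = 1.13
  expect_false(resolve_simultaneous(c(36.8, 37.8), "TMP")$discordant)
  expect_true(resolve_simultaneous(c(36.5, 37.8), "TMP")$discordant)
  expect_error(resolve_simultaneous(numeric(0), "HR"), "no values")
})

test_that("triple assembly enforces the 15-minute window", {
  ok <- assemble_initial_vitals(tiny_measurements("a", t_hr = 0, t_rr = 5, t_tmp = 14))
  expect_equal(ok$missing, "none")
  expect_equal(ok$hr, 120)
  late <- assemble_initial_vitals(tiny_measurements("a", t_hr = 0, t_rr = 5, t_tmp = 20))
  expect_equal(late$missing, "not_within_15min")
  m <- tiny_measurements("a")[1:2, ]  # no TMP recorded
  expect_equal(assemble_initial_vitals(m)$missing, "missing_vital")
})

test_that("the earliest qualifying triple is selected", {
  # two qualifying triples; earliest by latest-member time wins
  m <- data.frame(encounter_id = "a",
                  vital = c("HR", "RR", "TMP", "HR", "RR", "TMP"),
                  value = c(120, 22, 37, 130, 28, 38),
                  time_offset_min = c(0, 5, 10, 30, 35, 40))
  a <- assemble_initial_vitals(m)
  expect_equal(c(a$hr, a$rr, a$tmp), c(120, 22, 37))
})

test_that("exclusion boundaries are honored exactly", {
  enc <- list(trauma_flag = 0, chronic_dx_flag = 0)
  expect_equal(apply_exclusions(enc, list(hr = 30, rr = 22, tmp = 37)), "kept")
  expect_equal(apply_exclusions(enc, list(hr = 300, rr = 22, tmp = 37)), "kept")
  expect_equal(apply_exclusions(enc, list(hr = 310, rr = 22, tmp = 37)), "extreme_value")
  expect_equal(apply_exclusions(enc, list(hr = 29.5, rr = 22, tmp = 37)), "extreme_value")
  expect_equal(apply_exclusions(enc, list(hr = 150, rr = 119.5, tmp = 37)), "kept")
  expect_equal(apply_exclusions(enc, list(hr = 150, rr = 120, tmp = 37)), "extreme_value")
  expect_equal(apply_exclusions(enc, list(hr = 150, rr = 0, tmp = 37)), "extreme_value")
  expect_equal(apply_exclusions(enc, list(hr = 150, rr = 22, tmp = 46)), "kept")
  expect_equal(apply_exclusions(enc, list(hr = 150, rr = 22, tmp = 46.5)), "extreme_value")
  expect_equal(apply_exclusions(list(trauma_flag = 1, chronic_dx_flag = 0),
                                list(hr = 150, rr = 22, tmp = 37)), "trauma")
  expect_equal(apply_exclusions(list(trauma_flag = 0, chronic_dx_flag = 1),
                                list(hr = 150, rr = 22, tmp = 37)), "chronic_dx")
})

test_that("pipeline conserves encounters and matches the per-encounter rules", {
  enc <- tiny_encounters(letters[1:6], trauma = c(0, 0, 0, 0, 1, 0),
                         chronic = c(0, 0, 0, 0, 0, 1))
  mea <- rbind(
    tiny_measurements("a"),                                   # kept
    tiny_measurements("b", t_tmp = 30),                       # window breach
    tiny_measurements("c", hr = 320),                         # extreme HR
    rbind(tiny_measurements("d"),                             # discordant dup
          data.frame(encounter_id = "d", vital = "HR", value = 150,
                     time_offset_min = 0)),
    tiny_measurements("e"),                                   # trauma
    tiny_measurements("f")                                    # chronic
  )
  out <- clean_vitals(enc, mea)
  expect_equal(nrow(out$exclusions), 6)
  expect_setequal(out$exclusions$encounter_id, letters[1:6])
  got <- setNames(out$exclusions$reason, out$exclusions$encounter_id)
  expect_equal(unname(got[letters[1:6]]),
               c("", "not_within_15min", "extreme_value",
                 "discordant_duplicates", "trauma", "chronic_dx"))
  expect_equal(out$observations$encounter_id, "a")
  expect_equal(out$observations$hr, 120)
  expect_equal(out$observations$age_years, 5.5)
})

test_that("concordant duplicates are averaged in the pipeline", {
  enc <- tiny_encounters("a")
  mea <- rbind(tiny_measurements("a", hr = 150),
               data.frame(encounter_id = "a", vital = "HR", value = 160,
                          time_offset_min = 0))
  out <- clean_vitals(enc, mea)
  expect_equal(out$observations$hr, 155)
})

test_that("cleaning an already-clean table is idempotent", {
  cl <- get_sim_clean()$clean
  ob <- head(cl$observations, 2000)
  enc2 <- data.frame(encounter_id = ob$encounter_id,
                     age_value = 5L, age_unit = "years", sex = "F",
                     trauma_flag = 0, chronic_dx_flag = 0)
  mea2 <- data.frame(encounter_id = rep(ob$encounter_id, 3),
                     vital = rep(c("HR", "RR", "TMP"), each = nrow(ob)),
                     value = c(ob$hr, ob$rr, ob$tmp),
                     time_offset_min = 0)
  out <- clean_vitals(enc2, mea2)
  expect_equal(nrow(out$observations), nrow(ob))
  expect_equal(out$observations$hr, ob$hr)
  expect_equal(out$observations$rr, ob$rr)
})

test_that("injected exclusion fractions are recovered within binomial error", {
  fx <- get_sim_clean()
  truth <- fx$sim$truth
  log <- fx$clean$exclusions
  n <- nrow(truth)
  reasons <- table(factor(log$reason, exclude = ""))
  binom_hi <- function(p) n * p + 3.5 * sqrt(n * p * (1 - p))
  binom_lo <- function(p) n * p - 3.5 * sqrt(n * p * (1 - p))
  # trauma + chronic together ~ 0.4% minus overlap with extreme values
  tc <- sum(reasons[c("trauma", "chronic_dx")])
  expect_gt(tc, binom_lo(0.004) - sum(truth$outlier))
  expect_lt(tc, binom_hi(0.004))
  # discordant duplicates: duplicate_frac * discordant_frac = 0.7%
  expect_gt(reasons[["discordant_duplicates"]], binom_lo(0.007) - 5)
  expect_lt(reasons[["discordant_duplicates"]], binom_hi(0.007))
  # conservation
  expect_equal(sum(log$disposition == "kept") + sum(log$disposition == "dropped"), n)
  expect_equal(sum(log$disposition == "kept"), nrow(fx$clean$observations))
})
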