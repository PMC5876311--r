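# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# standard parameter sets used across distribution tests
std_bcpe <- function() family_params("BCPE", mu = 100, sigma = 0.1, nu = 1, tau = 2)
std_bct <- function() family_params("BCT", mu = 30, sigma = 0.2, nu = 0.5, tau = 8)

centile_levels <- c(1, 2.5, 5, 10, 25, 50, 75, 90, 95, 97.5, 99)

# one moderate synthetic data set + cleaned observations, shared
get_sim_clean <- function() {
  if (is.null(.fixture_env$clean)) {
    sim <- simulate_encounters(generator_config(n = 40000, seed = 301))
    .fixture_env$sim <- sim
    .fixture_env$clean <- clean_vitals(sim$encounters, sim$measurements)
  }
  list(sim = .fixture_env$sim, clean = .fixture_env$clean)
}

# one fitted model per vital on the shared data, shared across test files
get_test_model <- function(vital) {
  key <- paste0("model_", vital)
  if (is.null(.fixture_env[[key]])) {
    ob <- get_sim_clean()$clean$observations
    .fixture_env[[key]] <- fit_vital_model(
      ob, vital, seed = 401, zeta = 0.4,
      edf = c(mu = 12, sigma = 8, nu = 5, tau = 5))
  }
  .fixture_env[[key]]
}

# smoothly varying truth anchored to the published tables: the per-row
# inverted parameters are smoothed over transformed age (the shape
# parameters nu and tau more heavily, being barely identified from 11
# rounded centiles) so that a smooth fit can in principle track the truth
smooth_truth_params <- function(vital, dfs = c(10, 8, 4, 4)) {
  ref <- build_reference_params(vital)
  ages <- attr(ref, "age_years")
  x <- ages^0.4
  th <- sapply(ref, function(p) c(log(p$mu), log(p$sigma), p$nu, log(p$tau)))
  sm <- sapply(1:4, function(j)
    predict(smooth.spline(x, th[j, ], df = dfs[j]), x)$y)
  out <- lapply(seq_along(ages), function(i) family_params(
    if (vital == "hr") "BCPE" else "BCT",
    exp(sm[i, 1]), exp(sm[i, 2]), sm[i, 3], exp(sm[i, 4])))
  attr(out, "age_years") <- ages
  out
}

# small deterministic encounter/measurement tables for cleaning unit tests
tiny_encounters <- function(ids, trauma = 0, chronic = 0) {
  n <- length(ids)
  data.frame(encounter_id = ids, age_value = rep(5L, n),
             age_unit = "years", sex = "F",
             trauma_flag = rep_len(trauma, n),
             chronic_dx_flag = rep_len(chronic, n))
}

tiny_measurements <- function(id, hr = 120, rr = 22, tmp = 37,
                              t_hr = 0, t_rr = 5, t_tmp = 10) {
  data.frame(encounter_id = id,
             vital = c("HR", "RR", "TMP"),
             value = c(hr, rr, tmp),
             time_offset_min = c(t_hr, t_rr, t_tmp))
}
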