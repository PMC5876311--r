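# High-level convenience: clean observations -> fitted vital-sign model,
# applying each vital's scale conventions (BCPE on the raw scale for HR;
# dither + natural log + BCT for RR).

#' Fit the reference model for one vital sign
#'
#' @param observations Data frame with columns `age_years` and `hr` or
#'   `rr` (e.g. from [clean_vitals()]).
#' @param vital `"hr"` or `"rr"`.
#' @param select If `TRUE`, run the full SBC search ([select_model()]);
#'   otherwise fit at `zeta`/`edf` directly.
#' @param seed Seed for the RR dither (recorded in the model).
#' @param zeta,edf,config Passed to the fitter.
#' @return A `"centile_model"`.
#' @export
fit_vital_model <- function(observations, vital = c("hr", "rr"),
                            select = FALSE, seed = 17,
                            zeta = 0.4, edf = NULL, config = fit_config()) {
  vital <- match.arg(vital)
  age <- observations$age_years
  if (vital == "hr") {
    value <- observations$hr
    family <- "BCPE"; log_scale <- FALSE; ds <- NA
  } else {
    value <- rr_preprocess(observations$rr, seed = seed)
    family <- "BCT"; log_scale <- TRUE; ds <- seed
  }
  if (select) {
    select_model(age, value, family = family, log_scale = log_scale,
                 config = config, dither_seed = ds)
  } else {
    fit_model(age, value, family = family, log_scale = log_scale,
              zeta = zeta, edf = edf, config = config, dither_seed = ds)
  }
}
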