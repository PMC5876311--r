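# Deliverable tables: age-by-centile and age-by-z-score reference grids on
# the canonical 40-row age grid, with integer rounding (half away from
# zero) for publication.

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# unrounded vital-sign value at (age, centile-rank) from a fitted model
.model_centile <- function(model, age, p) {
  par <- .params_at(model, age)
  v <- bc_quantile(par, p)
  if (model$log_scale) exp(v) else v
}

#' Age-by-centile reference table from a fitted model
#'
#' Evaluates the model's quantiles at the 40 canonical age midpoints and
#' 11 centile levels (C1 ... C99), exponentiates for log-scale models, and
#' rounds half-away-from-zero to integers.  The unrounded values are kept
#' in the `"unrounded"` attribute.
#'
#' @param model A fitted `"centile_model"` covering ages 0.042 to 17.5
#'   years.
#' @param levels Centile levels; default the published 11.
#' @param ages Age grid; default [age_grid()].
#' @return Data frame of class `"centile_table"`: 40 rows x
#'   (3 id columns + 11 centile columns).
#' @export
make_centile_table <- function(model, levels = .CENTILE_LEVELS,
                               ages = age_grid()) {
  stopifnot(inherits(model, "centile_model"))
  if (min(ages$age_years) < model$age_range[1] - 1e-9 ||
      max(ages$age_years) > model$age_range[2] + 1e-9)
    stop("model does not cover the requested age grid (extrapolation breach)")
  raw <- vapply(levels,
                function(p) .model_centile(model, ages$age_years, p),
                numeric(nrow(ages)))
  colnames(raw) <- paste0("C", levels)
  out <- cbind(ages, as.data.frame(.round_half_away(raw)))
  attr(out, "unrounded") <- raw
  attr(out, "levels") <- levels
  class(out) <- c("centile_table", class(out))
  out
}

#' Age-by-z-score reference table from a fitted model
#'
#' Each cell is the vital-sign value at standard-normal deviate `z`:
#' `quantile(params(age), 100 * pnorm(z))`.
#'
#' @inheritParams make_centile_table
#' @param z z-score grid; default -3 to +3 in steps of 0.5 (13 columns).
#' @return Data frame of class `"zscore_table"`; unrounded values in the
#'   `"unrounded"` attribute.
#' @export
make_zscore_table <- function(model, z = seq(-3, 3, by = 0.5),
                              ages = age_grid()) {
  stopifnot(inherits(model, "centile_model"))
  raw <- vapply(z,
                function(zz) .model_centile(model, ages$age_years,
                                            100 * stats::pnorm(zz)),
                numeric(nrow(ages)))
  colnames(raw) <- sprintf("z%+.1f", z)
  out <- cbind(ages, as.data.frame(.round_half_away(raw)))
  attr(out, "unrounded") <- raw
  attr(out, "z") <- z
  class(out) <- c("zscore_table", class(out))
  out
}

#' z-score of an observed value at a given age
#'
#' The screening-tool lookup: the standard-normal equivalent deviate of a
#' measured vital-sign value under the fitted age-conditional reference
#' distribution.
#'
#' @param model A fitted `"centile_model"`.
#' @param age Age(s) in years, within the fitted range.
#' @param value Observed vital-sign value(s) on the raw scale, `> 0`.
#' @return z-score(s).
#' @export
lookup_zscore <- function(model, age, value) {
  stopifnot(inherits(model, "centile_model"), all(value > 0))
  if (any(age < model$age_range[1] - 1e-9 | age > model$age_range[2] + 1e-9))
    stop("age outside the fitted range")
  n <- max(length(age), length(value))
  age <- rep_len(age, n); value <- rep_len(value, n)
  par <- predict_params(model, age)
  v <- if (model$log_scale) log(value) else value
  vapply(seq_len(n), function(i) {
    bc_zscore(family_params(model$family, par$mu[i], par$sigma[i],
                            par$nu[i], par$tau[i]), v[i])
  }, numeric(1))
}

#' Write a reference table as delimited text
#'
#' @param table A `"centile_table"` or `"zscore_table"`.
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(table, path, sep = "\t") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
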