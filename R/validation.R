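# Split-sample validation and sensitivity analysis: stratified 2/3-1/3
# split, tail counting against training-fitted cutoffs, chi-square
# comparison of tail proportions, Holm step-down adjustment, and cellwise
# comparison of rounded centile tables.

#' Stratified training/test split
#'
#' Within each age category, a random two-thirds of records (floor(2n/3))
#' are labeled `"training"` and the remainder `"test"`; deterministic for a
#' fixed seed.
#'
#' @param stratum Age-category identifier per record.
#' @param seed Integer seed.
#' @return Character vector (`"training"`/`"test"`) aligned with `stratum`.
#' @export
split_sample <- function(stratum, seed) {
  stratum <- as.character(stratum)
  tab <- table(stratum)
  if (any(tab < 3)) stop("strata with fewer than 3 records: ",
                         paste(names(tab)[tab < 3], collapse = ", "))
  set.seed(seed)
  out <- rep("test", length(stratum))
  for (s in names(tab)) {
    ix <- which(stratum == s)
    n_train <- floor(2 * length(ix) / 3)
    out[sample(ix)[seq_len(n_train)]] <- "training"
  }
  out
}

#' Count observations beyond modeled centile cutoffs
#'
#' Counts records strictly above the age-matched C95 and C99 cutoffs and
#' strictly below the C5 and C1 cutoffs.  Groups are reported
#' independently, so the `>99th` count is numerically a subset of the
#' `>95th` count.
#'
#' @param value Observed vital-sign values (raw scale).
#' @param age Age category midpoint per record (years).
#' @param cutoffs Data frame with columns `age_years`, `c1`, `c5`, `c95`,
#'   `c99` (unrounded, raw scale), typically from a model fitted on the
#'   training subset only.
#' @return Named integer vector: `gt99`, `gt95`, `lt5`, `lt1`.
#' @export
count_extremes <- function(value, age, cutoffs) {
  stopifnot(all(c("age_years", "c1", "c5", "c95", "c99") %in% names(cutoffs)))
  i <- match(age, cutoffs$age_years)
  if (anyNA(i)) stop("missing cutoffs for age(s): ",
                     paste(unique(age[is.na(i)]), collapse = ", "))
  c(gt99 = sum(value > cutoffs$c99[i]),
    gt95 = sum(value > cutoffs$c95[i]),
    lt5 = sum(value < cutoffs$c5[i]),
    lt1 = sum(value < cutoffs$c1[i]))
}

#' Compare a tail proportion between training and test subsets
#'
#' Two-sided p-value for the 2x2 table of (beyond cutoff, within cutoff) x
#' (training, test).  The default is the Pearson chi-square statistic with
#' 1 df and no continuity correction; `method = "fisher"` gives Fisher's
#' exact test.
#'
#' @param k_train,n_train Count beyond cutoff and subset size, training.
#' @param k_test,n_test Same for the test subset.
#' @param method `"chisq"` or `"fisher"`.
#' @return p-value in `[0, 1]`.
#' @export
compare_proportions <- function(k_train, n_train, k_test, n_test,
                                method = c("chisq", "fisher")) {
  method <- match.arg(method)
  stopifnot(k_train <= n_train, k_test <= n_test)
  m <- matrix(c(k_train, n_train - k_train, k_test, n_test - k_test),
              nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1 by convention")
    return(1)
  }
  if (method == "fisher") {
    stats::fisher.test(m)$p.value
  } else {
    suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  }
}

#' Holm (step-down Bonferroni) adjustment
#'
#' `adjusted[(i)] = max_{j <= i} min(1, (m - j + 1) * p[(j)])` over the
#' ascending order, returned in the original order.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values, `>= p`, in the input order.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p))) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Split-sample validation report
#'
#' Fits a model on the training two-thirds of each vital's observations,
#' carries the unrounded C1/C5/C95/C99 cutoffs to both subsets, counts
#' tail exceedances, compares proportions, and Holm-adjusts the four
#' p-values per vital.
#'
#' @param observations Data frame with columns `age_years` and the vital
#'   column named by `vital`.
#' @param vital `"hr"` or `"rr"` (sets family and scale conventions).
#' @param seed Seed for the stratified split (and the RR dither).
#' @param method Proportion test, `"chisq"` (default) or `"fisher"`.
#' @param zeta,edf,config Passed to [fit_model()].
#' @return Data frame of class `"validation_report"`: one row per centile
#'   group with training/test counts, percentages, raw and Holm-adjusted
#'   p-values.  The training-fitted model is in attribute `"model"`.
#' @export
validate_model <- function(observations, vital = c("hr", "rr"), seed = 1,
                           method = c("chisq", "fisher"),
                           zeta = 0.4, edf = NULL, config = fit_config()) {
  vital <- match.arg(vital)
  method <- match.arg(method)
  value <- observations[[vital]]
  age <- observations$age_years
  lab <- split_sample(age, seed)
  tr <- lab == "training"

  if (vital == "hr") {
    model <- fit_model(age[tr], value[tr], family = "BCPE", log_scale = FALSE,
                       zeta = zeta, edf = edf, config = config)
  } else {
    mv <- rr_preprocess(value[tr], seed = seed)
    model <- fit_model(age[tr], mv, family = "BCT", log_scale = TRUE,
                       zeta = zeta, edf = edf, config = config,
                       dither_seed = seed)
  }
  ages <- sort(unique(age))
  cuts <- data.frame(age_years = ages,
                     c1 = .model_centile(model, ages, 1),
                     c5 = .model_centile(model, ages, 5),
                     c95 = .model_centile(model, ages, 95),
                     c99 = .model_centile(model, ages, 99))
  k_tr <- count_extremes(value[tr], age[tr], cuts)
  k_te <- count_extremes(value[!tr], age[!tr], cuts)
  n_tr <- sum(tr); n_te <- sum(!tr)
  groups <- c(gt99 = ">99th", gt95 = ">95th", lt5 = "<5th", lt1 = "<1st")
  raw_p <- mapply(compare_proportions, k_tr, n_tr, k_te, n_te,
                  MoreArgs = list(method = method))
  rep <- data.frame(vital = toupper(vital), centile_group = unname(groups),
                    train_n = unname(k_tr),
                    train_pct = unname(100 * k_tr / n_tr),
                    test_n = unname(k_te),
                    test_pct = unname(100 * k_te / n_te),
                    raw_p = unname(raw_p),
                    holm_p = unname(holm_adjust(raw_p)))
  attr(rep, "model") <- model
  attr(rep, "n") <- c(training = n_tr, test = n_te)
  class(rep) <- c("validation_report", class(rep))
  rep
}

#' Sensitivity comparison of two centile tables
#'
#' Cellwise comparison of two rounded age-by-centile tables (e.g., fitted
#' with and without the trauma/chronic-condition exclusions): number and
#' location of discrepant cells and their magnitudes.
#'
#' @param table_with,table_without Two `"centile_table"`s on the same grid.
#' @return List with `n_cells`, `n_discrepant`, `discrepancies` (data
#'   frame: age, level, value in each table, difference).
#' @export
sensitivity_compare <- function(table_with, table_without) {
  lv <- attr(table_with, "levels")
  if (!identical(dim(table_with), dim(table_without)) ||
      !identical(lv, attr(table_without, "levels")) ||
      !identical(table_with$age_years, table_without$age_years))
    stop("tables are on different grids")
  cols <- paste0("C", lv)
  a <- as.matrix(table_with[, cols])
  b <- as.matrix(table_without[, cols])
  d <- which(a != b, arr.ind = TRUE)
  disc <- data.frame(
    age_years = table_with$age_years[d[, 1]],
    description = table_with$description[d[, 1]],
    level = lv[d[, 2]],
    with_exclusions = a[d], without_exclusions = b[d],
    difference = b[d] - a[d])
  list(n_cells = length(a), n_discrepant = nrow(disc), discrepancies = disc)
}
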