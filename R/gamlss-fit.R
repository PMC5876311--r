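# Age-smooth four-parameter distributional regression.
#
# Each of mu, sigma, nu, tau is a penalized B-spline function of
# power-transformed age (age^zeta).  Fitting maximizes the penalized
# log-likelihood by cyclic backfitting (RS-type): each parameter's spline
# coefficients are updated in turn by a penalized weighted least-squares
# step on its working variable (score / negative curvature of the
# log-likelihood with respect to the predictor), with step-halving to keep
# the penalized deviance non-increasing, until convergence.  Smoothing
# weights are solved per cycle to match the requested effective df.
# Model selection (power parameter zeta and per-parameter edf) minimizes
# the Schwarz Bayesian Criterion, SBC = -2 logLik + ln(n) * total edf.

.PARAM_NAMES <- c("mu", "sigma", "nu", "tau")
.PARAM_LINKS <- c(mu = "log", sigma = "log", nu = "identity", tau = "log")

#' Power transform of age
#'
#' Ages are raised to an exponent `zeta` in (0, 1] before smoothing, to
#' spread out the rapidly changing infant range; `zeta = 1` is the
#' identity.
#'
#' @param age Age(s) in years, `> 0`.
#' @param zeta Power exponent in `[0.01, 1]`.
#' @return `age^zeta`.
#' @export
transform_age <- function(age, zeta) {
  stopifnot(all(age > 0), zeta >= 0.01, zeta <= 1)
  age^zeta
}

#' Respiratory-rate preprocessing: dither and log transform
#'
#' Adds zero-mean Gaussian noise truncated at +/-2 breaths/min on the raw
#' scale (standard normal truncated to \[-2, 2\]) to break the digit
#' preference of recorded respiratory rates, then takes the natural log
#' (the model scale for RR).  A dithered value that would be non-positive
#' (possible only for RR <= 2) is redrawn.
#'
#' @param rr Positive respiratory rates (breaths/min).
#' @param seed Optional integer seed for reproducibility.
#' @return Natural log of the dithered rates.
#' @export
rr_preprocess <- function(rr, seed = NULL) {
  stopifnot(all(rr > 0))
  if (!is.null(seed)) set.seed(seed)
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  out <- rr + stats::qnorm(lo + stats::runif(length(rr)) * (hi - lo))
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- rr[bad] + stats::qnorm(lo + stats::runif(length(bad)) * (hi - lo))
    bad <- bad[out[bad] <= 0]
  }
  log(out)
}

#' Fitting configuration
#'
#' @param zeta_grid Candidate age power exponents.
#' @param edf_mu,edf_sigma,edf_nu,edf_tau Candidate effective df per
#'   distribution parameter (model selection grids).
#' @param edf_start Named edf vector used while searching over `zeta` and
#'   as the [fit_model()] default.
#' @param n_knots Interior knots of each cubic B-spline basis.
#' @param penalty_order Difference-penalty order.
#' @param tol Relative penalized-deviance convergence tolerance.
#' @param max_iter Maximum backfitting cycles.
#' @param dither_seed Seed recorded for the RR dither.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(zeta_grid = c(0.01, 0.05, seq(0.1, 1, by = 0.1)),
                       edf_mu = c(2, 3, 5, 8, 12),
                       edf_sigma = c(2, 3, 5, 8, 12),
                       edf_nu = c(2, 3, 5),
                       edf_tau = c(2, 3, 5),
                       edf_start = c(mu = 8, sigma = 5, nu = 3, tau = 3),
                       n_knots = 20L,
                       penalty_order = 2L,
                       tol = 1e-6,
                       max_iter = 30L,
                       dither_seed = 17L) {
  stopifnot(length(zeta_grid) >= 1, all(zeta_grid >= 0.01 & zeta_grid <= 1),
            tol > 0, max_iter >= 1)
  structure(list(zeta_grid = zeta_grid, edf_mu = edf_mu, edf_sigma = edf_sigma,
                 edf_nu = edf_nu, edf_tau = edf_tau, edf_start = edf_start,
                 n_knots = as.integer(n_knots),
                 penalty_order = as.integer(penalty_order),
                 tol = tol, max_iter = as.integer(max_iter),
                 dither_seed = dither_seed),
            class = "fit_config")
}

# evaluate the four predictor vectors -> per-observation parameter values
.inv_link <- function(eta, link) if (link == "log") exp(eta) else eta

.model_loglik <- function(y, etas, family) {
  .bc_loglik(y,
             mu = exp(etas$mu), sigma = exp(etas$sigma),
             nu = etas$nu, tau = pmin(exp(etas$tau), 1e6),
             family = family)
}

#' Fit an age-smooth BCPE/BCT model at fixed smoothing
#'
#' @param age Ages in years (categorical midpoints are expected; repeated
#'   values are pooled internally).
#' @param value Measurements on the model scale: raw vital-sign values, or
#'   their natural logs when `log_scale = TRUE` (see [rr_preprocess()]).
#' @param weights Optional frequency weights.
#' @param family `"BCPE"` or `"BCT"`.
#' @param log_scale Metadata flag: `TRUE` when `value` is on the natural
#'   log scale, so that downstream centile tables exponentiate.
#' @param zeta Age power exponent.
#' @param edf Named vector of target effective df for `mu`, `sigma`, `nu`,
#'   `tau`.
#' @param config A [fit_config()] (supplies knots, penalty order,
#'   tolerances).
#' @param dither_seed Seed recorded in the model (provenance of the RR
#'   dither; not used during fitting).
#' @return An object of class `"centile_model"`.
#' @export
fit_model <- function(age, value, weights = NULL,
                      family = c("BCPE", "BCT"), log_scale = FALSE,
                      zeta = 0.4, edf = NULL, config = fit_config(),
                      dither_seed = NA) {
  family <- match.arg(family)
  stopifnot(length(age) == length(value), all(value > 0) || log_scale)
  if (is.null(weights)) weights <- rep(1, length(age))
  n_eff <- sum(weights)
  if (n_eff < 200) stop("at least 200 observations are required for a stable 4-parameter fit")
  if (length(unique(age)) < 2L) {
    return(.fit_single_age(age, value, weights, family, log_scale, config,
                           dither_seed))
  }
  if (is.null(edf)) edf <- config$edf_start
  edf <- edf[.PARAM_NAMES]

  x <- transform_age(age, zeta)
  ux <- sort(unique(x))
  idx <- match(x, ux)
  knots <- .ps_knots(min(ux), max(ux), config$n_knots)
  Bu <- .ps_basis(ux, knots)
  K <- ncol(Bu)
  P <- .ps_penalty(K, config$penalty_order)
  # cap requested edf at what the data can identify
  edf <- pmin(edf, length(ux) - 1L)

  y <- value
  w <- weights

  # --- initialization ---------------------------------------------------
  beta <- lambda <- edf_act <- stats::setNames(vector("list", 4), .PARAM_NAMES)
  agg <- function(wi, zi) {  # aggregated normal equations over age bins
    SW <- as.vector(rowsum(wi, idx, reorder = TRUE))
    SWZ <- as.vector(rowsum(wi * zi, idx, reorder = TRUE))
    list(A = crossprod(Bu, Bu * SW), b = crossprod(Bu, SWZ))
  }
  mstat <- function(f) {  # weighted per-bin statistic smoothed onto basis
    num <- rowsum(w * f, idx, reorder = TRUE)
    den <- rowsum(w, idx, reorder = TRUE)
    as.vector(num / den)
  }
  mu_bin <- mstat(y)
  eta_mu0 <- log(pmax(mu_bin, 1e-8))
  sd_bin <- sqrt(pmax(mstat(y^2) - mu_bin^2, 1e-12))
  eta_sg0 <- log(pmax(sd_bin / abs(mu_bin), 1e-4))
  init_fit <- function(eta_target, target_edf) {
    den <- as.vector(rowsum(w, idx, reorder = TRUE))
    A <- crossprod(Bu, Bu * den)
    b <- crossprod(Bu, den * eta_target)
    lam <- .ps_lambda_for_edf(A, P, target_edf)
    .ps_solve(A, b, P, lam)
  }
  beta$mu <- init_fit(eta_mu0, edf["mu"])
  beta$sigma <- init_fit(eta_sg0, edf["sigma"])
  beta$nu <- init_fit(rep(1, length(ux)), edf["nu"])
  beta$tau <- init_fit(rep(log(if (family == "BCPE") 2 else 10), length(ux)),
                       edf["tau"])
  lambda <- list(mu = NA, sigma = NA, nu = NA, tau = NA)
  edf_act <- edf

  etas_of <- function(beta) {
    lapply(beta, function(b) as.vector(Bu %*% b)[idx])
  }
  pdev <- function(beta, lambda) {
    ll <- sum(w * .model_loglik(y, etas_of(beta), family))
    pen <- sum(vapply(.PARAM_NAMES, function(k) {
      if (is.na(lambda[[k]])) 0 else lambda[[k]] * drop(crossprod(beta[[k]], P %*% beta[[k]]))
    }, numeric(1)))
    -2 * ll + pen
  }

  # --- backfitting cycles ----------------------------------------------
  dev_trace <- numeric(0)
  cur <- pdev(beta, lambda)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    for (k in .PARAM_NAMES) {
      etas <- etas_of(beta)
      eta <- etas[[k]]
      h <- 1e-3
      ll0 <- .model_loglik(y, etas, family)
      ep <- etas; ep[[k]] <- eta + h
      em <- etas; em[[k]] <- eta - h
      llp <- .model_loglik(y, ep, family)
      llm <- .model_loglik(y, em, family)
      u <- (llp - llm) / (2 * h)
      wi <- -(llp - 2 * ll0 + llm) / h^2
      bad <- !is.finite(wi) | wi <= 0
      if (any(bad)) {
        fallback <- stats::median(wi[!bad])
        if (!is.finite(fallback) || fallback <= 0) fallback <- 1e-4
        wi[bad] <- fallback
        u[!is.finite(u)] <- 0
      }
      wi <- wi * w
      zi <- eta + u * w / wi
      ne <- agg(wi, zi)
      lam <- .ps_lambda_for_edf(ne$A, P, edf[[k]])
      bnew <- .ps_solve(ne$A, ne$b, P, lam)
      lam_old <- lambda[[k]]
      lambda[[k]] <- lam
      # step-halving: keep the penalized deviance from increasing
      bold <- beta[[k]]
      step <- 1
      repeat {
        beta[[k]] <- bold + step * (bnew - bold)
        newdev <- pdev(beta, lambda)
        if (is.finite(newdev) && newdev <= cur + 1e-8 * abs(cur)) break
        step <- step / 2
        if (step < 1 / 64) {
          beta[[k]] <- bold
          lambda[[k]] <- if (is.na(lam_old)) lam else lam_old
          newdev <- pdev(beta, lambda)
          break
        }
      }
      cur <- newdev
      edf_act[[k]] <- .ps_edf(ne$A, P, lambda[[k]])
    }
    dev_trace <- c(dev_trace, cur)
    if (it > 1 && abs(dev_trace[it - 1] - cur) <
        config$tol * (abs(cur) + 0.1)) { converged <- TRUE; break }
  }
  if (!converged && config$max_iter > 2)
    warning(sprintf("backfitting did not converge in %d cycles (last change %.3g)",
                    config$max_iter,
                    abs(diff(utils::tail(dev_trace, 2)))))

  etas <- etas_of(beta)
  sg <- exp(etas$sigma); ta <- exp(etas$tau)
  if (any(!is.finite(sg)) || any(sg <= 0) || any(!is.finite(ta)) || any(ta <= 0))
    stop("link breach: predicted sigma or tau non-positive")
  ll <- sum(w * .model_loglik(y, etas, family))
  total_edf <- sum(unlist(edf_act))
  structure(list(
    family = family, log_scale = log_scale, zeta = zeta,
    knots = knots, degree = 3L, penalty_order = config$penalty_order,
    coef = lapply(beta, as.vector),
    lambda = lambda, edf = unlist(edf_act), edf_target = unlist(edf),
    links = .PARAM_LINKS,
    x_range = range(ux), age_range = range(age),
    n_fit = n_eff, loglik = ll,
    sbc = -2 * ll + log(n_eff) * total_edf,
    deviance = cur, dev_trace = dev_trace, iter = length(dev_trace),
    converged = converged, dither_seed = dither_seed,
    single_age = FALSE), class = "centile_model")
}

# degenerate case: a single distinct age -> direct 4-parameter ML fit
.fit_single_age <- function(age, value, weights, family, log_scale, config,
                            dither_seed) {
  nll <- function(th) {
    -sum(weights * .bc_loglik(value, mu = exp(th[1]), sigma = exp(th[2]),
                              nu = th[3], tau = exp(th[4]), family = family))
  }
  mu0 <- stats::weighted.mean(value, weights)
  s0 <- sqrt(stats::weighted.mean((value - mu0)^2, weights)) / abs(mu0)
  th <- c(log(abs(mu0)), log(max(s0, 1e-4)), 1,
          log(if (family == "BCPE") 2 else 10))
  fit <- stats::optim(th, nll, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  fit <- stats::optim(fit$par, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  th <- fit$par
  n_eff <- sum(weights)
  structure(list(
    family = family, log_scale = log_scale, zeta = 1,
    knots = NULL, degree = 3L, penalty_order = config$penalty_order,
    coef = list(mu = th[1], sigma = th[2], nu = th[3], tau = th[4]),
    lambda = list(mu = NA, sigma = NA, nu = NA, tau = NA),
    edf = c(mu = 1, sigma = 1, nu = 1, tau = 1),
    edf_target = c(mu = 1, sigma = 1, nu = 1, tau = 1),
    links = .PARAM_LINKS,
    x_range = range(age), age_range = range(age),
    n_fit = n_eff, loglik = -fit$value,
    sbc = 2 * fit$value + log(n_eff) * 4,
    deviance = 2 * fit$value, dev_trace = 2 * fit$value, iter = 1L,
    converged = fit$convergence == 0, dither_seed = dither_seed,
    single_age = TRUE), class = "centile_model")
}

#' @export
print.centile_model <- function(x, ...) {
  cat(sprintf("<centile_model %s%s>  zeta=%.3g  n=%g  SBC=%.1f\n",
              x$family, if (x$log_scale) " (log scale)" else "",
              x$zeta, x$n_fit, x$sbc))
  cat("  edf:", paste(sprintf("%s=%.2f", names(x$edf), x$edf), collapse = "  "),
      "\n")
  invisible(x)
}

#' Evaluate the fitted distribution parameters at given ages
#'
#' Evaluates each parameter's spline at `age^zeta` and applies the inverse
#' links (log for `mu`, `sigma`, `tau`; identity for `nu`).
#'
#' @param model A fitted [fit_model()] object.
#' @param age Ages in years; ages outside the fitted range trigger an
#'   extrapolation warning (splines are evaluated at the range boundary).
#' @return Data frame with columns `age`, `mu`, `sigma`, `nu`, `tau`, and
#'   attributes `family` and `log_scale`.
#' @export
predict_params <- function(model, age) {
  stopifnot(inherits(model, "centile_model"))
  if (any(age < model$age_range[1] - 1e-9 | age > model$age_range[2] + 1e-9))
    warning("extrapolating outside the fitted age range [",
            model$age_range[1], ", ", model$age_range[2], "]")
  if (model$single_age) {
    out <- data.frame(age = age,
                      mu = exp(model$coef$mu), sigma = exp(model$coef$sigma),
                      nu = model$coef$nu, tau = exp(model$coef$tau))
  } else {
    x <- transform_age(pmax(age, 1e-6), model$zeta)
    x <- pmin(pmax(x, model$x_range[1]), model$x_range[2])
    B <- .ps_basis(x, model$knots, model$degree)
    eta <- lapply(model$coef, function(b) as.vector(B %*% b))
    out <- data.frame(age = age, mu = exp(eta$mu), sigma = exp(eta$sigma),
                      nu = eta$nu, tau = pmin(exp(eta$tau), 1e6))
  }
  attr(out, "family") <- model$family
  attr(out, "log_scale") <- model$log_scale
  out
}

# family_params at one age
.params_at <- function(model, age) {
  p <- predict_params(model, age)
  family_params(model$family, mu = p$mu, sigma = p$sigma, nu = p$nu,
                tau = p$tau)
}

#' Select smoothing and the age power parameter by SBC
#'
#' Two-stage deterministic search: the power parameter `zeta` is chosen on
#' its grid at the starting edf, then the per-parameter effective df are
#' refined by coordinate descent in the stepwise order mu, sigma, nu, tau.
#' The returned model has the smallest SBC among all fits evaluated.
#'
#' @inheritParams fit_model
#' @param config A [fit_config()] supplying the search grids.
#' @param verbose Print the search trace.
#' @return The SBC-minimizing `"centile_model"`.
#' @export
select_model <- function(age, value, weights = NULL,
                         family = c("BCPE", "BCT"), log_scale = FALSE,
                         config = fit_config(), verbose = FALSE,
                         dither_seed = NA) {
  family <- match.arg(family)
  fits_ok <- function(expr) tryCatch(expr, error = function(e) NULL)
  best <- NULL
  for (z in config$zeta_grid) {
    m <- fits_ok(fit_model(age, value, weights, family, log_scale, zeta = z,
                           edf = config$edf_start, config = config,
                           dither_seed = dither_seed))
    if (verbose && !is.null(m)) message(sprintf("zeta=%.2f  SBC=%.2f", z, m$sbc))
    if (!is.null(m) && (is.null(best) || m$sbc < best$sbc)) best <- m
  }
  if (is.null(best)) stop("no zeta grid point produced a successful fit")
  edf <- best$edf_target
  grids <- list(mu = config$edf_mu, sigma = config$edf_sigma,
                nu = config$edf_nu, tau = config$edf_tau)
  for (k in .PARAM_NAMES) {
    for (e in grids[[k]]) {
      if (e == edf[[k]]) next
      trial <- edf; trial[[k]] <- e
      m <- fits_ok(fit_model(age, value, weights, family, log_scale,
                             zeta = best$zeta, edf = trial, config = config,
                             dither_seed = dither_seed))
      if (verbose && !is.null(m))
        message(sprintf("edf[%s]=%g  SBC=%.2f", k, e, m$sbc))
      if (!is.null(m) && m$sbc < best$sbc) { best <- m; edf <- trial }
    }
  }
  best
}

#' Serialize / restore a fitted model
#'
#' The model file is self-describing JSON: family, scale flag, `zeta`,
#' knots, spline coefficients, effective df, sample size, SBC and the
#' recorded dither seed.
#'
#' @param model A `"centile_model"`.
#' @param path Output (input) file path.
#' @return `read_centile_model()` returns the restored model;
#'   `write_centile_model()` returns `path` invisibly.
#' @export
write_centile_model <- function(model, path) {
  stopifnot(inherits(model, "centile_model"))
  obj <- unclass(model)
  obj$dev_trace <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_centile_model
#' @export
read_centile_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coef <- lapply(obj$coef, as.numeric)
  obj$lambda <- lapply(obj$lambda, function(x) if (is.null(x)) NA else x)
  obj$edf <- unlist(obj$edf)
  obj$edf_target <- unlist(obj$edf_target)
  obj$dev_trace <- numeric(0)
  structure(obj, class = "centile_model")
}
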