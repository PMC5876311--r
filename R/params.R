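#' Four-parameter Box-Cox family parameters
#'
#' Container for the parameters of a Box-Cox power exponential (BCPE) or
#' Box-Cox t (BCT) distribution at a single age: `mu` (location, the exact
#' median), `sigma` (relative dispersion), `nu` (Box-Cox skewness power)
#' and `tau` (kurtosis: power-exponential exponent for BCPE, degrees of
#' freedom for BCT).
#'
#' With `tau = 2` the BCPE family coincides with the Box-Cox normal (LMS)
#' family; the BCT family converges to it as `tau` grows large.
#'
#' @param family `"BCPE"` or `"BCT"`.
#' @param mu Location, `> 0`. On the natural-log scale for log-scale models.
#' @param sigma Relative dispersion, `> 0` (dimensionless).
#' @param nu Skewness power (any real).
#' @param tau Kurtosis parameter, `> 0`.
#' @return An object of class `"family_params"`.
#' @examples
#' family_params("BCPE", mu = 100, sigma = 0.1, nu = 1, tau = 2)
#' @export
family_params <- function(family = c("BCPE", "BCT"), mu, sigma, nu, tau) {
  family <- match.arg(family)
  stopifnot(is.numeric(mu), is.numeric(sigma), is.numeric(nu), is.numeric(tau))
  if (any(!is.finite(c(mu, sigma, nu, tau))))
    stop("family parameters must be finite")
  if (any(mu <= 0)) stop("mu must be > 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(tau <= 0)) stop("tau must be > 0")
  structure(list(family = family, mu = mu, sigma = sigma, nu = nu, tau = tau),
            class = "family_params")
}

#' @export
print.family_params <- function(x, ...) {
  cat(sprintf("<%s>  mu=%.6g  sigma=%.6g  nu=%.4g  tau=%.6g\n",
              x$family, x$mu[1], x$sigma[1], x$nu[1], x$tau[1]))
  if (length(x$mu) > 1L)
    cat(sprintf("  (vectorized over %d parameter sets)\n", length(x$mu)))
  invisible(x)
}

.check_params <- function(params) {
  if (!inherits(params, "family_params"))
    stop("`params` must be a family_params object")
  params
}
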