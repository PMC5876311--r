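# Inverse fitting: recover (mu, sigma, nu, tau) from a set of known centiles.
#
# This is how the synthetic-data generator is anchored to published
# age-by-centile reference tables: each printed table row is inverted into
# the four parameters of the distribution that generated it.

#' Fit BCPE/BCT parameters to known centiles
#'
#' Recovers `(mu, sigma, nu, tau)` from at least four `(p, value)` centile
#' points.  With more than four points the sum of squared quantile
#' residuals is minimized over `(log mu, log sigma, nu, log tau)`; with
#' exactly four points the least-squares solution is polished by damped
#' Newton root-finding on the 4x4 system so residuals fall below `1e-8` on
#' the value scale.
#'
#' @param points Data frame with columns `p` (centile rank in (0,100)) and
#'   `value` (positive, strictly increasing in `p`).
#' @param family `"BCPE"` or `"BCT"`.
#' @param log_scale If `TRUE`, values are log-transformed before fitting
#'   (the respiratory-rate convention) and the returned parameters describe
#'   the distribution of `log(value)`; predictions must be exponentiated.
#' @param tau_bounds Box constraint on `tau`; defaults to `[0.5, 200]` for
#'   BCPE and `[1, 1e6]` for BCT.
#' @return A [family_params()] object with attributes `residuals` (per
#'   input point, value scale), `rss`, `log_scale` and `converged`.
#' @examples
#' pts <- data.frame(p = c(5, 25, 75, 95),
#'                   value = qnorm(c(.05, .25, .75, .95), 100, 10))
#' fit_params_to_centiles(pts, "BCPE")  # recovers mu=100 sigma=0.1 nu=1 tau=2
#' @export
fit_params_to_centiles <- function(points, family = c("BCPE", "BCT"),
                                   log_scale = FALSE, tau_bounds = NULL) {
  family <- match.arg(family)
  stopifnot(is.data.frame(points), all(c("p", "value") %in% names(points)))
  p <- as.numeric(points$p)
  v <- as.numeric(points$value)
  if (length(p) < 4L) stop("at least 4 centile points are required")
  if (anyDuplicated(p)) stop("centile ranks p must be distinct")
  if (any(p <= 0) || any(p >= 100)) stop("p must lie in (0, 100)")
  if (any(v <= 0)) stop("values must be > 0")
  o <- order(p)
  p <- p[o]; v <- v[o]
  # ties between neighboring values are tolerated (integer-rounding
  # artifacts in published tables); decreases are genuine non-monotonicity
  if (any(diff(v) < 0))
    stop("values must be non-decreasing in p (non-monotone input)")
  if (length(p) == 4L && any(diff(v) == 0))
    stop("exact 4-point inversion requires strictly increasing values")
  if (is.null(tau_bounds))
    tau_bounds <- if (family == "BCPE") c(0.5, 200) else c(1, 1e6)

  vfit <- if (log_scale) log(v) else v
  pr <- p / 100

  resid_fun <- function(th) {
    tau <- exp(th[4])
    par <- list(family = family, mu = exp(th[1]), sigma = exp(th[2]),
                nu = th[3], tau = min(max(tau, tau_bounds[1]), tau_bounds[2]))
    q <- .bc_quantile_raw(par, pr)
    if (any(!is.finite(q))) return(NULL)
    q - vfit
  }
  obj <- function(th) {
    r <- resid_fun(th)
    if (is.null(r)) return(1e10)
    pen <- 0
    tau <- exp(th[4])
    if (tau < tau_bounds[1]) pen <- pen + 1e6 * (log(tau_bounds[1] / tau))^2
    if (tau > tau_bounds[2]) pen <- pen + 1e6 * (log(tau / tau_bounds[2]))^2
    sum(r^2) + pen
  }

  # normal-case moment-matched start
  mu0 <- stats::approx(p, vfit, xout = 50, rule = 2)$y
  q25 <- stats::approx(p, vfit, xout = 25, rule = 2)$y
  q75 <- stats::approx(p, vfit, xout = 75, rule = 2)$y
  sig0 <- max((q75 - q25) / (2 * 0.6745 * abs(mu0)), 1e-3)
  th <- c(log(abs(mu0)), log(sig0), 1, log(if (family == "BCPE") 2 else 10))

  fit <- stats::optim(th, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  th <- fit$par
  converged <- fit$convergence == 0L

  if (length(p) == 4L) {
    # polish: damped Newton with numerical Jacobian on the exact system
    for (it in 1:40) {
      r <- resid_fun(th)
      if (is.null(r) || max(abs(r)) < 1e-10) break
      J <- matrix(0, 4, 4)
      h <- 1e-6
      for (j in 1:4) {
        thp <- th; thp[j] <- thp[j] + h
        rp <- resid_fun(thp)
        if (is.null(rp)) { J <- NULL; break }
        J[, j] <- (rp - r) / h
      }
      if (is.null(J)) break
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        rn <- resid_fun(th - lam * step)
        if (!is.null(rn) && sum(rn^2) < sum(r^2)) { th <- th - lam * step; break }
        lam <- lam / 2
        if (lam < 1e-6) break
      }
      if (lam < 1e-6) break
    }
    r <- resid_fun(th)
    if (is.null(r) || max(abs(r)) > 1e-8)
      stop(sprintf("4-point inversion did not converge (best max residual %.3g)",
                   if (is.null(r)) Inf else max(abs(r))))
    converged <- TRUE
  }

  r <- resid_fun(th)
  out <- family_params(family, mu = exp(th[1]), sigma = exp(th[2]),
                       nu = th[3],
                       tau = min(max(exp(th[4]), tau_bounds[1]), tau_bounds[2]))
  pred <- .bc_quantile_raw(out, pr)
  resid_value_scale <- if (log_scale) exp(pred) - v else pred - v
  attr(out, "residuals") <- resid_value_scale
  attr(out, "rss") <- sum(r^2)
  attr(out, "log_scale") <- log_scale
  attr(out, "converged") <- converged
  out
}
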