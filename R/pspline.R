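# P-spline internals: cubic B-spline basis on equally spaced knots with a
# second-order difference penalty, and penalized weighted least squares
# with the penalty weight solved to match a target effective df.

# knot vector for `n_interior` equally spaced interior knots over [xl, xr],
# extended by `degree` knots each side (Eilers-Marx construction)
.ps_knots <- function(xl, xr, n_interior = 20L, degree = 3L) {
  if (xr <= xl) stop("degenerate x range for spline basis")
  nseg <- n_interior + 1L
  dx <- (xr - xl) / nseg
  seq(xl - degree * dx, xr + degree * dx, by = dx)
}

.ps_basis <- function(x, knots, degree = 3L) {
  x <- pmin(pmax(x, knots[degree + 1L]), knots[length(knots) - degree])
  splines::splineDesign(knots, x, ord = degree + 1L, outer.ok = TRUE)
}

.ps_penalty <- function(ncoef, order = 2L) {
  D <- diff(diag(ncoef), differences = order)
  crossprod(D)
}

.ps_edf <- function(A, P, lambda) {
  sum(diag(solve(A + lambda * P + diag(1e-8 * mean(diag(A)), nrow(A)), A)))
}

# solve for lambda giving the target edf; A = B'WB (aggregated)
.ps_lambda_for_edf <- function(A, P, target) {
  lo <- -8; hi <- 14
  f <- function(l) .ps_edf(A, P, 10^l) - target
  if (f(lo) <= 0) return(10^lo)       # even near-unpenalized is too smooth
  if (f(hi) >= 0) return(10^hi)       # cannot reach so few df; max smooth
  10^stats::uniroot(f, c(lo, hi), tol = 1e-3)$root
}

# penalized WLS given aggregated normal equations
.ps_solve <- function(A, b, P, lambda) {
  solve(A + lambda * P + diag(1e-8 * mean(diag(A)), nrow(A)), b)
}
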