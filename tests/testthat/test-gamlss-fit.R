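# Age-smooth fitting: dither, backfitting, selection, prediction

test_that("transform_age is a monotone power map", {
  expect_equal(transform_age(4, 0.5), 2)
  x <- c(0.05, 0.5, 3, 17.5)
  expect_equal(transform_age(x, 1), x)
  expect_true(all(diff(transform_age(x, 0.3)) > 0))
  expect_error(transform_age(1, 0.001))
})

test_that("rr_preprocess dithers within +/-2 and is reproducible", {
  rr <- rep(20, 1e5)
  a <- rr_preprocess(rr, seed = 5)
  b <- rr_preprocess(rr, seed = 5)
  expect_identical(a, b)
  expect_true(all(a > log(18) & a < log(22)))
  # mean perturbation -> 0 (CLT bound for the truncated normal)
  expect_lt(abs(mean(exp(a)) - 20), 0.02)
  lo <- rr_preprocess(rep(1.5, 500), seed = 6)
  expect_true(all(is.finite(lo)))  # redraw keeps dithered values positive
})

test_that("single-age fit agrees with an independent ML oracle", {
  truth <- family_params("BCPE", 120, 0.1, 0.8, 2.2)
  y <- bc_sample(truth, 3000, seed = 21)
  m <- fit_model(rep(2.5, 3000), y, family = "BCPE")
  got <- predict_params(m, 2.5)

  # oracle: direct likelihood maximization with a different optimizer path
  nll <- function(th) -sum(log(bc_pdf(
    family_params("BCPE", th[1], th[2], th[3], th[4]), y)))
  o <- optim(c(median(y), sd(y) / median(y), 0.5, 3), nll,
             method = "L-BFGS-B",
             lower = c(50, 0.01, -3, 0.5), upper = c(250, 1, 4, 20),
             control = list(factr = 1e4))
  expect_equal(got$mu, o$par[1], tolerance = 1e-4)
  expect_equal(got$sigma, o$par[2], tolerance = 1e-3)
  expect_equal(got$nu, o$par[3], tolerance = 1e-2)
  expect_equal(got$tau, o$par[4], tolerance = 1e-2)
})

test_that("age-constant truth is recovered across the age range", {
  set.seed(31)
  truth <- family_params("BCPE", 120, 0.1, 0.8, 2.2)
  ages <- age_grid()$age_years
  age <- sample(ages, 50000, replace = TRUE)
  y <- bc_sample(truth, 50000)
  m <- fit_model(age, y, family = "BCPE", zeta = 0.4,
                 edf = c(mu = 3, sigma = 2, nu = 2, tau = 2))
  pp <- predict_params(m, c(0.5, 5, 15))
  expect_equal(pp$mu, rep(120, 3), tolerance = 0.01)
  expect_true(all(abs(pp$nu - 0.8) < 0.15))
  expect_true(all(abs(pp$sigma - 0.1) / 0.1 < 0.05))
})

test_that("a decreasing location trend yields a decreasing median curve", {
  set.seed(32)
  age <- runif(20000, 0.1, 17.5)
  mu <- 150 - 5 * age
  y <- rnorm(20000, mu, 0.08 * mu)
  m <- fit_model(age, y, family = "BCPE", zeta = 1,
                 edf = c(mu = 5, sigma = 3, nu = 2, tau = 2))
  med <- predict_params(m, seq(0.5, 17, by = 0.5))$mu
  expect_true(all(diff(med) < 0))
})

test_that("penalized deviance is non-increasing over backfitting cycles", {
  fx <- get_test_model("hr")
  expect_true(all(diff(fx$dev_trace) <= 1e-6 * abs(fx$dev_trace[-1]) + 1e-6))
  expect_true(fx$converged)
})

test_that("SBC selection recovers the age power parameter", {
  cfg <- fit_config(zeta_grid = c(0.1, 0.2, 0.3, 0.4, 0.6, 1.0),
                    edf_mu = c(3, 5), edf_sigma = c(2, 3),
                    edf_nu = 2, edf_tau = 2,
                    edf_start = c(mu = 5, sigma = 3, nu = 2, tau = 2))
  ages <- exp(seq(log(0.05), log(17.5), length.out = 30))
  set.seed(99)
  picks <- replicate(20, {
    age <- sample(ages, 3000, replace = TRUE)
    mu <- 120 * exp(-0.9 * age^0.3)
    y <- mu * exp(0.15 * rnorm(length(age)))
    select_model(age, y, family = "BCPE", config = cfg)$zeta
  })
  expect_gte(mean(picks %in% c(0.2, 0.3, 0.4)), 0.9)
})

test_that("selected model attains the SBC minimum over its grid", {
  set.seed(41)
  age <- sample(age_grid()$age_years, 4000, replace = TRUE)
  y <- (140 - 4 * age) * exp(0.1 * rnorm(4000))
  cfg <- fit_config(zeta_grid = c(0.3, 0.6, 1.0), edf_mu = c(3, 5),
                    edf_sigma = 2, edf_nu = 2, edf_tau = 2,
                    edf_start = c(mu = 3, sigma = 2, nu = 2, tau = 2))
  best <- select_model(age, y, family = "BCPE", config = cfg)
  # independently evaluate the zeta grid at the starting edf
  sbcs <- vapply(cfg$zeta_grid, function(z) {
    fit_model(age, y, family = "BCPE", zeta = z, edf = cfg$edf_start,
              config = cfg)$sbc
  }, numeric(1))
  expect_lte(best$sbc, min(sbcs) + 1e-6)
})

test_that("selected complexity does not grow unboundedly with n", {
  cfg <- fit_config(zeta_grid = 0.5, edf_mu = c(2, 3, 5, 8, 12),
                    edf_sigma = c(2, 3), edf_nu = 2, edf_tau = 2,
                    edf_start = c(mu = 3, sigma = 2, nu = 2, tau = 2))
  ages <- age_grid()$age_years
  gen <- function(n, seed) {
    set.seed(seed)
    age <- sample(ages, n, replace = TRUE)
    mu <- 140 - 4 * age
    list(age = age, y = mu * exp(0.1 * rnorm(n)))
  }
  d1 <- gen(3000, 51); d2 <- gen(12000, 52)
  e1 <- sum(select_model(d1$age, d1$y, family = "BCPE", config = cfg)$edf_target)
  e2 <- sum(select_model(d2$age, d2$y, family = "BCPE", config = cfg)$edf_target)
  expect_lte(e2, e1 + 3)
})

test_that("predict_params is smooth, median-consistent and guards range", {
  m <- get_test_model("hr")
  a <- c(0.5, 2, 9)
  p1 <- predict_params(m, a)
  p2 <- predict_params(m, a + 1e-6)
  for (k in c("mu", "sigma", "nu", "tau"))
    expect_equal(p1[[k]], p2[[k]], tolerance = 1e-4)
  # median curve round-trip
  pr <- predict_params(m, a)
  med <- vapply(seq_along(a), function(i) bc_quantile(
    family_params(m$family, pr$mu[i], pr$sigma[i], pr$nu[i], pr$tau[i]), 50),
    numeric(1))
  expect_equal(med, pr$mu, tolerance = 1e-12)
  expect_warning(predict_params(m, 25), "extrapolating")
})

test_that("model serialization round-trips", {
  m <- get_test_model("hr")
  f <- tempfile(fileext = ".json")
  write_centile_model(m, f)
  m2 <- read_centile_model(f)
  a <- c(0.25, 3.5, 12.5)
  expect_equal(predict_params(m2, a), predict_params(m, a), tolerance = 1e-12)
  expect_equal(m2$sbc, m$sbc)
  expect_equal(m2$family, m$family)
  unlink(f)
})

test_that("fit guards: too few observations, link integrity", {
  expect_error(fit_model(1:10, rnorm(10, 100, 5), family = "BCPE"),
               "at least 200")
})
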