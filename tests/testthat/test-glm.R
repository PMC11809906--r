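test_that("Poisson fits match the independent likelihood oracle", {
  set.seed(101)
  for (i in 1:3) {
    x <- runif(8, 0, 1)
    y <- rpois(8, 5 * exp(2 + 1.5 * x))
    fit <- fit_count_glm(make_panel(y, x), "total", "visual", "poisson",
                         "linear")
    expect_lt(max(abs(fit$coefficients$estimate -
                        oracle_poisson(y, x, 5))), 1e-6)
  }
  # quadratic, n = 10
  x <- runif(10, 0, 1)
  y <- rpois(10, 5 * exp(2 + 2 * x - 0.8 * x^2))
  fit <- fit_count_glm(make_panel(y, x), "total", "visual", "poisson",
                       "quadratic")
  expect_lt(max(abs(fit$coefficients$estimate -
                      oracle_poisson(y, x, 5, quadratic = TRUE))), 1e-6)
})

test_that("negative binomial fits match the oracle in beta and theta", {
  set.seed(102)
  x <- runif(10, 0, 1)
  y <- MASS::rnegbin(10, 5 * exp(2 + 1.5 * x), theta = 3)
  fit <- fit_count_glm(make_panel(y, x), "total", "visual",
                       "negative_binomial", "linear")
  o <- oracle_negbin(y, x, 5)
  expect_lt(max(abs(fit$coefficients$estimate - o$beta)), 1e-6)
  expect_lt(abs(fit$dispersion - o$theta) / o$theta, 1e-4)
})

test_that("fit bookkeeping invariants hold", {
  set.seed(103)
  x <- runif(30, 0, 1)
  y <- rpois(30, 5 * exp(2 + x))
  fit <- fit_count_glm(make_panel(y, x), "total", "visual", "poisson",
                       "quadratic")
  co <- fit$coefficients
  expect_true(all(co$ci_lower <= co$estimate & co$estimate <= co$ci_upper))
  expect_equal(fit$n_points, 30L)
  ll <- stats::logLik(fit$glm)
  expect_equal(fit$aic, 2 * attr(ll, "df") - 2 * as.numeric(ll))
})

test_that("a constant response yields a null slope and log-mean intercept", {
  panel <- make_panel(rep(12L, 12), seq(0, 1, length.out = 12))
  fit <- fit_count_glm(panel, "total", "visual", "poisson", "linear")
  co <- fit$coefficients
  expect_true(co$ci_lower[2] <= 0 && 0 <= co$ci_upper[2])
  expect_equal(co$estimate[1], log(12 / 5), tolerance = 0.05)
})

test_that("exposure offset behaves exactly under area rescaling", {
  set.seed(104)
  x <- runif(20, 0, 1)
  y <- rpois(20, 5 * exp(2 + x))
  f1 <- fit_count_glm(make_panel(y, x), "total", "visual", "poisson",
                      "linear", area = 5)
  f2 <- fit_count_glm(make_panel(y, x), "total", "visual", "poisson",
                      "linear", area = 10)
  expect_equal(f1$coefficients$estimate[2], f2$coefficients$estimate[2],
               tolerance = 1e-8)
  expect_equal(f2$coefficients$estimate[1],
               f1$coefficients$estimate[1] - log(2), tolerance = 1e-8)
  # doubling both counts and area is weight duplication: identical fit
  f3 <- fit_count_glm(make_panel(2L * y, x), "total", "visual", "poisson",
                      "linear", area = 10)
  expect_equal(f3$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("NB fits approach Poisson fits on equidispersed data", {
  set.seed(105)
  x <- runif(60, 0, 1)
  y <- rpois(60, 5 * exp(2 + x))
  fp <- fit_count_glm(make_panel(y, x), "total", "visual", "poisson",
                      "linear")
  fn <- fit_count_glm(make_panel(y, x), "total", "visual",
                      "negative_binomial", "linear")
  expect_gt(fn$dispersion, 100)   # variance ~ mean
  expect_lt(max(abs(fp$coefficients$estimate - fn$coefficients$estimate)),
            1e-3)
})

test_that("degenerate and undersized panels are rejected", {
  expect_error(fit_count_glm(make_panel(c(1L, 2L, 3L), c(0, 0.5, 1)),
                             "total", "visual", "poisson", "quadratic"),
               "5 points|panel rows")
  expect_error(fit_count_glm(make_panel(c(1.5, 2, 3, 4, 5, 6),
                                        seq(0, 1, length.out = 6)),
                             "total", "visual", "poisson", "linear"),
               "integer")
  expect_error(fit_count_glm(make_panel(1:6, c(-0.1, seq(0.2, 1,
                                                         length.out = 5))),
                             "total", "visual", "poisson", "linear"),
               "non-negative")
})

test_that("Pearson GOF is exact at a perfect fit and calibrated under the null", {
  # constant response: fitted == observed, X2 = 0, p = 1
  fit0 <- fit_count_glm(make_panel(rep(9L, 8), seq(0, 1, length.out = 8)),
                        "total", "visual", "poisson", "linear")
  expect_equal(fit0$gof$statistic, 0, tolerance = 1e-10)
  expect_equal(fit0$gof$p_value, 1)
  # null calibration: p-values roughly uniform across replicates
  set.seed(106)
  pvals <- replicate(200, {
    x <- runif(50, 0, 1)
    y <- rpois(50, 5 * exp(1.5 + 1.2 * x))
    fit_count_glm(make_panel(y, x), "total", "visual", "poisson",
                  "linear")$gof$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  # power: strong overdispersion is flagged far more often than 5%
  rej <- mean(replicate(100, {
    x <- runif(50, 0, 1)
    y <- MASS::rnegbin(50, 5 * exp(1.5 + 1.2 * x), theta = 1)
    fit_count_glm(make_panel(y, x), "total", "visual", "poisson",
                  "linear")$gof$p_value < 0.05
  }))
  expect_gt(rej, 0.5)
})

test_that("density predictions follow the fitted curve geometry", {
  set.seed(107)
  x <- runif(80, 0, 1)
  y <- rpois(80, 5 * exp(2.45 + 3.58 * x - 0.82 * x^2))
  fit <- fit_count_glm(make_panel(y, x), "total", "visual", "poisson",
                       "quadratic")
  b <- fit$coefficients$estimate
  expect_lt(b[3], 0)
  apex <- -b[2] / (2 * b[3])
  grid <- seq(0, min(apex, max(x)), length.out = 50)
  pred <- predict_density(fit, grid)
  expect_true(all(diff(pred$predicted) > 0))  # increasing below the apex
  expect_true(all(pred$ci_lower <= pred$predicted &
                    pred$predicted <= pred$ci_upper))
  # intervals widen toward the edge of the fitted range
  w <- function(v) {
    p <- predict_density(fit, v)
    log(p$ci_upper) - log(p$ci_lower)
  }
  expect_gt(w(max(x)), w(mean(x)))
  expect_true(predict_density(fit, max(x) + 0.5)$extrapolated)
  expect_false(predict_density(fit, mean(x))$extrapolated)
})

test_that("prediction at zero CPUE is the intercept density", {
  panel <- make_panel(rep(10L, 10), seq(0, 1, length.out = 10))
  fit <- fit_count_glm(panel, "total", "visual", "poisson", "linear")
  p0 <- predict_density(fit, 0)
  expect_equal(p0$predicted, exp(fit$coefficients$estimate[1]))
})

test_that("AIC term selection finds the generating form", {
  set.seed(108)
  pick <- function(b2) {
    x <- runif(200, 0, 0.93)
    y <- rpois(200, 5 * exp(2.45 + 3.58 * x + b2 * x^2))
    select_terms(make_panel(y, x), "total", "visual", "poisson")$chosen
  }
  lin <- replicate(10, pick(0))
  qua <- replicate(10, pick(-0.82))
  expect_gte(mean(lin == "linear"), 0.9)
  expect_gte(mean(qua == "quadratic"), 0.9)
})

test_that("select_terms degrades gracefully when one candidate fails", {
  panel <- make_panel(c(3L, 4L, 5L, 6L), c(0, 0.3, 0.6, 0.9))  # n = 4
  expect_warning(out <- select_terms(panel, "total", "visual", "poisson"),
                 "surviving")
  expect_s3_class(out$best, "cpue_glm_fit")
  expect_equal(out$chosen, "linear")
  expect_null(out$quadratic)
})
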