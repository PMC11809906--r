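#' Count regression of abundance on CPUE
#'
#' Fits a log-link count GLM relating monthly true abundance to monthly
#' CPUE, the calibration at the heart of index validation. The response is
#' the integer monthly count (total snakes, or the trap-susceptible
#' > 900 mm segment) with `log(area)` as a fixed exposure offset, so the
#' coefficients describe density (snakes/ha): the fitted mean density is
#' `exp(b0 + b1 * CPUE [+ b2 * CPUE^2])`. Fitting counts with an offset
#' rather than the non-integer density keeps the Poisson/negative binomial
#' likelihood valid while leaving the coefficients on the density scale.
#'
#' Families: `"poisson"`, or `"negative_binomial"` (NB2, mean-dispersion
#' parameterisation, dispersion estimated by maximum likelihood via
#' [MASS::glm.nb()]). Confidence intervals are Wald (symmetric on the link
#' scale).
#'
#' @param panel a `monthly_panel` (see [build_panel()]).
#' @param response `"total"` (all snakes vs visual CPUE) or `"gt900"`
#'   (trap-susceptible snakes, typically vs trap CPUE).
#' @param predictor `"visual"` or `"trap"` CPUE.
#' @param family `"poisson"` or `"negative_binomial"`.
#' @param terms `"linear"` or `"quadratic"` in CPUE.
#' @param area exposure area in ha (default 5).
#' @param conf_level Wald interval level.
#' @return object of class `cpue_glm_fit`: coefficient table (`estimate`,
#'   `se`, `ci_lower`, `ci_upper`, `z`), `family`, `terms`, `dispersion`
#'   (NB theta or NA), `gof` (Pearson chi-square test), `n_points`,
#'   `log_likelihood`, `aic`, the underlying `glm` object, and the fitted
#'   CPUE range.
#' @export
fit_count_glm <- function(panel, response = c("total", "gt900"),
                          predictor = c("visual", "trap"),
                          family = c("poisson", "negative_binomial"),
                          terms = c("quadratic", "linear"),
                          area = 5, conf_level = 0.95) {
  response <- match.arg(response)
  predictor <- match.arg(predictor)
  family <- match.arg(family)
  terms <- match.arg(terms)
  y <- if (response == "total") panel$n_total else panel$n_gt900
  x <- if (predictor == "visual") panel$cpue_visual else panel$cpue_trap
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (any(x < 0)) stop("CPUE must be non-negative", call. = FALSE)
  if (any(y < 0) || any(y != round(y)))
    stop("response must be non-negative integer counts", call. = FALSE)
  k <- if (terms == "quadratic") 3L else 2L
  if (length(y) < k + 2L)
    stop(sprintf("need at least %d usable panel rows for a %s fit, got %d",
                 k + 2L, terms, length(y)), call. = FALSE)
  if (terms == "quadratic" && length(y) < 5L)
    stop("quadratic term requested with fewer than 5 points", call. = FALSE)

  dat <- data.frame(y = y, x = x, off = log(area))
  form <- if (terms == "quadratic") y ~ x + I(x^2) + offset(off)
          else y ~ x + offset(off)
  fit <- if (family == "poisson") {
    stats::glm(form, family = stats::poisson(), data = dat,
               control = stats::glm.control(maxit = 100))
  } else {
    suppressWarnings(MASS::glm.nb(form, data = dat, maxit = 100))
  }
  if (!fit$converged)
    stop(sprintf("%s GLM did not converge in %d iterations (%s terms)",
                 family, 100L, terms), call. = FALSE)
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(
    term = c("(Intercept)", "cpue", "cpue^2")[seq_len(k)],
    estimate = unname(est), se = unname(se),
    ci_lower = unname(est - zq * se), ci_upper = unname(est + zq * se),
    z = unname(est / se),
    stringsAsFactors = FALSE
  )
  theta <- if (family == "negative_binomial") fit$theta else NA_real_
  out <- structure(list(
    family = family, terms = terms, response = response,
    predictor = predictor, area = area,
    coefficients = coefs,
    dispersion = theta,
    n_points = length(y),
    log_likelihood = as.numeric(stats::logLik(fit)),
    aic = stats::AIC(fit),
    cpue_range = range(x),
    glm = fit
  ), class = "cpue_glm_fit")
  out$gof <- gof_chisq(out)
  out
}

#' Pearson chi-square goodness-of-fit test
#'
#' Pearson `X^2 = sum((obs - fitted)^2 / V(fitted))` against a chi-square
#' distribution with `n - k` degrees of freedom, where the family variance
#' is `V(mu) = mu` (Poisson) or `mu + mu^2 / theta` (NB2). A small p-value
#' flags overdispersion or structural misfit relative to the assumed
#' distribution.
#'
#' @param fit a `cpue_glm_fit`.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
gof_chisq <- function(fit) {
  mu <- stats::fitted(fit$glm)
  if (any(mu <= 0)) stop("zero fitted mean in goodness-of-fit", call. = FALSE)
  obs <- fit$glm$y
  v <- if (fit$family == "poisson") mu else mu + mu^2 / fit$dispersion
  x2 <- sum((obs - mu)^2 / v)
  k <- length(stats::coef(fit$glm))
  df <- max(fit$n_points - k, 1L)
  list(statistic = x2, df = df,
       p_value = stats::pchisq(x2, df, lower.tail = FALSE))
}

#' Predict density (with 95% CI) from CPUE
#'
#' Point prediction `exp(linear predictor) / area` snakes/ha, with the
#' Wald interval on the linear predictor exponentiated — an interval for
#' the mean density, not a prediction interval for new monthly counts.
#' Values outside the fitted CPUE range are returned but flagged as
#' extrapolation.
#'
#' @param fit a `cpue_glm_fit`.
#' @param cpue_values numeric vector of CPUE values.
#' @param conf_level interval level.
#' @return data.frame: `cpue`, `predicted` (snakes/ha), `ci_lower`,
#'   `ci_upper`, `extrapolated`.
#' @export
predict_density <- function(fit, cpue_values, conf_level = 0.95) {
  x <- as.numeric(cpue_values)
  k <- nrow(fit$coefficients)
  X <- cbind(1, x, if (k == 3L) x^2)
  beta <- fit$coefficients$estimate
  eta <- drop(X %*% beta)          # log mean density (offset already folded out)
  V <- stats::vcov(fit$glm)
  se <- sqrt(rowSums((X %*% V) * X))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    cpue = x,
    predicted = exp(eta),
    ci_lower = exp(eta - zq * se),
    ci_upper = exp(eta + zq * se),
    extrapolated = x < fit$cpue_range[1] | x > fit$cpue_range[2]
  )
}

#' Choose between linear and quadratic CPUE terms
#'
#' Fits both candidate models and keeps the lower-AIC one, with a
#' parsimony tie-break in favour of the linear term. If one candidate
#' fails to fit (e.g. too few points for a quadratic), the survivor is
#' returned with a warning.
#'
#' @inheritParams fit_count_glm
#' @return list: `best` (a `cpue_glm_fit`), `chosen` ("linear" or
#'   "quadratic"), `linear`, `quadratic` (NULL on failure).
#' @export
select_terms <- function(panel, response = "total", predictor = "visual",
                         family = "poisson", area = 5) {
  lin <- tryCatch(fit_count_glm(panel, response, predictor, family,
                                terms = "linear", area = area),
                  error = function(e) e)
  qua <- tryCatch(fit_count_glm(panel, response, predictor, family,
                                terms = "quadratic", area = area),
                  error = function(e) e)
  lin_ok <- inherits(lin, "cpue_glm_fit")
  qua_ok <- inherits(qua, "cpue_glm_fit")
  if (!lin_ok && !qua_ok)
    stop("both candidate models failed: ", conditionMessage(lin),
         call. = FALSE)
  if (!lin_ok || !qua_ok) {
    fail <- if (lin_ok) "quadratic" else "linear"
    warning(sprintf("%s fit failed; returning the surviving model", fail))
    best <- if (lin_ok) lin else qua
    return(list(best = best, chosen = best$terms,
                linear = if (lin_ok) lin else NULL,
                quadratic = if (qua_ok) qua else NULL))
  }
  chosen <- if (qua$aic < lin$aic) "quadratic" else "linear"  # tie -> linear
  list(best = if (chosen == "quadratic") qua else lin,
       chosen = chosen, linear = lin, quadratic = qua)
}

#' @export
print.cpue_glm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cpue_glm_fit> %s, %s CPUE term(s); response '%s' ~ %s CPUE\n",
              x$family, x$terms, x$response, x$predictor))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (!is.na(x$dispersion))
    cat(sprintf("  dispersion (theta): %.*g\n", digits, x$dispersion))
  cat(sprintf("  n = %d, logLik = %.*f, AIC = %.*f\n", x$n_points,
              digits, x$log_likelihood, digits, x$aic))
  cat(sprintf("  Pearson GOF: X2 = %.*g on %d df, p = %.*g\n", digits,
              x$gof$statistic, x$gof$df, digits, x$gof$p_value))
  invisible(x)
}
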