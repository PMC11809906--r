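# Independent likelihood oracles and small fixture builders.
# The oracles maximise the hand-written log-likelihoods directly with
# optim(); they never touch glm()/glm.nb(), so they can arbitrate the
# fitting path.

pois_loglik <- function(b, y, X, off) {
  eta <- off + drop(X %*% b)
  sum(y * eta - exp(eta) - lgamma(y + 1))
}

pois_score <- function(b, y, X, off) {
  mu <- exp(off + drop(X %*% b))
  drop(crossprod(X, y - mu))
}

oracle_poisson <- function(y, x, area, quadratic = FALSE) {
  X <- cbind(1, x, if (quadratic) x^2)
  off <- rep(log(area), length(y))
  o <- stats::optim(numeric(ncol(X)), pois_loglik, gr = pois_score,
                    y = y, X = X, off = off, method = "BFGS",
                    control = list(fnscale = -1, reltol = 1e-15,
                                   maxit = 1000))
  o$par
}

nb_loglik <- function(p, y, X, off) {
  b <- p[-length(p)]
  th <- exp(p[length(p)])
  mu <- exp(off + drop(X %*% b))
  sum(lgamma(y + th) - lgamma(th) - lgamma(y + 1) +
        th * log(th / (th + mu)) + y * log(mu / (th + mu)))
}

oracle_negbin <- function(y, x, area, quadratic = FALSE) {
  X <- cbind(1, x, if (quadratic) x^2)
  off <- rep(log(area), length(y))
  o <- stats::optim(c(numeric(ncol(X)), 0), nb_loglik, y = y, X = X,
                    off = off,
                    control = list(fnscale = -1, reltol = 1e-15,
                                   maxit = 5000))
  o <- stats::optim(o$par, nb_loglik, y = y, X = X, off = off,
                    method = "BFGS",
                    control = list(fnscale = -1, reltol = 1e-15,
                                   maxit = 1000))
  list(beta = o$par[-length(o$par)], theta = exp(o$par[length(o$par)]))
}

# monthly_panel from bare count/CPUE vectors (area 5 ha unless given)
make_panel <- function(y, x, area = 5, y900 = NA, x_trap = NA) {
  n <- length(y)
  structure(data.frame(
    month = month_label(month_index("2018-01") + seq_len(n) - 1L),
    n_total = y, n_gt900 = y900,
    density = y / area, density_gt900 = y900 / area,
    cpue_visual = x, km_surveyed = 6.38, n_capture_visual = y,
    cpue_trap = x_trap, trap_nights_corrected = NA_real_,
    n_capture_trap = NA_integer_, stringsAsFactors = FALSE
  ), class = c("monthly_panel", "data.frame"))
}

# small fast simulator configuration (overridable defaults)
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(initial_abundance = 30, n_months = 12, monthly_survival = 0.95,
         monthly_birth_rate = 0.01, seed = 1L),
    list(...))
  do.call(sim_config, args)
}
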