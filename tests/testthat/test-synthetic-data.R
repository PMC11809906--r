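test_that("population with no dynamics stays constant", {
  cfg <- sim_config(initial_abundance = 25, n_months = 24,
                    monthly_survival = 1, monthly_birth_rate = 0, seed = 7)
  pop <- simulate_population(cfg)
  expect_equal(pop$truth$n_total, rep(25L, 24))
  expect_equal(pop$truth$births, rep(0L, 24))
  expect_equal(pop$truth$deaths, rep(0L, 24))
})

test_that("closure holds exactly: dN = births - deaths", {
  for (s in 1:5) {
    cfg <- sim_config(initial_abundance = 60, n_months = 36,
                      monthly_survival = 0.95, monthly_birth_rate = 0.03,
                      removal_schedule = data.frame(
                        month = c("2017-06", "2018-01"),
                        extra_mortality = c(0.3, 0.2)),
                      seed = s)
    tr <- simulate_population(cfg)$truth
    n <- tr$n_total
    # an individual dying in month t still counts as present in t, so
    # N(t+1) - N(t) = births(t+1) - deaths(t)
    expect_equal(diff(n), tr$births[-1] - tr$deaths[-nrow(tr)])
  }
})

test_that("paper-like preset declines from ~117 toward ~15 over 72 months", {
  finals <- vapply(1:10, function(s)
    utils::tail(simulate_population(paper_like_config(seed = s))$truth$n_total,
                1), 0L)
  expect_true(stats::median(finals) >= 10 && stats::median(finals) <= 40)
  pop <- simulate_population(paper_like_config(seed = 1))
  expect_gt(pop$truth$n_total[1], 100)
  expect_lt(mean(utils::tail(pop$truth$n_total, 6)),
            mean(utils::head(pop$truth$n_total, 6)) / 3)
})

test_that("identical config and seed reproduce identical tables", {
  cfg <- tiny_config(seed = 11)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$captures, d2$captures)
  expect_identical(d1$effort, d2$effort)
  expect_identical(d1$population$truth, d2$population$truth)
})

test_that("invalid rates are rejected with the field named", {
  expect_error(sim_config(monthly_survival = 1.2), "monthly_survival")
  expect_error(sim_config(monthly_survival = NA), "monthly_survival")
  expect_error(sim_config(trap_capture_prob = -0.1), "trap_capture_prob")
  expect_error(sim_config(hyperstability_beta = 0), "hyperstability_beta")
  expect_error(sim_config(monthly_birth_rate = Inf), "monthly_birth_rate")
})

test_that("zero catchability yields effort but no captures", {
  cfg <- tiny_config(catchability_q = 0, monthly_survival = 1,
                     monthly_birth_rate = 0)
  pop <- simulate_population(cfg)
  sched <- default_survey_schedule(cfg, nights_per_week = 2,
                                   gap_months = character())
  out <- simulate_visual_surveys(pop, sched, cfg)
  expect_equal(nrow(out$captures), 0L)
  expect_equal(nrow(out$effort), nrow(sched))
  expect_equal(out$effort$km, rep(29 * 0.220, nrow(sched)))
})

test_that("cumulative survey km equals nights x transects x 0.220 exactly", {
  cfg <- tiny_config()
  pop <- simulate_population(cfg)
  sched <- default_survey_schedule(cfg, nights_per_week = 3,
                                   gap_months = character())
  out <- simulate_visual_surveys(pop, sched, cfg)
  expect_equal(sum(out$effort$km), nrow(sched) * 29 * 0.220)
})

test_that("transect ids outside geometry are rejected", {
  cfg <- tiny_config()
  pop <- simulate_population(cfg)
  sched <- data.frame(night = month_start("2017-01"))
  sched$transects <- list(c(1L, 30L))
  expect_error(simulate_visual_surveys(pop, sched, cfg), "transect ids")
})

test_that("with beta = 1 mean nightly detections match q*N*coverage", {
  # fixed N = 50, ~2100 replicate nights under one long calendar
  cfg <- sim_config(initial_abundance = 50, n_months = 72,
                    monthly_survival = 1, monthly_birth_rate = 0,
                    catchability_q = 0.1, hyperstability_beta = 1, seed = 2)
  pop <- simulate_population(cfg)
  sched <- default_survey_schedule(cfg, nights_per_week = 7,
                                   gap_months = character())
  out <- simulate_visual_surveys(pop, sched, cfg)
  n_nights <- nrow(sched)
  expect_gt(n_nights, 2000)
  lambda <- 0.1 * 50 * coverage_fraction(29, cfg)   # closed form
  mean_det <- nrow(out$captures) / n_nights
  se <- sqrt(lambda / n_nights)
  expect_lt(abs(mean_det - lambda), 3 * se)
})

test_that("beta = 0.5 halving N changes CPUE by ~sqrt(2), not 2", {
  mean_cpue_at <- function(N, seed) {
    cfg <- sim_config(initial_abundance = N, n_months = 60,
                      monthly_survival = 1, monthly_birth_rate = 0,
                      catchability_q = 0.1, hyperstability_beta = 0.5,
                      seed = seed)
    pop <- simulate_population(cfg)
    sched <- default_survey_schedule(cfg, nights_per_week = 7,
                                     gap_months = character())
    out <- simulate_visual_surveys(pop, sched, cfg)
    nrow(out$captures) / sum(out$effort$km)
  }
  c100 <- mean_cpue_at(100, 21)
  c50 <- mean_cpue_at(50, 22)
  ratio <- c100 / c50
  expect_lt(abs(ratio - sqrt(2)), 0.25)  # far from the proportional ratio 2
  expect_gt(2 - ratio, 0.25)
})

test_that("trapping never captures snakes at or below the size threshold", {
  cfg <- tiny_config(initial_age_range_days = c(30, 60),
                     monthly_survival = 1, monthly_birth_rate = 0,
                     n_months = 6)
  pop <- simulate_population(cfg)   # all well under 900 mm
  out <- simulate_trapping(pop, data.frame(start = month_start("2017-01"),
                                           n_nights = 14), cfg)
  expect_equal(nrow(out$captures), 0L)
  expect_equal(nrow(out$effort), 14L)
})

test_that("empty bout schedule gives empty outputs, not an error", {
  cfg <- tiny_config()
  pop <- simulate_population(cfg)
  out <- simulate_trapping(pop, NULL, cfg)
  expect_equal(nrow(out$captures), 0L)
  expect_equal(nrow(out$effort), 0L)
})

test_that("bout captures match the closed-form per-individual risk", {
  # fixed susceptible N = 40 (all huge), p = 0.001, 169 traps x 14 nights
  cfg <- sim_config(initial_abundance = 40, n_months = 6,
                    monthly_survival = 1, monthly_birth_rate = 0,
                    initial_age_range_days = c(1000, 1100),
                    trap_capture_prob = 0.001, trap_inoperable_rate = 0,
                    seed = 31)
  pop <- simulate_population(cfg)
  expect_true(all(pop$truth$n_gt900 == 40L))
  bout <- data.frame(start = month_start("2017-01"), n_nights = 14)
  n_reps <- 40
  caught <- vapply(seq_len(n_reps), function(i) {
    out <- simulate_trapping(pop, bout, cfg, seed = 1000 + i)
    length(unique(out$captures$individual_id))
  }, 0L)
  p_any <- 1 - (1 - 0.001)^(169 * 14)
  se <- sqrt(40 * p_any * (1 - p_any) / n_reps)
  expect_lt(abs(mean(caught) - 40 * p_any), 3 * se)
})

test_that("strong prey modulation decouples trap CPUE from density", {
  # OLS of monthly trap CPUE on true susceptible density: slope CI should
  # cover 0 in >= 80% of replicate simulations
  covers <- vapply(1:20, function(s) {
    cfg <- paper_like_config(seed = s, prey_modulation_sd = 1.5)
    pop <- simulate_population(cfg)
    trp <- simulate_trapping(pop, default_trap_bouts(cfg), cfg)
    cp <- monthly_cpue(trp$captures, trp$effort, "trap")
    d <- pop$truth$density_gt900[match(cp$month, pop$truth$month)]
    f <- stats::lm(cp$cpue ~ d)
    ci <- stats::confint(f)["d", ]
    ci[1] <= 0 && 0 <= ci[2]
  }, NA)
  expect_gte(mean(covers), 0.8)
})
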