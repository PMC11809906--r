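test_that("back-dating reproduces the 682-mm worked example", {
  # 682 mm at 0.98 mm/day first seen in December 2017: ceil(282/0.98) =
  # 288 days before 1 Dec 2017 lands in February 2017
  for (day in c("2017-12-01", "2017-12-15", "2017-12-31"))
    expect_equal(backdate_presence(682, 0.98, as.Date(day)), "2017-02")
})

test_that("individuals below the threshold keep their detection month", {
  expect_equal(backdate_presence(350, 0.7, as.Date("2018-06-20")), "2018-06")
  expect_equal(backdate_presence(399.9, 2, as.Date("2018-06-01")), "2018-06")
})

test_that("a one-day back-step can cross a month boundary", {
  cfg <- census_config(anchor_day_policy = "exact-detection-date")
  expect_equal(backdate_presence(400.98, 0.98, as.Date("2018-03-01"), cfg),
               "2018-02")
  expect_equal(backdate_presence(400.98, 0.98, as.Date("2018-03-02"), cfg),
               "2018-03")
})

test_that("bad growth rates or sizes are rejected informatively", {
  expect_error(backdate_presence(500, 0, as.Date("2018-01-01"), id = "S001"),
               "S001")
  expect_error(backdate_presence(500, c(1, -2), as.Date("2018-01-01")),
               "growth rate")
  expect_error(backdate_presence(NaN, 1, as.Date("2018-01-01")), "SVL")
})

test_that("inferred first presence is monotone in the birth threshold", {
  # a higher threshold shortens the back-step (svl - threshold)/rate, so
  # first presence can only move later, never earlier
  set.seed(40)
  for (i in 1:50) {
    svl <- runif(1, 300, 1200)
    g <- runif(1, 0.3, 1.5)
    d <- as.Date("2016-10-24") + sample(0:2000, 1)
    lo <- backdate_presence(svl, g, d, census_config(birth_svl_threshold = 350))
    hi <- backdate_presence(svl, g, d, census_config(birth_svl_threshold = 450))
    expect_gte(month_index(hi), month_index(lo))
  }
})

test_that("density arithmetic matches printed counts over 5 ha", {
  p117 <- data.frame(individual_id = sprintf("S%03d", 1:117),
                     first_month = "2017-03", last_month = "2017-03")
  out <- enumerate_monthly(p117, area = 5)
  expect_equal(out$density, 23.4)
  # 85 of 117 above 900 mm that month -> 17 snakes/ha
  p117$ref_date <- as.Date("2017-03-01")
  p117$ref_svl <- c(rep(1000, 85), rep(500, 32))
  p117$growth_rate <- 1
  out <- enumerate_monthly(p117, area = 5)
  expect_equal(out$n_gt900, 85L)
  expect_equal(out$density_gt900, 17)
})

test_that("empty presence tables give an all-zero series", {
  months <- month_label(month_index("2017-01") + 0:5)
  out <- enumerate_monthly(data.frame(individual_id = character(),
                                      first_month = character(),
                                      last_month = character()),
                           area = 5, months = months)
  expect_equal(out$n_total, rep(0L, 6))
  expect_equal(out$density, rep(0, 6))
})

test_that("duplicate individuals are rejected", {
  p <- data.frame(individual_id = c("a", "a"),
                  first_month = c("2017-01", "2017-02"),
                  last_month = c("2017-03", "2017-04"))
  expect_error(enumerate_monthly(p, area = 5), "duplicate")
})

test_that("census round-trips the simulator truth under full detection", {
  # ideal conditions: birth SVL equals the census threshold, zero growth
  # heterogeneity error (true per-individual rates supplied), every
  # individual captured in every month it is alive, exact SVL records,
  # exact-date anchoring
  cfg <- sim_config(initial_abundance = 40, n_months = 24,
                    monthly_survival = 0.93, monthly_birth_rate = 0.04,
                    birth_svl = 400, seed = 13)
  pop <- simulate_population(cfg)
  ind <- pop$individuals
  m0 <- month_index(cfg$start_month)
  rows <- list()
  for (i in seq_len(nrow(ind))) {
    last <- if (is.na(ind$death_month[i])) m0 + cfg$n_months - 1L
            else ind$death_month[i]
    for (m in max(ind$birth_month[i], m0):last) {
      d <- max(month_start(m), ind$birth_date[i])
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = ind$id[i], date = d, method = "visual",
        location_id = "T01",
        svl_mm = cfg$birth_svl + ind$growth_rate[i] *
          as.numeric(d - ind$birth_date[i]),
        sex = ind$sex[i], stringsAsFactors = FALSE)
    }
  }
  captures <- do.call(rbind, rows)
  ccfg <- census_config(anchor_day_policy = "exact-detection-date")
  pres <- build_presence(captures, ccfg,
                         growth_rates = data.frame(
                           individual_id = ind$id,
                           growth_rate = ind$growth_rate))
  est <- enumerate_monthly(pres, area = 5, months = pop$truth$month,
                           config = ccfg)
  expect_equal(est$n_total, pop$truth$n_total)
  expect_equal(est$n_gt900, pop$truth$n_gt900)
})

test_that("default anchoring recovers birth month to within one month", {
  cfg <- sim_config(initial_abundance = 30, n_months = 18,
                    monthly_survival = 1, monthly_birth_rate = 0.05,
                    birth_svl = 400, seed = 14)
  pop <- simulate_population(cfg)
  ind <- pop$individuals
  det_date <- pmax(ind$birth_date + 200L, month_start(cfg$start_month))
  inferred <- backdate_presence(
    400 + ind$growth_rate * as.numeric(det_date - ind$birth_date),
    ind$growth_rate, det_date)   # first-of-detection-month policy
  err <- month_index(inferred) - ind$birth_month
  expect_true(all(abs(err) <= 1))
})
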