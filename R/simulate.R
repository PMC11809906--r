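#' Simulate a closed, declining population of individually growing snakes
#'
#' Individual-based birth-death simulation on a monthly clock inside a
#' fenced enclosure: no immigration or emigration, so every change in
#' abundance is attributable to a birth or a death (natural mortality plus
#' any scheduled removal pulses). Each individual carries a sex, a constant
#' growth rate (mm/day) drawn around a sex-specific mean, a birth date, and
#' a home transect; snout-vent length is linear in age from `birth_svl`.
#' An individual that dies within a month still counts as present that
#' month (census semantics: presence is supported by any detection on or
#' after a date within the month).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`. Pass `NULL` to
#'   continue from the current RNG state.
#' @return an object of class `sim_population`: a list with
#'   \describe{
#'     \item{individuals}{data.frame: `id`, `sex`, `growth_rate`,
#'       `birth_date`, `birth_month` (month index), `death_month` (month
#'       index or NA if alive at the end), `home_transect`.}
#'     \item{truth}{data.frame per study month: `month` ("YYYY-MM"),
#'       `n_total`, `n_gt900`, `density`, `density_gt900` (snakes/ha),
#'       `births`, `deaths`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' pop <- simulate_population(sim_config(initial_abundance = 30, n_months = 12))
#' head(pop$truth)
#' @export
simulate_population <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  m0 <- month_index(config$start_month)
  months <- m0 + seq_len(config$n_months) - 1L
  n0 <- config$initial_abundance

  extra_mort <- numeric(config$n_months)
  if (!is.null(config$removal_schedule)) {
    idx <- month_index(config$removal_schedule$month) - m0 + 1L
    keep <- idx >= 1L & idx <= config$n_months
    extra_mort[idx[keep]] <- config$removal_schedule$extra_mortality[keep]
  }

  draw_sex <- function(n) sample(c("F", "M"), n, replace = TRUE)
  draw_growth <- function(sex) {
    g <- stats::rnorm(length(sex),
                      config$growth_rate_mean_by_sex[sex],
                      config$growth_rate_sd)
    pmax(g, 0.05)
  }
  draw_transect <- function(n) {
    w <- config$transect_weights
    if (is.null(w)) w <- rep(1, config$n_transects)
    sample.int(config$n_transects, n, replace = TRUE, prob = w)
  }

  start_day <- month_start(m0)
  sex <- draw_sex(n0)
  age0 <- round(stats::runif(n0, config$initial_age_range_days[1],
                             config$initial_age_range_days[2]))
  birth_date <- start_day - age0
  ind <- data.frame(
    id = sprintf("S%04d", seq_len(max(n0, 1L)))[seq_len(n0)],
    sex = sex,
    growth_rate = draw_growth(sex),
    birth_date = birth_date,
    birth_month = month_index(birth_date),
    death_month = NA_integer_,
    home_transect = draw_transect(n0),
    stringsAsFactors = FALSE
  )
  if (n0 == 0L) ind <- ind[0L, ]
  next_id <- n0 + 1L

  births <- deaths <- integer(config$n_months)
  for (k in seq_len(config$n_months)) {
    m <- months[k]
    alive <- is.na(ind$death_month) & ind$birth_month <= m
    n_alive <- sum(alive)
    # births from the pool present at the start of the month
    if (config$monthly_birth_rate > 0 && n_alive > 0) {
      nb <- stats::rpois(1L, config$monthly_birth_rate * n_alive)
      if (nb > 0) {
        bsex <- draw_sex(nb)
        bdate <- month_start(m) +
          sample.int(days_in_month(m), nb, replace = TRUE) - 1L
        baby <- data.frame(
          id = sprintf("S%04d", next_id + seq_len(nb) - 1L),
          sex = bsex,
          growth_rate = draw_growth(bsex),
          birth_date = bdate,
          birth_month = rep(m, nb),
          death_month = NA_integer_,
          home_transect = draw_transect(nb),
          stringsAsFactors = FALSE
        )
        ind <- rbind(ind, baby)
        next_id <- next_id + nb
        births[k] <- nb
      }
    }
    # mortality over everyone present this month (newborns included)
    p_die <- 1 - config$monthly_survival * (1 - extra_mort[k])
    at_risk <- which(is.na(ind$death_month) & ind$birth_month <= m)
    if (length(at_risk) > 0 && p_die > 0) {
      dies <- at_risk[stats::runif(length(at_risk)) < p_die]
      ind$death_month[dies] <- m
      deaths[k] <- length(dies)
    }
  }

  truth <- true_abundance(ind, months, config)
  truth$births <- births
  truth$deaths <- deaths
  activity <- NULL
  if (config$transect_activity_sd > 0) {
    s <- config$transect_activity_sd
    rho <- config$transect_activity_rho
    v <- matrix(0, config$n_months, config$n_transects)
    v[1, ] <- stats::rnorm(config$n_transects, 0, s)
    if (config$n_months > 1) for (k in 2:config$n_months)
      v[k, ] <- rho * v[k - 1, ] +
        stats::rnorm(config$n_transects, 0, s * sqrt(1 - rho^2))
    activity <- exp(v - s^2 / 2)  # mean-1 stationary field
  }
  structure(list(individuals = ind, truth = truth, activity = activity,
                 config = config),
            class = "sim_population")
}

days_in_month <- function(m) {
  as.integer(month_start(m + 1L) - month_start(m))
}

# SVL of each individual on a given date (no measurement noise)
svl_on <- function(individuals, date, config) {
  config$birth_svl + individuals$growth_rate *
    as.numeric(date - individuals$birth_date)
}

present_in_month <- function(individuals, m) {
  individuals$birth_month <= m &
    (is.na(individuals$death_month) | individuals$death_month >= m)
}

true_abundance <- function(individuals, months, config) {
  area_ha <- config$enclosure_side^2 / 1e4
  n_total <- n_gt900 <- integer(length(months))
  for (k in seq_along(months)) {
    m <- months[k]
    pres <- present_in_month(individuals, m)
    n_total[k] <- sum(pres)
    svl <- svl_on(individuals, month_start(m), config)
    n_gt900[k] <- sum(pres & svl > config$trap_susceptibility_threshold)
  }
  data.frame(month = month_label(months),
             n_total = n_total, n_gt900 = n_gt900,
             density = n_total / area_ha,
             density_gt900 = n_gt900 / area_ha,
             stringsAsFactors = FALSE)
}

#' Build a nightly visual-survey schedule
#'
#' Weekly pattern over the simulated horizon: the first `nights_per_week`
#' days of every 7-day block, optionally excluding whole calendar months
#' (emulating field gaps when no surveys occurred). Every scheduled night
#' covers all transects.
#'
#' @param config a [sim_config()].
#' @param nights_per_week survey nights per week (1-7).
#' @param gap_months "YYYY-MM" months with no surveys (default mirrors two
#'   multi-month interruptions of the emulated study calendar).
#' @return data.frame with column `night` (Date), sorted.
#' @export
default_survey_schedule <- function(config, nights_per_week = 4,
                                    gap_months = c(sprintf("2019-%02d", 1:3),
                                                   sprintf("2020-%02d", 3:10))) {
  stopifnot(nights_per_week >= 1, nights_per_week <= 7)
  m0 <- month_index(config$start_month)
  first <- month_start(m0)
  last <- month_start(m0 + config$n_months) - 1L
  all_days <- seq(first, last, by = "day")
  dow <- as.integer(all_days - first) %% 7L
  nights <- all_days[dow < nights_per_week]
  if (length(gap_months))
    nights <- nights[!(month_label(month_index(nights)) %in% gap_months)]
  data.frame(night = nights)
}

#' Simulate nocturnal visual surveys along transects
#'
#' Detection follows a thinned count model: on a night when transects `S`
#' are walked, a snake whose home transect lies in `S` is detected with
#' probability `min(1, q * N^(beta-1) * C)`, where `N` is the number of
#' snakes alive that night and `C` the full-design covered-area fraction.
#' Summed over individuals this gives expected detections
#' `q * N^beta * coverage(S)` under spatially uniform density, so
#' `beta = 1` makes CPUE proportional to abundance, `beta < 1` hyperstable
#' and `beta > 1` hyperdeplete. Effort is recorded for every scheduled
#' night whether or not snakes were found.
#'
#' @param pop a `sim_population`.
#' @param schedule data.frame with column `night` (Date); optional
#'   list-column `transects` of integer transect ids per night (default:
#'   all transects every night).
#' @param config a [sim_config()]; defaults to the population's.
#' @param seed optional seed; `NULL` (default) continues the RNG stream.
#' @return list with `captures` (individual_id, date, method, location_id,
#'   svl_mm, sex) and `effort` (date, method, n_transects, km,
#'   trap_nights_deployed, trap_nights_corrected — trap columns NA).
#' @export
simulate_visual_surveys <- function(pop, schedule = default_survey_schedule(config),
                                    config = pop$config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- pop$individuals
  nights <- as.Date(schedule$night)
  if (is.unsorted(nights)) {
    o <- order(nights)
    nights <- nights[o]
    schedule <- schedule[o, , drop = FALSE]
  }
  has_sets <- "transects" %in% names(schedule)
  cov_full <- coverage_fraction(config$n_transects, config)
  q <- config$catchability_q
  beta <- config$hyperstability_beta

  cap_list <- vector("list", length(nights))
  eff <- data.frame(
    date = nights, method = "visual",
    n_transects = NA_integer_, km = NA_real_,
    trap_nights_deployed = NA_integer_, trap_nights_corrected = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(nights)) {
    night <- nights[k]
    S <- if (has_sets) sort(unique(as.integer(schedule$transects[[k]])))
         else seq_len(config$n_transects)
    if (length(S) && (min(S) < 1L || max(S) > config$n_transects))
      stop("transect ids outside [1, n_transects] in schedule", call. = FALSE)
    eff$n_transects[k] <- length(S)
    eff$km[k] <- length(S) * config$transect_length / 1000
    m <- month_index(night)
    alive <- present_in_month(ind, m) & ind$birth_date <= night
    n_alive <- sum(alive)
    if (n_alive == 0L || q == 0 || length(S) == 0L) next
    p_base <- q * n_alive^(beta - 1) * cov_full
    cand <- which(alive & ind$home_transect %in% S)
    if (!length(cand)) next
    p <- rep(p_base, length(cand))
    if (!is.null(pop$activity)) {
      row <- m - month_index(config$start_month) + 1L
      row <- min(max(row, 1L), nrow(pop$activity))
      p <- p_base * pop$activity[row, ind$home_transect[cand]]
    }
    p <- pmin(p, 1)
    hit <- cand[stats::runif(length(cand)) < p]
    if (!length(hit)) next
    svl <- svl_on(ind[hit, ], night, config)
    if (config$svl_noise_sd > 0)
      svl <- svl + stats::rnorm(length(hit), 0, config$svl_noise_sd)
    cap_list[[k]] <- data.frame(
      individual_id = ind$id[hit],
      date = rep(night, length(hit)),
      method = "visual",
      location_id = sprintf("T%02d", ind$home_transect[hit]),
      svl_mm = round(svl, 1),
      sex = ind$sex[hit],
      stringsAsFactors = FALSE
    )
  }
  captures <- do.call(rbind, cap_list[!vapply(cap_list, is.null, logical(1))])
  if (is.null(captures)) captures <- empty_captures()
  list(captures = captures, effort = eff)
}

#' Default trapping-bout calendar
#'
#' Evenly spaced multi-night bouts over the horizon (default ten 16-night
#' bouts of the full grid, ~27,000 deployed trap-nights).
#'
#' @param config a [sim_config()].
#' @param n_bouts number of bouts.
#' @param nights_per_bout contiguous nights per bout.
#' @return data.frame with columns `start` (Date) and `n_nights`.
#' @export
default_trap_bouts <- function(config, n_bouts = 10, nights_per_bout = 16) {
  m0 <- month_index(config$start_month)
  span <- max(config$n_months - 10L, 1L)
  at <- unique(round(seq(3, span + 2, length.out = n_bouts)))
  data.frame(start = month_start(m0 + at),
             n_nights = rep(as.integer(nights_per_bout), length(at)))
}

#' Simulate grid trapping with a size-susceptibility threshold
#'
#' Only snakes above `trap_susceptibility_threshold` (900 mm SVL by
#' default) can be trapped. Each susceptible snake runs an independent
#' nightly risk `1 - (1 - p)^n_traps` of being caught somewhere on the
#' grid, with `p` the per-trap per-night capture probability. When
#' `prey_modulation_sd > 0`, a per-bout log-normal factor (mean 1)
#' multiplies `p`, emulating landscape prey availability driving trap
#' success independently of density. Trapped snakes are processed and
#' released (they stay in the population). Deployed and corrected
#' trap-nights are recorded per night; a fraction
#' `trap_inoperable_rate` of deployed trap-nights is flagged inoperable.
#'
#' @param pop a `sim_population`.
#' @param bouts data.frame (`start` Date, `n_nights`) of contiguous-night
#'   bouts, or NULL/empty for no trapping (empty outputs, not an error).
#' @param config a [sim_config()]; defaults to the population's.
#' @param seed optional seed; `NULL` continues the RNG stream.
#' @return list with `captures` and `effort` as in
#'   [simulate_visual_surveys()] (visual columns NA in effort).
#' @export
simulate_trapping <- function(pop, bouts = default_trap_bouts(config),
                              config = pop$config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- pop$individuals
  if (is.null(bouts) || nrow(bouts) == 0L)
    return(list(captures = empty_captures(), effort = empty_effort()))
  cap_list <- list()
  eff_list <- list()
  for (b in seq_len(nrow(bouts))) {
    p_eff <- config$trap_capture_prob
    if (config$prey_modulation_sd > 0) {
      s <- config$prey_modulation_sd
      p_eff <- p_eff * exp(stats::rnorm(1, 0, s) - s^2 / 2)
    }
    p_eff <- min(p_eff, 1)
    p_night <- 1 - (1 - p_eff)^config$n_traps
    nights <- as.Date(bouts$start[b]) + seq_len(bouts$n_nights[b]) - 1L
    for (night in seq_along(nights)) {
      d <- nights[night]
      m <- month_index(d)
      alive <- present_in_month(ind, m) & ind$birth_date <= d
      svl <- svl_on(ind, d, config)
      susc <- which(alive & svl > config$trap_susceptibility_threshold)
      inop <- stats::rbinom(1L, config$n_traps, config$trap_inoperable_rate)
      eff_list[[length(eff_list) + 1L]] <- data.frame(
        date = d, method = "trap",
        n_transects = NA_integer_, km = NA_real_,
        trap_nights_deployed = config$n_traps,
        trap_nights_corrected = config$n_traps - inop,
        stringsAsFactors = FALSE
      )
      if (!length(susc) || p_night == 0) next
      hit <- susc[stats::runif(length(susc)) < p_night]
      if (!length(hit)) next
      svl_rec <- svl[hit]
      if (config$svl_noise_sd > 0)
        svl_rec <- svl_rec + stats::rnorm(length(hit), 0, config$svl_noise_sd)
      cap_list[[length(cap_list) + 1L]] <- data.frame(
        individual_id = ind$id[hit],
        date = rep(d, length(hit)),
        method = "trap",
        location_id = sprintf("trap%03d",
                              sample.int(config$n_traps, length(hit),
                                         replace = TRUE)),
        svl_mm = round(svl_rec, 1),
        sex = ind$sex[hit],
        stringsAsFactors = FALSE
      )
    }
  }
  captures <- if (length(cap_list)) do.call(rbind, cap_list) else empty_captures()
  effort <- if (length(eff_list)) do.call(rbind, eff_list) else empty_effort()
  list(captures = captures, effort = effort)
}

empty_captures <- function() {
  data.frame(individual_id = character(), date = as.Date(character()),
             method = character(), location_id = character(),
             svl_mm = numeric(), sex = character(), stringsAsFactors = FALSE)
}

empty_effort <- function() {
  data.frame(date = as.Date(character()), method = character(),
             n_transects = integer(), km = numeric(),
             trap_nights_deployed = integer(),
             trap_nights_corrected = integer(), stringsAsFactors = FALSE)
}

#' Simulate a full capture-effort dataset
#'
#' Runs [simulate_population()], [simulate_visual_surveys()] and
#' [simulate_trapping()] under a single seed, in a fixed order, so the
#' whole dataset is reproducible from `config$seed` alone.
#'
#' @param config a [sim_config()].
#' @param survey_schedule passed to [simulate_visual_surveys()].
#' @param trap_bouts passed to [simulate_trapping()]; NULL disables
#'   trapping.
#' @param nights_per_week used when `survey_schedule` is NULL.
#' @return list of class `sim_dataset`: `population`, `captures` (both
#'   methods, sorted), `effort`, `config`.
#' @export
simulate_dataset <- function(config, survey_schedule = NULL,
                             trap_bouts = default_trap_bouts(config),
                             nights_per_week = 4) {
  pop <- simulate_population(config, seed = config$seed)
  if (is.null(survey_schedule))
    survey_schedule <- default_survey_schedule(config, nights_per_week)
  vis <- simulate_visual_surveys(pop, survey_schedule, config, seed = NULL)
  trp <- simulate_trapping(pop, trap_bouts, config, seed = NULL)
  captures <- rbind(vis$captures, trp$captures)
  captures <- captures[order(captures$date, captures$method,
                             captures$individual_id), , drop = FALSE]
  rownames(captures) <- NULL
  effort <- rbind(vis$effort, trp$effort)
  effort <- effort[order(effort$date, effort$method), , drop = FALSE]
  rownames(effort) <- NULL
  structure(list(population = pop, captures = captures, effort = effort,
                 config = config),
            class = "sim_dataset")
}
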