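#' Monthly effort-corrected CPUE
#'
#' Capture-per-unit-effort by calendar month as a ratio of monthly totals:
#' cumulative captures divided by cumulative effort across all nights of
#' the month (km walked for visual surveys, corrected trap-nights for
#' trapping). Averaging at the month level damps nightly searcher/trap
#' variation and temporal autocorrelation. Months with no recorded effort
#' for the method are absent from the output (they carry no CPUE, not a
#' zero); a month with captures but no effort is a bookkeeping error.
#'
#' @param captures capture table (`individual_id`, `date`, `method`, ...).
#' @param effort effort table (`date`, `method`, `km`,
#'   `trap_nights_corrected`, ...).
#' @param method `"visual"` (effort in km) or `"trap"` (effort in
#'   corrected trap-nights).
#' @param mean_of_nightly if TRUE, use the unweighted mean of nightly CPUEs
#'   instead of the ratio of monthly totals (sensitivity analysis only;
#'   the ratio of totals is the km-weighted mean of nightly CPUEs).
#' @return data.frame: `month`, `n_captures`, `effort`
#'   (km or corrected trap-nights), `cpue`.
#' @examples
#' eff <- data.frame(date = as.Date("2018-05-01") + 0:1, method = "visual",
#'                   km = 6.38)
#' cap <- data.frame(individual_id = sprintf("S%02d", 1:4),
#'                   date = as.Date("2018-05-01"), method = "visual")
#' monthly_cpue(cap, eff, "visual")$cpue  # 4 / 12.76
#' @export
monthly_cpue <- function(captures, effort, method = c("visual", "trap"),
                         mean_of_nightly = FALSE) {
  method <- match.arg(method)
  eff <- effort[effort$method == method, , drop = FALSE]
  cap <- captures[captures$method == method, , drop = FALSE]
  eff_val <- if (method == "visual") eff$km else eff$trap_nights_corrected
  if (any(!is.finite(eff_val) | eff_val < 0))
    stop(sprintf("non-finite or negative %s effort", method), call. = FALSE)
  eff_month <- month_label(month_index(as.Date(eff$date)))
  cap_month <- month_label(month_index(as.Date(cap$date)))
  orphan <- setdiff(unique(cap_month), unique(eff_month))
  if (length(orphan))
    stop(sprintf("captures recorded in month(s) %s with no %s effort record",
                 paste(orphan, collapse = ", "), method), call. = FALSE)
  if (nrow(eff) == 0L)
    return(data.frame(month = character(), n_captures = integer(),
                      effort = numeric(), cpue = numeric(),
                      stringsAsFactors = FALSE))
  months <- sort(unique(eff_month))
  tot_eff <- vapply(months, function(m) sum(eff_val[eff_month == m]), 0)
  n_cap <- vapply(months, function(m) sum(cap_month == m), 0L)
  if (mean_of_nightly) {
    cap_by_night <- table(factor(as.character(cap$date),
                                 levels = as.character(eff$date)))
    nightly <- as.numeric(cap_by_night) / eff_val
    cpue <- vapply(months, function(m) mean(nightly[eff_month == m]), 0)
  } else {
    cpue <- ifelse(tot_eff > 0, n_cap / tot_eff, NA_real_)
  }
  out <- data.frame(month = months, n_captures = n_cap, effort = tot_eff,
                    cpue = cpue, stringsAsFactors = FALSE)
  out <- out[out$effort > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Corrected trap-nights
#'
#' A deployed trap-night counts toward effort only while the trap is
#' operable. The default correction subtracts trap-nights flagged
#' inoperable (sprung, disturbed); a custom policy function can replace
#' it.
#'
#' @param effort trap effort records with `trap_nights_deployed` and
#'   `trap_nights_corrected` columns (the simulator fills both).
#' @param policy `"flagged"` (default: use the recorded corrected counts)
#'   or a function mapping the effort data.frame to a corrected-count
#'   vector.
#' @return total corrected trap-nights (scalar).
#' @export
corrected_trap_nights <- function(effort, policy = "flagged") {
  eff <- effort[effort$method == "trap", , drop = FALSE]
  if (nrow(eff) == 0L) return(0L)
  corr <- if (is.function(policy)) policy(eff) else eff$trap_nights_corrected
  if (any(corr > eff$trap_nights_deployed) || any(corr < 0))
    stop("corrected trap-nights must lie in [0, deployed]", call. = FALSE)
  sum(corr)
}

#' Join census truth and monthly CPUE into an analysis panel
#'
#' One row per calendar month with recorded effort: true abundance and
#' density (total and trap-susceptible segment) alongside visual and trap
#' CPUE with their effort denominators. Months with no effort of either
#' method are dropped, not imputed. Rows where a method was not run that
#' month carry NA in that method's columns.
#'
#' @param truth monthly truth table (`month`, `n_total`, `n_gt900`,
#'   `density`, `density_gt900`), e.g. from [enumerate_monthly()] or the
#'   simulator.
#' @param captures,effort capture and effort tables covering both methods.
#' @return data.frame of class `monthly_panel`.
#' @export
build_panel <- function(truth, captures, effort) {
  vis <- monthly_cpue(captures, effort, "visual")
  trp <- monthly_cpue(captures, effort, "trap")
  months <- sort(unique(c(vis$month, trp$month)))
  months <- months[months %in% truth$month]
  ti <- match(months, truth$month)
  vi <- match(months, vis$month)
  pi <- match(months, trp$month)
  panel <- data.frame(
    month = months,
    n_total = truth$n_total[ti],
    n_gt900 = truth$n_gt900[ti],
    density = truth$density[ti],
    density_gt900 = truth$density_gt900[ti],
    cpue_visual = vis$cpue[vi],
    km_surveyed = vis$effort[vi],
    n_capture_visual = vis$n_captures[vi],
    cpue_trap = trp$cpue[pi],
    trap_nights_corrected = trp$effort[pi],
    n_capture_trap = trp$n_captures[pi],
    stringsAsFactors = FALSE
  )
  class(panel) <- c("monthly_panel", "data.frame")
  panel
}
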