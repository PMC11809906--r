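#' Temporal sampling schemes
#'
#' The 15 rarefied visual-survey designs form a 3 x 5 grid. The sampling
#' interval is monthly (M, a 30-day cycle), quarterly (Q, one sampled
#' month out of every 90 days) or biannual (B, one out of every 180 days).
#' Within each sampled ~month (a 28-day, 4-week window), the five
#' intensities are:
#' \tabular{lll}{
#'   code \tab weeks sampled \tab nights per week \cr
#'   1 \tab 4 \tab 2 \cr
#'   2 \tab 4 \tab 1 \cr
#'   3 \tab 2 \tab 1 \cr
#'   4 \tab 1 \tab 2 \cr
#'   5 \tab 1 \tab 1 \cr
#' }
#'
#' @param code scheme code, one of M1-M5, Q1-Q5, B1-B5.
#' @return list of class `temporal_scheme`: `code`, `interval_days`,
#'   `weeks`, `nights_per_week`.
#' @export
temporal_scheme <- function(code) {
  code <- toupper(code)
  if (!grepl("^[MQB][1-5]$", code))
    stop("scheme code must be one of M1-M5, Q1-Q5, B1-B5", call. = FALSE)
  interval <- c(M = 30L, Q = 90L, B = 180L)[[substr(code, 1, 1)]]
  lvl <- as.integer(substr(code, 2, 2))
  weeks <- c(4L, 4L, 2L, 1L, 1L)[lvl]
  nights <- c(2L, 1L, 1L, 2L, 1L)[lvl]
  structure(list(code = code, interval_days = interval, weeks = weeks,
                 nights_per_week = nights),
            class = "temporal_scheme")
}

#' All 15 temporal scheme codes
#' @return character vector M1..B5.
#' @export
temporal_scheme_codes <- function() {
  paste0(rep(c("M", "Q", "B"), each = 5), 1:5)
}

#' Thin a survey calendar to a temporal sampling scheme
#'
#' A start date is drawn once, uniformly within 28 days of the first
#' survey night (seeded). The calendar then tiles into consecutive
#' `interval_days`-day blocks from that start; within each block the first
#' 28 days form the sampling window, split into four 7-day weeks. A week
#' qualifies if it contains at least the scheme's `nights_per_week` survey
#' nights; weeks that fall short are excluded from selection (so e.g. a
#' week with a single survey night can never be chosen for an
#' \emph{x}4 scheme, and a block with no qualifying week contributes
#' nothing). The earliest qualifying weeks after the start date are taken,
#' up to the scheme's `weeks`, and within each selected week the earliest
#' `nights_per_week` nights are retained — random start, deterministic
#' thinning.
#'
#' @param survey_nights sorted `Date` vector (or data.frame with `night`).
#' @param scheme a [temporal_scheme()] or its code.
#' @param seed integer seed for the start-date draw.
#' @param redraw_start_per_block if TRUE, an independent start offset is
#'   drawn for every block (default FALSE: one global start).
#' @return sorted `Date` vector of retained nights (subset of the input).
#' @export
apply_temporal_scheme <- function(survey_nights, scheme, seed = 1L,
                                  redraw_start_per_block = FALSE) {
  if (is.character(scheme)) scheme <- temporal_scheme(scheme)
  nights <- if (is.data.frame(survey_nights)) as.Date(survey_nights$night)
            else as.Date(survey_nights)
  nights <- sort(unique(nights))
  if (length(nights) == 0L) {
    warning("empty survey calendar; nothing to rarefy")
    return(as.Date(character()))
  }
  set.seed(seed)
  start <- nights[1] + sample.int(28L, 1L) - 1L
  horizon <- nights[length(nights)]
  kept <- list()
  b <- 0L
  repeat {
    block_start <- start + b * scheme$interval_days
    if (block_start > horizon) break
    if (redraw_start_per_block && b > 0L)
      block_start <- block_start + sample.int(7L, 1L) - 1L
    taken <- 0L
    for (w in 0:3) {
      if (taken >= scheme$weeks) break
      wk_start <- block_start + w * 7L
      in_week <- nights[nights >= wk_start & nights < wk_start + 7L]
      if (length(in_week) < scheme$nights_per_week) next  # week excluded
      kept[[length(kept) + 1L]] <- in_week[seq_len(scheme$nights_per_week)]
      taken <- taken + 1L
    }
    b <- b + 1L
  }
  out <- if (!length(kept)) as.Date(character())
         else sort(unique(do.call(c, kept)))
  attr(out, "start") <- start
  out
}

#' Evenly spread transect subset
#'
#' Deterministic, non-random spatial thinning: keeping `n_keep` of `T`
#' ordered transects retains positions `floor(i * T / n_keep) + 1` for
#' `i = 0, ..., n_keep - 1`. This spreads the kept transects evenly over
#' the site and reproduces the alternating lane pattern (1st, 3rd,
#' 5th, ...) when 14 of 29 are kept. The same subset is reused on every
#' survey night (repeated sampling design).
#'
#' @param n_keep number of transects to keep (1 to `length(transect_order)`).
#' @param transect_order ordered transect ids (default `1:29`).
#' @param geometry a [sim_config()] used to report the covered fraction.
#' @return list of class `spatial_scheme`: `n_transects_kept`,
#'   `transect_ids_kept`, `coverage_fraction`.
#' @export
apply_spatial_scheme <- function(n_keep, transect_order = seq_len(29),
                                 geometry = sim_config()) {
  n_total <- length(transect_order)
  if (n_keep < 1L || n_keep > n_total)
    stop("'n_keep' must lie in [1, number of transects]", call. = FALSE)
  pos <- floor((seq_len(n_keep) - 1L) * n_total / n_keep) + 1L
  structure(list(n_transects_kept = as.integer(n_keep),
                 transect_ids_kept = transect_order[pos],
                 coverage_fraction = coverage_fraction(n_keep, geometry)),
            class = "spatial_scheme")
}

#' Rebuild a monthly panel from rarefied captures and effort
#'
#' Applies a temporal night filter and/or a spatial transect filter to the
#' visual survey record, rescales nightly survey effort to the kept
#' transects, recomputes monthly CPUE, and re-joins the truth series.
#' Trap records pass through unchanged. With both filters at identity the
#' result equals the unrarefied panel.
#'
#' @param captures,effort full capture and effort tables.
#' @param truth monthly truth table (see [build_panel()]).
#' @param nights_kept `Date` vector of retained survey nights (NULL: all).
#' @param spatial a `spatial_scheme` from [apply_spatial_scheme()] (NULL:
#'   all transects).
#' @param config a [sim_config()] supplying transect geometry.
#' @return a `monthly_panel` (see [build_panel()]).
#' @export
rebuild_panel <- function(captures, effort, truth, nights_kept = NULL,
                          spatial = NULL, config = sim_config()) {
  cap <- captures
  eff <- effort
  is_vis_cap <- cap$method == "visual"
  is_vis_eff <- eff$method == "visual"
  if (!is.null(nights_kept)) {
    nights_kept <- as.Date(nights_kept)
    cap <- cap[!is_vis_cap | as.Date(cap$date) %in% nights_kept, , drop = FALSE]
    eff <- eff[!is_vis_eff | as.Date(eff$date) %in% nights_kept, , drop = FALSE]
    is_vis_cap <- cap$method == "visual"
    is_vis_eff <- eff$method == "visual"
  }
  if (!is.null(spatial)) {
    labels_kept <- sprintf("T%02d", spatial$transect_ids_kept)
    cap <- cap[!is_vis_cap | cap$location_id %in% labels_kept, , drop = FALSE]
    vis_rows <- which(eff$method == "visual")
    eff$n_transects[vis_rows] <- spatial$n_transects_kept
    eff$km[vis_rows] <- spatial$n_transects_kept * config$transect_length / 1000
  }
  build_panel(truth, cap, eff)
}

#' One-call rarefaction: scheme code + coverage to panel
#'
#' Convenience wrapper combining [apply_temporal_scheme()],
#' [apply_spatial_scheme()] and [rebuild_panel()].
#'
#' @param captures,effort,truth as in [rebuild_panel()].
#' @param temporal_code M1..B5, or NULL for the full calendar.
#' @param n_transects_keep transects to keep, or NULL for all.
#' @param seed seed for the temporal start-date draw.
#' @param config a [sim_config()].
#' @return a `monthly_panel`.
#' @export
rarefy_panel <- function(captures, effort, truth, temporal_code = NULL,
                         n_transects_keep = NULL, seed = 1L,
                         config = sim_config()) {
  nights <- NULL
  if (!is.null(temporal_code)) {
    vis_nights <- sort(unique(as.Date(effort$date[effort$method == "visual"])))
    nights <- apply_temporal_scheme(vis_nights, temporal_code, seed = seed)
  }
  spatial <- NULL
  if (!is.null(n_transects_keep) && n_transects_keep < config$n_transects)
    spatial <- apply_spatial_scheme(n_transects_keep,
                                    seq_len(config$n_transects), config)
  rebuild_panel(captures, effort, truth, nights, spatial, config)
}
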