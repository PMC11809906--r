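#' Read and write capture/effort/panel tables
#'
#' The interchange format is plain CSV with ISO-8601 dates.
#' `captures.csv`: individual_id, date, method, location_id, svl_mm, sex.
#' `effort.csv`: date, method, n_transects, km, trap_nights_deployed,
#' trap_nights_corrected. Writing prepends `#`-comment metadata lines
#' (package version, seed) which readers skip.
#'
#' @param path file path.
#' @param x table to write.
#' @param seed optional seed recorded in the metadata header.
#' @return the table (readers), or `path` invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_captures <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("individual_id", "date", "method", "location_id", "svl_mm", "sex")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("captures file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("unparseable ISO-8601 dates in captures",
                          call. = FALSE)
  x
}

#' @rdname table_io
#' @export
read_effort <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("date", "method", "n_transects", "km", "trap_nights_deployed",
            "trap_nights_corrected")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("effort file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("unparseable ISO-8601 dates in effort",
                          call. = FALSE)
  x
}

#' @rdname table_io
#' @export
write_table_csv <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# written by cpuecal %s",
                     as.character(utils::packageVersion("cpuecal"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Validate capture and effort tables
#'
#' Schema, referential-integrity and plausibility checks before analysis:
#' required columns and parseable dates; every capture night/method backed
#' by an effort record; transect/trap ids within the configured geometry;
#' non-negative effort with corrected <= deployed trap-nights; and
#' monotone non-decreasing SVL within an individual (violations beyond
#' `svl_slack_mm` of measurement slack are warnings, not errors).
#'
#' @param captures,effort tables as from [read_captures()]/[read_effort()]
#'   or the simulator.
#' @param config a [sim_config()] describing the geometry.
#' @param svl_slack_mm tolerated within-individual SVL decrease, mm.
#' @return data.frame of violations (`severity` "error"/"warning",
#'   `rule`, `detail`); zero rows when clean.
#' @export
validate_tables <- function(captures, effort, config = sim_config(),
                            svl_slack_mm = 10) {
  v <- list()
  note <- function(severity, rule, detail)
    v[[length(v) + 1L]] <<- data.frame(severity = severity, rule = rule,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  cap <- captures
  eff <- effort
  cap$date <- as.Date(cap$date)
  eff$date <- as.Date(eff$date)

  key_cap <- paste(cap$date, cap$method)
  key_eff <- paste(eff$date, eff$method)
  orphan <- which(!(key_cap %in% key_eff))
  for (i in orphan)
    note("error", "capture-without-effort",
         sprintf("row %d: %s capture on %s has no effort record",
                 i, cap$method[i], cap$date[i]))

  bad_m <- which(!cap$method %in% c("visual", "trap"))
  for (i in bad_m)
    note("error", "unknown-method", sprintf("captures row %d: '%s'", i,
                                            cap$method[i]))

  vis <- which(cap$method == "visual")
  t_ids <- suppressWarnings(as.integer(sub("^T", "", cap$location_id[vis])))
  bad_t <- vis[is.na(t_ids) | t_ids < 1L | t_ids > config$n_transects]
  for (i in bad_t)
    note("error", "transect-out-of-range",
         sprintf("captures row %d: location '%s'", i, cap$location_id[i]))
  trp <- which(cap$method == "trap")
  k_ids <- suppressWarnings(as.integer(sub("^trap", "", cap$location_id[trp])))
  bad_k <- trp[is.na(k_ids) | k_ids < 1L | k_ids > config$n_traps]
  for (i in bad_k)
    note("error", "trap-out-of-range",
         sprintf("captures row %d: location '%s'", i, cap$location_id[i]))

  tr <- which(eff$method == "trap")
  bad_corr <- tr[!is.na(eff$trap_nights_corrected[tr]) &
                   (eff$trap_nights_corrected[tr] >
                      eff$trap_nights_deployed[tr] |
                      eff$trap_nights_corrected[tr] < 0)]
  for (i in bad_corr)
    note("error", "corrected-exceeds-deployed",
         sprintf("effort row %d: corrected %d of %d deployed", i,
                 eff$trap_nights_corrected[i], eff$trap_nights_deployed[i]))
  vis_e <- which(eff$method == "visual")
  bad_km <- vis_e[!is.finite(eff$km[vis_e]) | eff$km[vis_e] < 0]
  for (i in bad_km)
    note("error", "negative-effort", sprintf("effort row %d: km = %s", i,
                                             eff$km[i]))

  if (nrow(cap)) {
    o <- order(cap$individual_id, cap$date)
    cc <- cap[o, ]
    same <- cc$individual_id[-1] == cc$individual_id[-nrow(cc)]
    shrink <- cc$svl_mm[-1] - cc$svl_mm[-nrow(cc)]
    bad_s <- which(same & shrink < -svl_slack_mm)
    for (i in bad_s)
      note("warning", "svl-decrease",
           sprintf("individual %s: SVL fell %.1f mm between %s and %s",
                   cc$individual_id[i + 1], -shrink[i], cc$date[i],
                   cc$date[i + 1]))
  }

  if (length(v)) do.call(rbind, v)
  else data.frame(severity = character(), rule = character(),
                  detail = character(), stringsAsFactors = FALSE)
}
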