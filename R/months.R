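#' Calendar-month keys
#'
#' All monthly bookkeeping in the package uses calendar months, encoded
#' either as "YYYY-MM" labels (in tables written to disk) or as an integer
#' index `year * 12 + month - 1` (internally, so month arithmetic is plain
#' integer arithmetic). These helpers convert between the two and to dates.
#'
#' @param x a `Date`, a "YYYY-MM" (or "YYYY-MM-DD") character vector, or an
#'   integer index already in month-index form.
#' @return `month_index()` returns an integer vector; `month_label()` a
#'   "YYYY-MM" character vector; `month_start()` a `Date` (first day of the
#'   month).
#' @examples
#' month_index("2016-10")          # 24201
#' month_label(month_index("2016-10") + 14)  # "2017-12"
#' @export
month_index <- function(x) {
  if (inherits(x, "Date")) {
    lt <- as.POSIXlt(x)
    return(as.integer((lt$year + 1900L) * 12L + lt$mon))
  }
  if (is.numeric(x)) return(as.integer(x))
  if (is.character(x)) {
    y <- as.integer(substr(x, 1L, 4L))
    m <- as.integer(substr(x, 6L, 7L))
    if (anyNA(y) || anyNA(m) || any(m < 1L | m > 12L))
      stop("malformed month label; expected 'YYYY-MM'", call. = FALSE)
    return(y * 12L + m - 1L)
  }
  stop("cannot interpret 'x' as a calendar month", call. = FALSE)
}

#' @rdname month_index
#' @export
month_label <- function(x) {
  i <- month_index(x)
  sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L)
}

#' @rdname month_index
#' @export
month_start <- function(x) {
  as.Date(paste0(month_label(x), "-01"))
}
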