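#' Calendar-month utilities
#'
#' Months are the finest time unit in this package: every prescription event is
#' dated to a calendar month written as an ISO `"YYYY-MM"` string.  Internally a
#' month is an integer index (`year * 12 + month - 1`) so arithmetic and
#' comparisons are exact.
#'
#' @param x character vector of `"YYYY-MM"` month strings.
#' @return `month_index()` returns an integer vector of month indices;
#'   `month_label()` the inverse; `month_year()` the calendar year;
#'   `quarter_label()` a `"YYYY-Qk"` quarter string; `month_seq()` a character
#'   vector of consecutive months from `from` to `to` inclusive.
#' @examples
#' month_seq("2012-04", "2012-06")
#' quarter_label("2003-07")
#' @name months
NULL

#' @rdname months
#' @export
month_index <- function(x) {
  ok <- grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", x)
  if (any(!ok)) {
    stop("invalid month string(s): ", paste(unique(x[!ok]), collapse = ", "),
         " (expected \"YYYY-MM\")", call. = FALSE)
  }
  y <- as.integer(substr(x, 1L, 4L))
  m <- as.integer(substr(x, 6L, 7L))
  y * 12L + (m - 1L)
}

#' @rdname months
#' @param i integer month index as returned by `month_index()`.
#' @export
month_label <- function(i) {
  i <- as.integer(i)
  sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L)
}

#' @rdname months
#' @export
month_year <- function(x) month_index(x) %/% 12L

#' @rdname months
#' @export
quarter_label <- function(x) {
  i <- month_index(x)
  sprintf("%04d-Q%d", i %/% 12L, (i %% 12L) %/% 3L + 1L)
}

#' @rdname months
#' @param from,to `"YYYY-MM"` endpoints, `from <= to`.
#' @export
month_seq <- function(from, to) {
  a <- month_index(from)
  b <- month_index(to)
  if (b < a) stop("'to' month precedes 'from' month", call. = FALSE)
  month_label(seq.int(a, b))
}

# period key for a vector of months at a given granularity
period_of <- function(months, granularity = c("month", "quarter")) {
  granularity <- match.arg(granularity)
  if (granularity == "month") months else quarter_label(months)
}

# all periods spanned by a month range, in order
period_levels <- function(from, to, granularity = c("month", "quarter")) {
  granularity <- match.arg(granularity)
  m <- month_seq(from, to)
  if (granularity == "month") m else unique(quarter_label(m))
}
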