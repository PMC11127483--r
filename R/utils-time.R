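# Calendar helpers. All instants are POSIXct in a single implicit timezone
# (UTC); calendar days split at midnight; months are labelled "YYYY-MM".

#' Parse a calendar month
#'
#' Accepts "YYYY-MM" strings or Date objects and returns the first day of the
#' month as a Date.
#'
#' @param x character vector of "YYYY-MM" labels, or Dates.
#' @return Date vector (first of month).
#' @export
parse_month <- function(x) {
  if (inherits(x, "Date")) return(as.Date(format(x, "%Y-%m-01")))
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}$", x)
  if (!all(ok)) {
    stop("invalid month label(s): ", paste(x[!ok], collapse = ", "),
         " (expected 'YYYY-MM')", call. = FALSE)
  }
  as.Date(paste0(x, "-01"))
}

#' Format a Date as a "YYYY-MM" month label
#'
#' @param d Date vector.
#' @return character vector of month labels.
#' @export
month_label <- function(d) format(as.Date(d), "%Y-%m")

# months since year 0, used as an absolute month index
month_number <- function(d) {
  d <- as.Date(d)
  as.integer(format(d, "%Y")) * 12L + as.integer(format(d, "%m")) - 1L
}

#' Shift a month by a number of calendar months
#'
#' @param d a month (Date or "YYYY-MM").
#' @param k integer number of months to add (may be negative).
#' @return Date (first of month).
#' @export
add_months <- function(d, k) {
  i <- month_number(parse_month(d)) + as.integer(k)
  as.Date(sprintf("%04d-%02d-01", i %/% 12L, i %% 12L + 1L))
}

month_seq <- function(from, to) {
  seq(parse_month(from), parse_month(to), by = "month")
}

days_in_month <- function(d) {
  d <- parse_month(d)
  as.integer(add_months(d, 1) - d)
}

#' POSIXct instant from a calendar day plus hour and minute
#'
#' All instants in the package live in a single implicit timezone (UTC) at
#' minute resolution; calendar days split at midnight.
#'
#' @param day Date (vector).
#' @param hour,minute time of day.
#' @return POSIXct vector.
#' @export
day_time <- function(day, hour = 0, minute = 0) {
  as.POSIXct(sprintf("%s %02d:%02d:00", format(as.Date(day)), hour, minute),
             tz = "UTC")
}

day_of <- function(ts) as.Date(ts, tz = "UTC")

hours_between <- function(a, b) as.numeric(difftime(b, a, units = "hours"))

fmt_ts <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(as.character(x), format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    # tolerate a space separator
    out[bad] <- as.POSIXct(as.character(x)[bad], tz = "UTC")
  }
  out
}
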