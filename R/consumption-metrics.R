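# Monthly antimicrobial consumption metrics. A course is a maximal run of
# administrations for one patient-drug with no silent gap above a threshold
# (48 h by default, matching the alert rule). The two reported metrics are
# mean duration of therapy (antibiotic days per course initiated, attributed
# to the initiation month) and days of therapy per 1000 patient-days (one DOT
# per patient per drug per calendar day with >= 1 administration, attributed
# to the calendar month actually dosed — the NHSN convention).

#' Segment dose streams into drug courses
#'
#' Doses of each patient-drug pair are partitioned greedily in time order: a
#' new course begins whenever the gap to the previous dose exceeds
#' \code{gap_hours}. A course's antibiotic days are its distinct dosed
#' calendar days.
#'
#' @param doses data.frame (patient_id, drug, timestamp POSIXct).
#' @param gap_hours course-splitting gap threshold in hours (> 0).
#' @return data.frame (patient_id, drug, course_id, start_day, end_day,
#'   antibiotic_days, n_doses).
#' @export
build_courses <- function(doses, gap_hours = 48) {
  if (gap_hours <= 0) {
    stop("configuration error: gap_hours must be strictly positive",
         call. = FALSE)
  }
  if (nrow(doses) == 0) {
    return(data.frame(patient_id = character(0), drug = character(0),
                      course_id = integer(0),
                      start_day = as.Date(character(0)),
                      end_day = as.Date(character(0)),
                      antibiotic_days = integer(0), n_doses = integer(0),
                      stringsAsFactors = FALSE))
  }
  doses <- doses[order(doses$patient_id, doses$drug, doses$timestamp), ,
                 drop = FALSE]
  key <- paste(doses$patient_id, doses$drug, sep = "\r")
  out <- lapply(split(seq_len(nrow(doses)), key), function(idx) {
    ts <- doses$timestamp[idx]
    cid <- course_assignment(ts, gap_hours)
    days <- day_of(ts)
    parts <- split(seq_along(ts), cid)
    data.frame(
      patient_id = doses$patient_id[idx[1]], drug = doses$drug[idx[1]],
      course_id = as.integer(names(parts)),
      start_day = as.Date(vapply(parts, function(p) min(days[p]),
                                 numeric(1)), origin = "1970-01-01"),
      end_day = as.Date(vapply(parts, function(p) max(days[p]),
                               numeric(1)), origin = "1970-01-01"),
      antibiotic_days = vapply(parts, function(p)
        length(unique(days[p])), integer(1)),
      n_doses = lengths(parts), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$patient_id, res$drug, res$start_day), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Monthly consumption metrics per drug
#'
#' Courses are attributed to the calendar month of their first dose; a
#' course's antibiotic days count entirely toward its initiation month, so
#' \code{mean_duration} is the mean total duration of courses started that
#' month (deliberately outlier-sensitive). DOT is attributed to the calendar
#' month in which each dosed day actually falls. Patient-days come from the
#' daily census.
#'
#' @param courses output of \code{\link{build_courses}}.
#' @param doses the dose events the courses were built from.
#' @param census data.frame (date, patient_days) covering every month in
#'   range.
#' @param start_month,end_month month range ("YYYY-MM" or Date).
#' @param drugs drugs to report; default all drugs present in \code{doses}.
#' @return data.frame (month, drug, antibiotic_days, courses_initiated,
#'   mean_duration, dot, patient_days, dot_per_1000pd), one row per
#'   month-drug; \code{mean_duration} is NA for months with no initiations.
#' @export
monthly_consumption <- function(courses, doses, census, start_month,
                                end_month, drugs = NULL) {
  months <- month_seq(start_month, end_month)
  labels <- month_label(months)
  if (is.null(drugs)) drugs <- sort(unique(doses$drug))

  census$month <- month_label(as.Date(census$date))
  pd <- tapply(census$patient_days, census$month, sum)
  missing_m <- setdiff(labels, names(pd))
  if (length(missing_m) > 0) {
    stop("census does not cover month(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  if (any(pd[labels] <= 0)) {
    stop("denominator error: zero patient-days in month(s): ",
         paste(labels[pd[labels] <= 0], collapse = ", "), call. = FALSE)
  }

  # one DOT per (patient, drug, dosed calendar day)
  dosed <- unique(data.frame(patient_id = doses$patient_id,
                             drug = doses$drug,
                             day = day_of(doses$timestamp),
                             stringsAsFactors = FALSE))
  dosed$month <- month_label(dosed$day)

  courses$month <- month_label(courses$start_day)
  grid <- expand.grid(month = labels, drug = drugs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$drug, grid$month), , drop = FALSE]
  rownames(grid) <- NULL

  n <- nrow(grid)
  grid$antibiotic_days <- integer(n)
  grid$courses_initiated <- integer(n)
  grid$dot <- integer(n)
  for (i in seq_len(n)) {
    sel <- courses$month == grid$month[i] & courses$drug == grid$drug[i]
    grid$antibiotic_days[i] <- sum(courses$antibiotic_days[sel])
    grid$courses_initiated[i] <- sum(sel)
    grid$dot[i] <- sum(dosed$month == grid$month[i] &
                         dosed$drug == grid$drug[i])
  }
  grid$mean_duration <- ifelse(grid$courses_initiated > 0,
                               grid$antibiotic_days / grid$courses_initiated,
                               NA_real_)
  grid$patient_days <- as.integer(pd[grid$month])
  grid$dot_per_1000pd <- 1000 * grid$dot / grid$patient_days
  grid[, c("month", "drug", "antibiotic_days", "courses_initiated",
           "mean_duration", "dot", "patient_days", "dot_per_1000pd")]
}

#' Monthly mean length of stay
#'
#' Mean (discharge - admission) in days over admissions discharged in each
#' calendar month.
#'
#' @param admissions data.frame (patient_id, admit, discharge), Dates or
#'   POSIXct, with discharge >= admit.
#' @param start_month,end_month month range.
#' @return data.frame (month, n_discharges, mean_los).
#' @export
mean_length_of_stay <- function(admissions, start_month, end_month) {
  if (any(as.numeric(difftime(admissions$discharge, admissions$admit,
                              units = "days")) < 0)) {
    stop("admissions must have discharge >= admit", call. = FALSE)
  }
  labels <- month_label(month_seq(start_month, end_month))
  los <- as.numeric(difftime(admissions$discharge, admissions$admit,
                             units = "days"))
  dmonth <- month_label(as.Date(admissions$discharge))
  data.frame(
    month = labels,
    n_discharges = vapply(labels, function(m) sum(dmonth == m), integer(1)),
    mean_los = vapply(labels, function(m) {
      sel <- dmonth == m
      if (!any(sel)) NA_real_ else mean(los[sel])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
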