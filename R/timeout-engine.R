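# Day-5 antibiotic time-out detection. A patient-drug "reaches day 5" on a
# calendar day D when the four preceding calendar days each carry at least 2
# administrations of the drug, no gap between consecutive administrations in
# that run exceeds 48 hours, and an active order for the drug overlaps day D.
# The scan emulates the daily 06:30 batch and emits one alert per continuous
# course.

#' Construct an alert routing policy
#'
#' Three eras of alert routing are supported: \code{"pre_duplication"}
#' (attending physician only), \code{"duplication"} (attending, plus a
#' duplicate to the ID consult physician for consulted patients) and
#' \code{"abx"} (consulted patients' alerts go to the ID physician only;
#' others to the attending).
#'
#' @param name policy era name.
#' @param targeted_drugs character vector of drug names subject to the
#'   time-out.
#' @return object of class \code{routing_policy}.
#' @export
routing_policy <- function(name = c("pre_duplication", "duplication", "abx"),
                           targeted_drugs) {
  name <- match.arg(name)
  if (length(targeted_drugs) == 0) {
    stop("routing policy requires at least one targeted drug", call. = FALSE)
  }
  duplicate_to_id_consult <- name == "duplication"
  id_only_when_consulted <- name == "abx"
  if (duplicate_to_id_consult && id_only_when_consulted) {
    stop("duplicate_to_id_consult and id_only_when_consulted are mutually ",
         "exclusive", call. = FALSE)
  }
  structure(list(name = name,
                 duplicate_to_id_consult = duplicate_to_id_consult,
                 id_only_when_consulted = id_only_when_consulted,
                 targeted_drugs = unique(targeted_drugs)),
            class = "routing_policy")
}

#' Does a patient-drug reach day 5 of continuous therapy on a given day?
#'
#' Tests the eligibility rule for alerting on \code{as_of}: the four
#' consecutive calendar days ending the day before \code{as_of} must each
#' contain at least two dose administrations, every gap between consecutive
#' administrations from the first dose of the window's first day to the last
#' dose of its fourth day must be at most 48 hours, and some order interval
#' must overlap \code{as_of} (start-inclusive, end-exclusive at day
#' boundaries).
#'
#' @param doses POSIXct vector of administration times for one patient-drug,
#'   sorted ascending.
#' @param orders data.frame with POSIXct columns \code{start}, \code{end}
#'   (active-order intervals for the same patient-drug).
#' @param as_of the calendar day (Date) under evaluation, i.e. the candidate
#'   fifth day.
#' @param gap_hours maximum permitted silent gap within the qualifying run.
#' @param min_daily_doses administrations required on each qualifying day.
#' @return list with \code{eligible} (logical), and when eligible
#'   \code{window_start}, \code{window_end} (first and fourth qualifying
#'   days, Dates).
#' @export
reaches_day5 <- function(doses, orders, as_of, gap_hours = 48,
                         min_daily_doses = 2L) {
  as_of <- as.Date(as_of)
  if (length(doses) == 0) {
    return(list(eligible = FALSE, window_start = as.Date(NA),
                window_end = as.Date(NA)))
  }
  if (is.unsorted(doses)) {
    stop("contract violation: dose timestamps must be sorted ascending",
         call. = FALSE)
  }
  window_days <- as_of - 4:1          # d, d+1, d+2, d+3
  window_days <- sort(window_days)
  dday <- day_of(doses)
  counts <- vapply(window_days, function(d) sum(dday == d), integer(1))
  if (any(counts < min_daily_doses)) {
    return(list(eligible = FALSE, window_start = as.Date(NA),
                window_end = as.Date(NA)))
  }
  run <- doses[dday >= window_days[1] & dday <= window_days[4]]
  if (length(run) >= 2) {
    gaps <- hours_between(run[-length(run)], run[-1])
    if (any(gaps > gap_hours)) {
      return(list(eligible = FALSE, window_start = as.Date(NA),
                  window_end = as.Date(NA)))
    }
  }
  day5_start <- day_time(as_of)
  day5_end <- day_time(as_of + 1)
  active <- nrow(orders) > 0 &&
    any(orders$start < day5_end & orders$end > day5_start)
  if (!active) {
    return(list(eligible = FALSE, window_start = as.Date(NA),
                window_end = as.Date(NA)))
  }
  list(eligible = TRUE, window_start = window_days[1],
       window_end = window_days[4])
}

# course index (1-based) of each dose, split where gaps exceed the threshold
course_assignment <- function(ts, gap_hours = 48) {
  if (length(ts) == 0) return(integer(0))
  if (length(ts) == 1) return(1L)
  gaps <- hours_between(ts[-length(ts)], ts[-1])
  cumsum(c(1L, as.integer(gaps > gap_hours)))
}

#' Scan a study window for day-5 time-out alerts
#'
#' Emulates the daily batch: for each calendar day in the window and each
#' patient-drug pair on a targeted drug, evaluates \code{\link{reaches_day5}}
#' and emits at most one alert per continuous course (a second alert for the
#' same patient-drug requires an intervening gap that breaks the rule, i.e. a
#' new course). Recipients follow the routing policy and the patient's
#' ID-consult flag.
#'
#' @param doses data.frame (patient_id, drug, timestamp).
#' @param orders data.frame (patient_id, drug, start, end).
#' @param policy a \code{\link{routing_policy}}.
#' @param start,end first and last calendar days (Date) of the scan.
#' @param id_consult character vector of patient_ids carrying an active ID
#'   consult.
#' @param gap_hours gap threshold shared with the eligibility rule.
#' @return data.frame of alert records: alert_id, patient_id, drug,
#'   alert_date, window_start, window_end, recipients (semicolon-joined),
#'   rationale_code, continued, responded.
#' @export
scan_alerts <- function(doses, orders, policy, start, end,
                        id_consult = character(), gap_hours = 48) {
  stopifnot(inherits(policy, "routing_policy"))
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("scan window start must not exceed end", call. = FALSE)
  targeted <- doses[doses$drug %in% policy$targeted_drugs, , drop = FALSE]
  out <- list()
  if (nrow(targeted) > 0) {
    keys <- unique(targeted[, c("patient_id", "drug")])
    for (i in seq_len(nrow(keys))) {
      pid <- keys$patient_id[i]; drg <- keys$drug[i]
      ts <- sort(targeted$timestamp[targeted$patient_id == pid &
                                      targeted$drug == drg])
      ords <- orders[orders$patient_id == pid & orders$drug == drg, ,
                     drop = FALSE]
      course <- course_assignment(ts, gap_hours)
      dday <- day_of(ts)
      candidates <- sort(unique(dday)) + 4L
      candidates <- candidates[candidates >= start & candidates <= end]
      alerted <- integer(0)
      for (a in seq_along(candidates)) {
        as_of <- candidates[a]
        r <- reaches_day5(ts, ords, as_of, gap_hours = gap_hours)
        if (!r$eligible) next
        cid <- course[match(r$window_start, dday)]
        if (cid %in% alerted) next
        alerted <- c(alerted, cid)
        consulted <- pid %in% id_consult
        rec <- alert_recipients(policy, consulted)
        out[[length(out) + 1L]] <- data.frame(
          patient_id = pid, drug = drg, alert_date = as_of,
          window_start = r$window_start, window_end = r$window_end,
          recipients = paste(rec, collapse = ";"),
          rationale_code = NA_character_, continued = NA,
          responded = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(alert_id = integer(0), patient_id = character(0),
                      drug = character(0), alert_date = as.Date(character(0)),
                      window_start = as.Date(character(0)),
                      window_end = as.Date(character(0)),
                      recipients = character(0),
                      rationale_code = character(0), continued = logical(0),
                      responded = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$alert_date, res$patient_id, res$drug), , drop = FALSE]
  res <- cbind(alert_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

alert_recipients <- function(policy, consulted) {
  if (policy$id_only_when_consulted && consulted) return("id_consult")
  if (policy$duplicate_to_id_consult && consulted) {
    return(c("attending", "id_consult"))
  }
  "attending"
}

#' Predefined rationale codes for continuing therapy past the time-out
#'
#' @return character vector of enumerated rationale codes; free text is also
#'   accepted by \code{\link{record_response}}.
#' @export
rationale_codes <- function() {
  c("documented_infection_culture_directed",
    "documented_infection_empiric",
    "febrile_neutropenia",
    "prophylaxis",
    "awaiting_culture_results",
    "id_consult_recommendation",
    "other_free_text")
}

#' Record a physician response to a time-out alert
#'
#' Append-only audit semantics: returns a new alert log with the response
#' attached; the input log is never modified. Responding twice to the same
#' alert is a conflict.
#'
#' @param alerts alert log from \code{\link{scan_alerts}}.
#' @param alert_id id of the alert being answered.
#' @param rationale_code one of \code{\link{rationale_codes}} or free text;
#'   required when \code{continued} is TRUE.
#' @param continued logical: was the antimicrobial continued?
#' @return the updated alert log.
#' @export
record_response <- function(alerts, alert_id, rationale_code = NA_character_,
                            continued = NA) {
  row <- which(alerts$alert_id == alert_id)
  if (length(row) != 1) {
    stop("unknown alert id: ", alert_id, call. = FALSE)
  }
  if (isTRUE(alerts$responded[row])) {
    stop("conflict: alert ", alert_id, " already has a recorded response",
         call. = FALSE)
  }
  alerts$rationale_code[row] <- rationale_code
  alerts$continued[row] <- continued
  alerts$responded[row] <- TRUE
  alerts
}

#' Write an alert log to CSV
#'
#' @param alerts alert log from \code{\link{scan_alerts}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_alerts <- function(alerts, path) {
  utils::write.csv(alerts, path, row.names = FALSE)
  invisible(path)
}
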