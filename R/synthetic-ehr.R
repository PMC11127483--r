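# Synthetic inpatient EHR event streams: antibiotic courses whose mean
# duration follows a segmented-linear trend with a level/slope break at an
# intervention month, dose administrations within courses, active-order
# intervals, a daily census, and annual infection counts with a log-linear
# secular trend. Everything is reproducible from a single integer seed.

#' Scenario configuration for the synthetic inpatient cohort
#'
#' Defines the study window, the intervention month, and per-drug generative
#' parameters: the monthly mean course duration follows
#' \code{baseline_duration + pre_slope * (t - t0)} before the intervention
#' month and gains \code{level_change + slope_change * (t - t0)} from the
#' intervention month onward (t = month index, t0 = intervention month).
#' Realised course durations are whole days, truncated below at 1.
#'
#' @param study_start,study_end first and last study months ("YYYY-MM").
#' @param intervention_month first post-intervention month ("YYYY-MM").
#' @param drugs data.frame with columns \code{drug}, \code{group}
#'   ("targeted"/"nontargeted"), \code{baseline_duration} (days),
#'   \code{pre_slope} (days/month), \code{level_change} (days),
#'   \code{slope_change} (days/month), \code{courses_per_month}
#'   (expected course initiations per month).
#' @param doses_per_day administrations per course day (default 2, 12 h apart,
#'   so dense courses satisfy the day-5 rule by construction).
#' @param dose_interval_hours spacing between same-day doses.
#' @param sparse_dosing if TRUE some course days get a single dose and some
#'   are skipped entirely, to exercise negative detector cases.
#' @param order_tail_hours how long the active order outlives the last dose.
#' @param census_mean_monthly mean hospital patient-days per month.
#' @param duration_noise SD (days) of Gaussian noise on each course's
#'   duration before rounding; 0 gives deterministic durations.
#' @param los_days fixed synthetic length of stay per admission (days).
#' @param seed integer random seed.
#' @return object of class \code{scenario_config}.
#' @export
scenario_config <- function(study_start = "2007-01",
                            study_end = "2015-03",
                            intervention_month = "2010-07",
                            drugs = default_drug_table(),
                            doses_per_day = 2L,
                            dose_interval_hours = 12,
                            sparse_dosing = FALSE,
                            order_tail_hours = 24,
                            census_mean_monthly = 18000,
                            duration_noise = 2,
                            los_days = 12,
                            seed = 1L) {
  start <- parse_month(study_start)
  end <- parse_month(study_end)
  t0 <- parse_month(intervention_month)
  if (!(start < t0 && t0 <= end)) {
    stop("configuration error: require study_start < intervention_month <= ",
         "study_end; got study_start=", month_label(start),
         ", intervention_month=", month_label(t0),
         ", study_end=", month_label(end), call. = FALSE)
  }
  req <- c("drug", "group", "baseline_duration", "pre_slope", "level_change",
           "slope_change", "courses_per_month")
  if (!is.data.frame(drugs) || !all(req %in% names(drugs))) {
    stop("configuration error: `drugs` must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(drugs$baseline_duration <= 0) || any(drugs$courses_per_month <= 0)) {
    stop("configuration error: baseline_duration and courses_per_month must ",
         "be strictly positive", call. = FALSE)
  }
  if (!all(drugs$group %in% c("targeted", "nontargeted"))) {
    stop("configuration error: drug group must be 'targeted' or 'nontargeted'",
         call. = FALSE)
  }
  if (duration_noise < 0 || census_mean_monthly <= 0 || order_tail_hours < 0) {
    stop("configuration error: noise/census/order_tail must be non-negative ",
         "(census strictly positive)", call. = FALSE)
  }
  structure(list(
    study_start = start, study_end = end, intervention_month = t0,
    drugs = drugs, doses_per_day = as.integer(doses_per_day),
    dose_interval_hours = dose_interval_hours, sparse_dosing = sparse_dosing,
    order_tail_hours = order_tail_hours,
    census_mean_monthly = census_mean_monthly,
    duration_noise = duration_noise, los_days = los_days,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Default two-drug demonstration scenario drug table
#'
#' One targeted drug with an injected immediate change of -1.0 day of mean
#' duration at the intervention, and one nontargeted null-control drug.
#'
#' @return data.frame of per-drug generative parameters.
#' @export
default_drug_table <- function() {
  data.frame(
    drug = c("daptomycin", "cefepime"),
    group = c("targeted", "nontargeted"),
    baseline_duration = c(6.2, 5.3),
    pre_slope = c(-0.01, -0.01),
    level_change = c(-1.0, 0.0),
    slope_change = c(0.0, 0.0),
    courses_per_month = c(40, 40),
    stringsAsFactors = FALSE
  )
}

# segmented-linear monthly mean duration implied by the config
segmented_mean <- function(t, t0, baseline, pre_slope, level_change,
                           slope_change) {
  post <- as.numeric(t >= t0)
  baseline + pre_slope * (t - t0) + post * (level_change +
                                              slope_change * (t - t0))
}

#' Generate a synthetic cohort of dose events, orders, census and admissions
#'
#' Per drug and month, the number of initiated courses is Poisson with the
#' configured rate; each course's whole-day duration is drawn around the
#' segmented-linear monthly mean (truncated below at 1 day); doses are
#' emitted within each course (2/day, 12 h apart by default); an order
#' interval spans each course plus a configurable tail; census rows cover
#' every study day. Each course occupies its own synthetic admission with an
#' opaque patient id.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return list with data.frames \code{doses} (patient_id, drug, timestamp),
#'   \code{orders} (patient_id, drug, start, end), \code{census}
#'   (date, patient_days), \code{admissions} (patient_id, admit, discharge).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  months <- month_seq(config$study_start, config$study_end)
  t <- month_number(months)
  t0 <- month_number(config$intervention_month)

  doses <- list(); orders <- list(); adm <- list()
  pid_counter <- 0L
  for (i in seq_len(nrow(config$drugs))) {
    dr <- config$drugs[i, ]
    mu <- segmented_mean(t, t0, dr$baseline_duration, dr$pre_slope,
                         dr$level_change, dr$slope_change)
    for (m in seq_along(months)) {
      k <- stats::rpois(1, dr$courses_per_month)
      if (k == 0) next
      start_offsets <- sample.int(days_in_month(months[m]), k, replace = TRUE)
      durations <- pmax(1, round(mu[m] +
        stats::rnorm(k, 0, config$duration_noise)))
      for (j in seq_len(k)) {
        pid_counter <- pid_counter + 1L
        pid <- sprintf("P%06d", pid_counter)
        start_day <- months[m] + (start_offsets[j] - 1L)
        ev <- course_dose_times(start_day, durations[j], config)
        if (length(ev) == 0) next
        doses[[length(doses) + 1L]] <- data.frame(
          patient_id = pid, drug = dr$drug, timestamp = ev,
          stringsAsFactors = FALSE)
        orders[[length(orders) + 1L]] <- data.frame(
          patient_id = pid, drug = dr$drug, start = min(ev),
          end = max(ev) + config$order_tail_hours * 3600,
          stringsAsFactors = FALSE)
        adm[[length(adm) + 1L]] <- data.frame(
          patient_id = pid, admit = start_day,
          discharge = start_day + config$los_days,
          stringsAsFactors = FALSE)
      }
    }
  }
  doses <- do.call(rbind, doses)
  orders <- do.call(rbind, orders)
  adm <- do.call(rbind, adm)
  doses <- doses[order(doses$patient_id, doses$drug, doses$timestamp), ,
                 drop = FALSE]
  rownames(doses) <- NULL; rownames(orders) <- NULL; rownames(adm) <- NULL

  days <- seq(config$study_start, add_months(config$study_end, 1) - 1, by = "day")
  pd <- round(config$census_mean_monthly /
                days_in_month(parse_month(format(days, "%Y-%m"))))
  census <- data.frame(date = days, patient_days = as.integer(pd))
  list(doses = doses, orders = orders, census = census, admissions = adm)
}

# dose timestamps for one course starting on start_day lasting `duration` days
course_dose_times <- function(start_day, duration, config) {
  hours <- 8 + config$dose_interval_hours * (seq_len(config$doses_per_day) - 1)
  hours <- hours[hours < 24]
  out <- vector("list", duration)
  for (d in seq_len(duration)) {
    h <- hours
    if (config$sparse_dosing) {
      u <- stats::runif(1)
      if (u < 0.15) next            # skipped day
      if (u < 0.45) h <- hours[1]   # single-dose day
    }
    out[[d]] <- day_time(start_day + (d - 1L), floor(h), round((h %% 1) * 60))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(as.POSIXct(character(), tz = "UTC"))
  sort(do.call(c, out))
}

#' Scenario configuration for annual healthcare-associated infection counts
#'
#' @param years integer vector of calendar years.
#' @param organisms data.frame with columns \code{organism},
#'   \code{baseline_rate} (events per 1000 patient-days in the first year) and
#'   \code{rate_ratio} (multiplicative per-year trend, > 0).
#' @param patient_days_per_year single value or per-year vector.
#' @param seed integer random seed.
#' @return object of class \code{hai_scenario_config}.
#' @export
hai_scenario_config <- function(years = 2007:2015,
                                organisms = default_hai_table(),
                                patient_days_per_year = 200000,
                                seed = 1L) {
  if (length(years) == 0) {
    stop("configuration error: empty year list", call. = FALSE)
  }
  req <- c("organism", "baseline_rate", "rate_ratio")
  if (!is.data.frame(organisms) || !all(req %in% names(organisms))) {
    stop("configuration error: `organisms` must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(organisms$rate_ratio <= 0) || any(organisms$baseline_rate < 0)) {
    stop("configuration error: rate_ratio must be > 0 and baseline_rate >= 0",
         call. = FALSE)
  }
  pd <- rep_len(patient_days_per_year, length(years))
  if (any(pd <= 0)) {
    stop("configuration error: patient_days_per_year must be positive",
         call. = FALSE)
  }
  structure(list(years = as.integer(years), organisms = organisms,
                 patient_days = pd, seed = as.integer(seed)),
            class = "hai_scenario_config")
}

#' Default organism table for the HAI scenario
#'
#' Plausible baseline incidence rates (per 1000 patient-days) and secular
#' per-year rate ratios for the surveilled organism categories in a large
#' oncology hospital; CDI is given a flat trend.
#'
#' @return data.frame of per-organism generative parameters.
#' @export
default_hai_table <- function() {
  data.frame(
    organism = c("MRSA", "VRE", "MDR-PA", "ESBL", "CRE", "CDI"),
    baseline_rate = c(1.2, 1.0, 0.6, 0.8, 0.3, 1.5),
    rate_ratio = c(0.84, 0.90, 0.86, 1.04, 0.93, 1.00),
    stringsAsFactors = FALSE
  )
}

#' Generate annual organism counts under a log-linear secular trend
#'
#' For organism o in year index t (0-based), the count is Poisson with mean
#' \code{baseline_rate_o * rate_ratio_o^t * patient_days_t / 1000}.
#'
#' @param config a \code{\link{hai_scenario_config}}.
#' @return data.frame (year, organism, count, patient_days).
#' @export
generate_hai_counts <- function(config) {
  stopifnot(inherits(config, "hai_scenario_config"))
  set.seed(config$seed)
  tt <- seq_along(config$years) - 1L
  out <- lapply(seq_len(nrow(config$organisms)), function(i) {
    o <- config$organisms[i, ]
    lambda <- o$baseline_rate * o$rate_ratio^tt * config$patient_days / 1000
    data.frame(year = config$years, organism = o$organism,
               count = stats::rpois(length(tt), lambda),
               patient_days = as.integer(round(config$patient_days)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes \code{doses.csv}, \code{orders.csv}, \code{census.csv} and
#' \code{admissions.csv} (ISO-8601 timestamps, UTF-8, RFC-4180).
#'
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- cohort$doses
  d$timestamp <- fmt_ts(d$timestamp)
  o <- cohort$orders
  o$start <- fmt_ts(o$start); o$end <- fmt_ts(o$end)
  paths <- c(doses = file.path(dir, "doses.csv"),
             orders = file.path(dir, "orders.csv"),
             census = file.path(dir, "census.csv"),
             admissions = file.path(dir, "admissions.csv"))
  utils::write.csv(d, paths["doses"], row.names = FALSE)
  utils::write.csv(o, paths["orders"], row.names = FALSE)
  utils::write.csv(cohort$census, paths["census"], row.names = FALSE)
  utils::write.csv(cohort$admissions, paths["admissions"], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort back from CSV files
#'
#' @param dir directory containing \code{doses.csv}, \code{orders.csv},
#'   \code{census.csv} and optionally \code{admissions.csv}.
#' @return list as produced by \code{\link{generate_cohort}}.
#' @export
read_cohort <- function(dir) {
  d <- utils::read.csv(file.path(dir, "doses.csv"), stringsAsFactors = FALSE)
  d$timestamp <- parse_ts(d$timestamp)
  o <- utils::read.csv(file.path(dir, "orders.csv"), stringsAsFactors = FALSE)
  o$start <- parse_ts(o$start); o$end <- parse_ts(o$end)
  cz <- utils::read.csv(file.path(dir, "census.csv"), stringsAsFactors = FALSE)
  cz$date <- as.Date(cz$date)
  out <- list(doses = d, orders = o, census = cz)
  apath <- file.path(dir, "admissions.csv")
  if (file.exists(apath)) {
    a <- utils::read.csv(apath, stringsAsFactors = FALSE)
    a$admit <- as.Date(a$admit); a$discharge <- as.Date(a$discharge)
    out$admissions <- a
  }
  out
}
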