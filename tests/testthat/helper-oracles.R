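# Independent brute-force oracles and fixture generators shared across the
# suite. The oracles deliberately use the most literal formulation available
# (explicit loops, minute-grid enumeration, transitive closure, explicit
# normal equations) so they stay independent of the package's vectorised
# implementations.

utc <- function(x) as.POSIXct(x, tz = "UTC")
empty_orders <- function() {
  data.frame(start = utc(character(0)), end = utc(character(0)))
}

# Literal re-reading of the day-5 rule: test the (single) candidate 4-day
# window ending the day before as_of, dose by dose; decide order presence on
# the fifth day by enumerating every minute of that day.
oracle_reaches_day5 <- function(doses, orders, as_of, gap_hours = 48) {
  doses <- sort(doses)
  days <- sort(as_of - 4:1)
  for (day in seq_along(days)) {
    n <- 0
    for (i in seq_along(doses)) {
      if (as.Date(doses[i], tz = "UTC") == days[day]) n <- n + 1
    }
    if (n < 2) return(FALSE)
  }
  run <- doses[as.Date(doses, tz = "UTC") >= days[1] &
                 as.Date(doses, tz = "UTC") <= days[4]]
  run <- sort(run)
  if (length(run) >= 2) {
    for (i in 2:length(run)) {
      gap_sec <- as.numeric(difftime(run[i], run[i - 1], units = "secs"))
      if (gap_sec > gap_hours * 3600) return(FALSE)
    }
  }
  minutes <- abxtimeout::day_time(as_of) + 60 * (0:1439)
  active <- FALSE
  if (nrow(orders) > 0) {
    for (j in seq_len(nrow(orders))) {
      if (any(minutes >= orders$start[j] & minutes < orders$end[j])) {
        active <- TRUE
      }
    }
  }
  active
}

# Unstructured random instance: doses at arbitrary minutes over a short span.
random_day5_instance <- function(base = as.Date("2021-03-01")) {
  ndays <- sample(5:8, 1)
  ndoses <- sample(0:14, 1)
  doses <- if (ndoses > 0) {
    abxtimeout::day_time(base) + 60 * sort(sample(0:(ndays * 1440 - 1), ndoses))
  } else utc(character(0))
  norders <- sample(0:2, 1)
  orders <- if (norders > 0) {
    s <- sample(0:(ndays * 1440 - 1), norders)
    len <- sample(60:(4 * 1440), norders, replace = TRUE)
    data.frame(start = abxtimeout::day_time(base) + 60 * s,
               end = abxtimeout::day_time(base) + 60 * (s + len))
  } else empty_orders()
  list(doses = doses, orders = orders,
       as_of = base + sample(4:ndays, 1))
}

# Structured instance biased toward (near-)qualifying patterns: 1-3 doses on
# each of the four days before as_of, occasionally a missing or extra day.
structured_day5_instance <- function(base = as.Date("2021-03-01")) {
  as_of <- base + 4
  doses <- utc(character(0))
  for (d in 0:3) {
    k <- sample(0:3, 1, prob = c(0.1, 0.2, 0.5, 0.2))
    if (k > 0) {
      doses <- c(doses, abxtimeout::day_time(base + d) +
                   60 * sort(sample(0:1439, k)))
    }
  }
  if (stats::runif(1) < 0.3) {   # stray doses outside the window
    doses <- c(doses, abxtimeout::day_time(base + sample(c(-1, 4, 5), 1)) +
                 60 * sample(0:1439, 1))
  }
  doses <- sort(doses)
  orders <- switch(sample(1:3, 1),
    data.frame(start = abxtimeout::day_time(base),
               end = abxtimeout::day_time(base + 6)),      # covers day 5
    data.frame(start = abxtimeout::day_time(base),
               end = abxtimeout::day_time(as_of)),          # ends at day-5 midnight
    empty_orders())
  list(doses = doses, orders = orders, as_of = as_of)
}

# Transitive-closure clustering of doses under the "gap <= threshold"
# relation; returns course sizes in time order.
oracle_course_sizes <- function(ts, gap_hours = 48) {
  ts <- sort(ts)
  n <- length(ts)
  if (n == 0) return(integer(0))
  adj <- abs(outer(as.numeric(ts), as.numeric(ts), "-")) <= gap_hours * 3600
  adj <- adj * 1
  repeat {
    new <- ((adj + adj %*% adj) > 0) * 1
    if (identical(new, adj)) break
    adj <- new
  }
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      k <- k + 1L
      comp[adj[i, ] > 0] <- k
    }
  }
  as.integer(table(factor(comp, levels = unique(comp))))
}

# Closed-form log-linear trend fit: OLS of log(count/patient_days) on year.
oracle_loglinear_irr <- function(records) {
  fit <- stats::lm(log(count / patient_days) ~ year, data = records)
  exp(unname(stats::coef(fit)[2]))
}

# Literal re-encoding of the MDR P. aeruginosa sentence on a named character
# vector of agent results.
oracle_mdr_pa <- function(res) {
  if (res[["meropenem"]] == "resistant") return(TRUE)
  if (res[["imipenem"]] == "resistant") return(TRUE)
  g1 <- res[["ceftazidime"]] == "resistant" || res[["cefepime"]] == "resistant"
  g2 <- res[["piperacillin_tazobactam"]] == "resistant"
  g3 <- res[["ciprofloxacin"]] == "resistant" ||
    res[["levofloxacin"]] == "resistant"
  (g1 + g2 + g3) >= 3
}

mdr_agents <- c("meropenem", "imipenem", "ceftazidime", "cefepime",
                "piperacillin_tazobactam", "ciprofloxacin", "levofloxacin")

# the i-th (1-based) of the 3^7 possible profiles as a named character vector
mdr_profile_from_index <- function(i) {
  lv <- c("resistant", "susceptible", "unknown")
  digits <- integer(7)
  i <- i - 1L
  for (k in 1:7) {
    digits[k] <- i %% 3L
    i <- i %/% 3L
  }
  stats::setNames(lv[digits + 1L], mdr_agents)
}

# dense twice-daily dosing fixture for one patient-drug
make_course_doses <- function(pid, drug, start_day, n_days,
                              hours = c(8, 20)) {
  days <- rep(start_day + 0:(n_days - 1), each = length(hours))
  data.frame(patient_id = pid, drug = drug,
             timestamp = abxtimeout::day_time(days, rep(hours, n_days)),
             stringsAsFactors = FALSE)
}

flat_census <- function(start_month, end_month, per_day = 600) {
  days <- seq(abxtimeout::parse_month(start_month),
              abxtimeout::add_months(end_month, 1) - 1, by = "day")
  data.frame(date = days, patient_days = per_day)
}

# small fast scenario for cross-module and pipeline tests
mini_scenario <- function(seed = 7, noise = 0, ...) {
  scenario_config(
    study_start = "2007-01", study_end = "2008-06",
    intervention_month = "2007-10",
    drugs = data.frame(
      drug = c("meropenem", "cefepime"),
      group = c("targeted", "nontargeted"),
      baseline_duration = c(7, 6), pre_slope = c(0, 0),
      level_change = c(-2, 0), slope_change = c(0, 0),
      courses_per_month = c(10, 10), stringsAsFactors = FALSE),
    duration_noise = noise, seed = seed, ...)
}
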