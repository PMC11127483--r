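base_day <- as.Date("2020-01-01")

dense_doses <- function(days, hours = c(8, 20), base = base_day) {
  sort(day_time(rep(base + days, each = length(hours)),
                rep(hours, length(days))))
}

test_that("day-5 rule: definitional positive and single-condition negatives", {
  ords <- data.frame(start = day_time(base_day), end = day_time(base_day + 6))
  ts <- dense_doses(0:3)
  r <- reaches_day5(ts, ords, base_day + 4)
  expect_true(r$eligible)
  expect_equal(r$window_start, base_day)
  expect_equal(r$window_end, base_day + 3)

  # only one dose on the third day
  ts1 <- ts[!(day_of(ts) == base_day + 2 & format(ts, "%H") == "20")]
  expect_false(reaches_day5(ts1, ords, base_day + 4)$eligible)

  # 49-hour silent gap inside the run (day 3 doses removed entirely would
  # fail the count; instead push day 3's doses to violate the gap)
  ts2 <- sort(c(dense_doses(0:1), day_time(base_day + 2, 23, 30),
                day_time(base_day + 2, 23, 45), dense_doses(3, hours = c(8, 20))))
  gap <- as.numeric(difftime(day_time(base_day + 2, 23, 30),
                             day_time(base_day + 1, 20), units = "hours"))
  expect_gt(gap, 27)  # still under 48 — this pattern remains eligible
  expect_true(reaches_day5(ts2, ords, base_day + 4)$eligible)
  # a genuine >48 h silence: two doses late on day 1, none until day 4 fails
  # the per-day count first, so violate the gap with min_daily_doses met via
  # a 49-hour stretch between day 2's last and day 4's... not constructible
  # inside a 4-day window with >=2 doses/day; verified via the oracle below.

  # no order on the fifth day
  ords2 <- data.frame(start = day_time(base_day),
                      end = day_time(base_day + 4))  # ends midnight of day 5
  expect_false(reaches_day5(ts, ords2, base_day + 4)$eligible)

  # empty dose list is false, not an error
  expect_false(reaches_day5(day_time(base_day)[0], ords,
                            base_day + 4)$eligible)
  # unsorted input violates the contract
  expect_error(reaches_day5(rev(ts), ords, base_day + 4),
               "contract violation")
})

test_that("gap rule is enforced within the qualifying run", {
  ords <- data.frame(start = day_time(base_day), end = day_time(base_day + 6))
  # doses of a different drug never rescue a silent gap: the stream handed to
  # the detector is per-drug, so a day dosed only with another drug is an
  # empty day for the queried drug and the window fails
  ts_other_drug_day3 <- dense_doses(c(0, 1, 3))
  expect_false(reaches_day5(ts_other_drug_day3, ords, base_day + 4)$eligible)

  # with the calendar-day reading and >=2 doses/day, consecutive dosed days
  # can never be >48 h apart, so exercise the gap logic at a tighter
  # threshold: pushing day 2's doses to just after midnight opens a 31.5 h
  # silence before day 3's first dose
  ts <- sort(c(dense_doses(c(0, 2, 3)), day_time(base_day + 1, 0, c(0, 30))))
  expect_true(reaches_day5(ts, ords, base_day + 4)$eligible)
  expect_false(reaches_day5(ts, ords, base_day + 4,
                            gap_hours = 20)$eligible)
})

test_that("detector agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:400) {
    inst <- if (i %% 2 == 0) random_day5_instance() else
      structured_day5_instance()
    got <- reaches_day5(inst$doses, inst$orders, inst$as_of)$eligible
    want <- oracle_reaches_day5(inst$doses, inst$orders, inst$as_of)
    expect_identical(got, want,
                     info = sprintf("instance %d disagrees with oracle", i))
  }
})

test_that("adding a dose never turns an eligible patient ineligible", {
  set.seed(202)
  checked <- 0
  for (i in 1:300) {
    inst <- structured_day5_instance()
    if (!reaches_day5(inst$doses, inst$orders, inst$as_of)$eligible) next
    checked <- checked + 1
    extra <- day_time(inst$as_of - sample(1:4, 1)) + 60 * sample(0:1439, 1)
    augmented <- sort(c(inst$doses, extra))
    expect_true(reaches_day5(augmented, inst$orders, inst$as_of)$eligible)
    expect_true(oracle_reaches_day5(augmented, inst$orders, inst$as_of))
  }
  expect_gt(checked, 20)
})

test_that("whole-day time translation shifts alert dates equally", {
  doses <- make_course_doses("p1", "meropenem", base_day, 7)
  orders <- data.frame(patient_id = "p1", drug = "meropenem",
                       start = min(doses$timestamp),
                       end = max(doses$timestamp) + 24 * 3600,
                       stringsAsFactors = FALSE)
  pol <- routing_policy("pre_duplication", "meropenem")
  a0 <- scan_alerts(doses, orders, pol, base_day, base_day + 30)
  for (shift in c(3, 11)) {
    d2 <- doses; d2$timestamp <- d2$timestamp + shift * 86400
    o2 <- orders; o2$start <- o2$start + shift * 86400
    o2$end <- o2$end + shift * 86400
    a2 <- scan_alerts(d2, o2, pol, base_day, base_day + 60)
    expect_equal(a2$alert_date, a0$alert_date + shift)
    expect_equal(a2$window_start, a0$window_start + shift)
  }
})

test_that("scan emits one alert per course and none for nontargeted drugs", {
  pol <- routing_policy("pre_duplication", "meropenem")
  # one 10-day continuously dosed course -> exactly one alert, on day 5
  doses <- make_course_doses("p1", "meropenem", base_day, 10)
  orders <- data.frame(patient_id = "p1", drug = "meropenem",
                       start = min(doses$timestamp),
                       end = max(doses$timestamp) + 24 * 3600,
                       stringsAsFactors = FALSE)
  al <- scan_alerts(doses, orders, pol, base_day, base_day + 30)
  expect_equal(nrow(al), 1L)
  expect_equal(al$alert_date, base_day + 4)

  # two courses separated by a 5-day gap -> two alerts
  doses2 <- rbind(doses, make_course_doses("p1", "meropenem",
                                           base_day + 15, 6))
  orders2 <- rbind(orders, data.frame(
    patient_id = "p1", drug = "meropenem",
    start = day_time(base_day + 15, 8),
    end = day_time(base_day + 20, 20) + 24 * 3600,
    stringsAsFactors = FALSE))
  al2 <- scan_alerts(doses2, orders2, pol, base_day, base_day + 40)
  expect_equal(nrow(al2), 2L)
  expect_equal(al2$alert_date, c(base_day + 4, base_day + 19))

  # a drug outside the policy never alerts
  doses3 <- doses; doses3$drug <- "cefepime"
  orders3 <- orders; orders3$drug <- "cefepime"
  expect_equal(nrow(scan_alerts(doses3, orders3, pol, base_day,
                                base_day + 30)), 0L)
})

test_that("alert counts match course counts on a dense synthetic cohort", {
  cfg <- scenario_config(
    study_start = "2007-01", study_end = "2007-06",
    intervention_month = "2007-04",
    drugs = data.frame(drug = c("meropenem", "cefepime"),
                       group = c("targeted", "nontargeted"),
                       baseline_duration = c(7, 7), pre_slope = c(0, 0),
                       level_change = c(0, 0), slope_change = c(0, 0),
                       courses_per_month = c(5, 5), stringsAsFactors = FALSE),
    duration_noise = 0, seed = 21)
  co <- generate_cohort(cfg)
  pol <- routing_policy("pre_duplication", "meropenem")
  al <- scan_alerts(co$doses, co$orders, pol, as.Date("2007-01-01"),
                    as.Date("2007-07-31"))
  courses <- build_courses(co$doses)
  n_target <- sum(courses$drug == "meropenem")
  expect_equal(nrow(al), n_target)
  expect_true(all(al$drug == "meropenem"))
})

test_that("routing policy eras set recipients from the ID-consult flag", {
  doses <- make_course_doses("p1", "meropenem", base_day, 6)
  orders <- data.frame(patient_id = "p1", drug = "meropenem",
                       start = min(doses$timestamp),
                       end = max(doses$timestamp) + 24 * 3600,
                       stringsAsFactors = FALSE)
  rec <- function(policy, consulted) {
    al <- scan_alerts(doses, orders, routing_policy(policy, "meropenem"),
                      base_day, base_day + 10,
                      id_consult = if (consulted) "p1" else character(0))
    al$recipients
  }
  expect_equal(rec("pre_duplication", TRUE), "attending")
  expect_equal(rec("duplication", FALSE), "attending")
  expect_equal(rec("duplication", TRUE), "attending;id_consult")
  expect_equal(rec("abx", TRUE), "id_consult")
  expect_equal(rec("abx", FALSE), "attending")
  expect_error(routing_policy("duplication", character(0)), "targeted drug")
})

test_that("alert responses are append-only with conflict detection", {
  doses <- make_course_doses("p1", "meropenem", base_day, 6)
  orders <- data.frame(patient_id = "p1", drug = "meropenem",
                       start = min(doses$timestamp),
                       end = max(doses$timestamp) + 24 * 3600,
                       stringsAsFactors = FALSE)
  al <- scan_alerts(doses, orders, routing_policy("abx", "meropenem"),
                    base_day, base_day + 10)
  al2 <- record_response(al, al$alert_id[1],
                         "documented_infection_culture_directed",
                         continued = TRUE)
  expect_false(al$responded[1])           # original log untouched
  expect_true(al2$responded[1])
  expect_equal(al2$rationale_code[1], "documented_infection_culture_directed")
  expect_error(record_response(al2, al$alert_id[1], "prophylaxis", FALSE),
               "conflict")
  expect_error(record_response(al, 999L, "prophylaxis", FALSE),
               "unknown alert id")
})
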