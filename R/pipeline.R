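# End-to-end pipeline: simulate (or load) the event streams, scan day-5
# alerts, aggregate monthly consumption, fit the segmented models per drug
# and metric, estimate HAI trends, and write a reproducible report bundle
# (CSVs + manifest + rendered tables). All randomness flows from the single
# config seed through per-stage derived sub-seeds.

#' Pipeline configuration
#'
#' Exactly one of \code{scenario} (simulation mode) or \code{input_dir}
#' (CSV mode: doses.csv, orders.csv, census.csv and optionally
#' admissions.csv / hai.csv) must be supplied.
#'
#' @param scenario a \code{\link{scenario_config}} for simulation mode.
#' @param hai_scenario optional \code{\link{hai_scenario_config}}
#'   (simulation mode only).
#' @param input_dir directory of input CSVs for data mode.
#' @param t0_month change-point month for the segmented fits; defaults to the
#'   scenario's intervention month in simulation mode.
#' @param policy_name routing policy era (see \code{\link{routing_policy}}).
#' @param targeted_drugs,nontargeted_drugs drug lists (must be disjoint);
#'   default from the scenario's drug table in simulation mode.
#' @param out_dir output directory for the report bundle.
#' @param seed master seed for the run (simulation mode).
#' @param log_level "quiet" or "info" (stage-tagged messages on stderr).
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scenario = NULL, hai_scenario = NULL,
                            input_dir = NULL, t0_month = NULL,
                            policy_name = "abx", targeted_drugs = NULL,
                            nontargeted_drugs = NULL, out_dir = tempfile("abx"),
                            seed = 1L, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(scenario) == is.null(input_dir)) {
    stop("supply exactly one of `scenario` (simulation mode) or `input_dir` ",
         "(data mode)", call. = FALSE)
  }
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "scenario_config"))
    if (is.null(targeted_drugs)) {
      targeted_drugs <- scenario$drugs$drug[scenario$drugs$group == "targeted"]
    }
    if (is.null(nontargeted_drugs)) {
      nontargeted_drugs <-
        scenario$drugs$drug[scenario$drugs$group == "nontargeted"]
    }
    if (is.null(t0_month)) t0_month <- scenario$intervention_month
  }
  if (is.null(t0_month)) {
    stop("t0_month is required in data mode", call. = FALSE)
  }
  if (length(intersect(targeted_drugs, nontargeted_drugs)) > 0) {
    stop("targeted and nontargeted drug lists must be disjoint", call. = FALSE)
  }
  structure(list(scenario = scenario, hai_scenario = hai_scenario,
                 input_dir = input_dir, t0_month = parse_month(t0_month),
                 policy_name = policy_name, targeted_drugs = targeted_drugs,
                 nontargeted_drugs = nontargeted_drugs, out_dir = out_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' Two-drug demonstration configuration
#'
#' The living end-to-end example: a 2007-01 to 2015-03 monthly study with
#' change point 2010-07, one targeted drug with an injected immediate change
#' of -1.0 day of mean duration and one nontargeted null-control drug, plus
#' the annual HAI scenario.
#'
#' @param seed master seed (documented default 20100701).
#' @param out_dir output directory.
#' @param ... passed on to \code{\link{scenario_config}}.
#' @return a \code{\link{pipeline_config}}.
#' @export
demo_config <- function(seed = 20100701, out_dir = tempfile("abx-demo"), ...) {
  drugs <- default_drug_table()
  drugs$level_change[drugs$group == "targeted"] <- -1.0
  pipeline_config(
    scenario = scenario_config(drugs = drugs, duration_noise = 2,
                               seed = seed %% 2147483647L, ...),
    hai_scenario = hai_scenario_config(seed = (seed + 1) %% 2147483647L),
    out_dir = out_dir, seed = seed)
}

stage_log <- function(config, stage, ...) {
  if (identical(config$log_level, "info")) {
    message("[", stage, "] ", ...)
  }
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, alert scan, monthly consumption, segmented
#' regression per drug and metric, and HAI trend estimation; writes the CSV
#' bundle, rendered tables and a JSON run manifest into the output
#' directory. Identical config and seed give an identical bundle.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list: cohort, alerts, courses, consumption,
#'   its_report, hai, hai_trends, manifest, paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$scenario)) {
    stage_log(config, "simulate", "generating synthetic cohort (seed ",
              config$scenario$seed, ")")
    cohort <- generate_cohort(config$scenario)
    hai <- if (!is.null(config$hai_scenario)) {
      generate_hai_counts(config$hai_scenario)
    }
    write_cohort(cohort, config$out_dir)
    if (!is.null(hai)) {
      utils::write.csv(hai, file.path(config$out_dir, "hai.csv"),
                       row.names = FALSE)
    }
    start_month <- config$scenario$study_start
    end_month <- config$scenario$study_end
  } else {
    stage_log(config, "load", "reading CSVs from ", config$input_dir)
    cohort <- read_cohort(config$input_dir)
    hpath <- file.path(config$input_dir, "hai.csv")
    hai <- if (file.exists(hpath)) {
      utils::read.csv(hpath, stringsAsFactors = FALSE)
    }
    days <- as.Date(cohort$census$date)
    start_month <- parse_month(format(min(days), "%Y-%m"))
    end_month <- parse_month(format(max(days), "%Y-%m"))
  }

  policy <- routing_policy(config$policy_name, config$targeted_drugs)
  stage_log(config, "scan", "scanning day-5 alerts (policy ", policy$name, ")")
  alerts <- scan_alerts(cohort$doses, cohort$orders, policy,
                        start = start_month,
                        end = add_months(end_month, 1) - 1)
  write_alerts(alerts, file.path(config$out_dir, "alerts.csv"))

  stage_log(config, "metrics", "building courses and monthly consumption")
  courses <- build_courses(cohort$doses)
  consumption <- monthly_consumption(courses, cohort$doses, cohort$census,
                                     start_month, end_month)
  utils::write.csv(consumption,
                   file.path(config$out_dir, "monthly_consumption.csv"),
                   row.names = FALSE)

  stage_log(config, "its", "fitting segmented models (t0 ",
            month_label(config$t0_month), ")")
  groups <- c(stats::setNames(rep("targeted", length(config$targeted_drugs)),
                              config$targeted_drugs),
              stats::setNames(rep("nontargeted",
                                  length(config$nontargeted_drugs)),
                              config$nontargeted_drugs))
  its_report <- rbind(
    batch_report(consumption, groups, "mean_duration", config$t0_month),
    batch_report(consumption, groups, "dot_per_1000pd", config$t0_month))
  utils::write.csv(its_report, file.path(config$out_dir, "its_report.csv"),
                   row.names = FALSE)

  hai_trends <- NULL
  if (!is.null(hai)) {
    stage_log(config, "hai", "estimating annual HAI trends")
    hai_trends <- hai_trend_report(hai)
    utils::write.csv(hai_trends, file.path(config$out_dir, "hai_trends.csv"),
                     row.names = FALSE)
  }

  tables <- render_tables(its_report)
  writeLines(tables$text, file.path(config$out_dir, "tables.txt"))
  utils::write.csv(tables$delimited,
                   file.path(config$out_dir, "its_tables_rounded.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("abxtimeout")),
    seed = config$seed,
    mode = if (is.null(config$scenario)) "data" else "simulation",
    t0_month = month_label(config$t0_month),
    policy = config$policy_name,
    targeted_drugs = config$targeted_drugs,
    nontargeted_drugs = config$nontargeted_drugs,
    row_counts = list(doses = nrow(cohort$doses), orders = nrow(cohort$orders),
                      census = nrow(cohort$census), alerts = nrow(alerts),
                      courses = nrow(courses),
                      monthly_consumption = nrow(consumption),
                      its_report = nrow(its_report),
                      hai = if (is.null(hai)) 0L else nrow(hai),
                      hai_trends = if (is.null(hai_trends)) 0L
                                   else nrow(hai_trends)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, alerts = alerts, courses = courses,
                 consumption = consumption, its_report = its_report,
                 hai = hai, hai_trends = hai_trends, manifest = manifest,
                 out_dir = config$out_dir))
}

#' Render publication-style tables from a segmented-regression report
#'
#' Produces an aligned plain-text table and a delimited (data.frame) table
#' with the intercept block (baseline value, immediate change, 95% CI, p)
#' and slope block (baseline slope, slope change, 95% CI, p), numbers
#' rounded to 2 decimals.
#'
#' @param its_report data.frame from \code{\link{batch_report}} (possibly
#'   both metrics stacked).
#' @return list with \code{text} (character vector of lines) and
#'   \code{delimited} (rounded data.frame).
#' @export
render_tables <- function(its_report) {
  num_cols <- c("baseline_value", "level_change", "level_ci_low",
                "level_ci_high", "level_p", "baseline_slope", "slope_change",
                "slope_ci_low", "slope_ci_high", "slope_p")
  delim <- its_report[, c("drug", "group", "metric", num_cols), drop = FALSE]
  for (cc in num_cols) delim[[cc]] <- round(delim[[cc]], 2)

  header <- c("drug", "group", "baseline", "change", "95% CI", "p",
              "slope", "slope change", "95% CI", "p")
  lines <- character(0)
  for (met in unique(its_report$metric)) {
    sub <- delim[delim$metric == met, , drop = FALSE]
    title <- if (met == "mean_duration") {
      "Change in mean duration of therapy (days)"
    } else if (met == "dot_per_1000pd") {
      "Change in days of therapy per 1000 patient-days"
    } else met
    body <- if (nrow(sub) == 0) {
      character(0)
    } else {
      apply(sub, 1, function(r) {
        ci1 <- paste0(r[["level_ci_low"]], " to ", r[["level_ci_high"]])
        ci2 <- paste0(r[["slope_ci_low"]], " to ", r[["slope_ci_high"]])
        c(r[["drug"]], r[["group"]], r[["baseline_value"]],
          r[["level_change"]], ci1, r[["level_p"]], r[["baseline_slope"]],
          r[["slope_change"]], ci2, r[["slope_p"]])
      })
    }
    m <- rbind(header, if (length(body)) t(body))
    widths <- apply(nchar(m), 2, max)
    fmt_row <- function(r) paste(mapply(formatC, r, width = widths,
                                        flag = "-"), collapse = "  ")
    lines <- c(lines, title, strrep("-", sum(widths) + 2 * (ncol(m) - 1)),
               apply(m, 1, fmt_row), "")
  }
  list(text = lines, delimited = delim)
}
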