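# Healthcare-associated infection surveillance: the multidrug-resistant
# P. aeruginosa classification rule and annual secular-trend estimation by
# Poisson regression with a patient-day exposure offset.

mdr_pa_agents <- c("meropenem", "imipenem", "ceftazidime", "cefepime",
                   "piperacillin_tazobactam", "ciprofloxacin", "levofloxacin")

#' Construct a susceptibility profile
#'
#' @param organism organism name.
#' @param ... per-agent results for meropenem, imipenem, ceftazidime,
#'   cefepime, piperacillin_tazobactam, ciprofloxacin, levofloxacin; each one
#'   of "resistant", "susceptible", "unknown". Unspecified agents default to
#'   "unknown"; at least one result must be known.
#' @return object of class \code{susceptibility_profile}.
#' @export
susceptibility_profile <- function(organism, ...) {
  res <- list(...)
  bad <- setdiff(names(res), mdr_pa_agents)
  if (length(bad) > 0) {
    stop("unknown agent(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  prof <- stats::setNames(rep("unknown", length(mdr_pa_agents)),
                          mdr_pa_agents)
  for (a in names(res)) {
    v <- match.arg(res[[a]], c("resistant", "susceptible", "unknown"))
    prof[a] <- v
  }
  if (all(prof == "unknown")) {
    stop("profile must contain at least one known result", call. = FALSE)
  }
  structure(list(organism = organism, results = prof),
            class = "susceptibility_profile")
}

#' Classify a P. aeruginosa isolate as multidrug-resistant
#'
#' An isolate is MDR when it is resistant to meropenem or imipenem, or
#' resistant to at least 3 of the 3 antipseudomonal groups
#' \{ceftazidime/cefepime\}, \{piperacillin-tazobactam\},
#' \{ciprofloxacin/levofloxacin\} (a group counts as resistant when any
#' member is resistant; an unknown result never counts as resistant).
#'
#' @param profile a \code{\link{susceptibility_profile}}, or a named
#'   character vector/list of per-agent results.
#' @return logical.
#' @export
classify_mdr_pa <- function(profile) {
  if (inherits(profile, "susceptibility_profile")) {
    if (!grepl("aeruginosa", profile$organism, ignore.case = TRUE)) {
      stop("domain error: MDR classification applies to P. aeruginosa, got '",
           profile$organism, "'", call. = FALSE)
    }
    res <- profile$results
  } else {
    res <- unlist(profile)
  }
  r <- function(agent) !is.na(res[agent]) && res[[agent]] == "resistant"
  if (r("meropenem") || r("imipenem")) return(TRUE)
  groups <- c(r("ceftazidime") || r("cefepime"),
              r("piperacillin_tazobactam"),
              r("ciprofloxacin") || r("levofloxacin"))
  sum(groups) >= 3
}

#' Annual incidence rate per 1000 patient-days
#'
#' @param count infection count.
#' @param patient_days patient-days in the same period (> 0).
#' @return rate per 1000 patient-days.
#' @export
incidence_rate <- function(count, patient_days) {
  if (any(patient_days <= 0)) {
    stop("patient_days must be strictly positive", call. = FALSE)
  }
  1000 * count / patient_days
}

#' Poisson secular trend in annual infection rates
#'
#' Fits \code{log E[count_t] = alpha + gamma * year_t + log(patient_days_t)}
#' by Poisson maximum likelihood and reports the incidence rate ratio per
#' year, \code{IRR = exp(gamma)}, with a Wald 95\% CI on the log scale and a
#' two-sided p-value.
#'
#' @param records data.frame (year, count, patient_days) for one organism,
#'   with at least 3 years.
#' @param level confidence level.
#' @return one-row data.frame (irr, ci_low, ci_high, p, se_log, n_years).
#' @export
poisson_trend <- function(records, level = 0.95) {
  if (nrow(records) < 3) {
    stop("insufficient data: need at least 3 years, got ", nrow(records),
         call. = FALSE)
  }
  if (any(records$patient_days <= 0)) {
    stop("patient_days must be strictly positive", call. = FALSE)
  }
  if (all(records$count == 0)) {
    stop("non-estimable: all annual counts are zero", call. = FALSE)
  }
  fit <- stats::glm(count ~ year + offset(log(patient_days)),
                    family = stats::poisson(), data = records)
  sm <- summary(fit)$coefficients
  gamma <- sm["year", "Estimate"]
  se <- sm["year", "Std. Error"]
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(irr = exp(gamma), ci_low = exp(gamma - z * se),
             ci_high = exp(gamma + z * se),
             p = sm["year", "Pr(>|z|)"], se_log = se,
             n_years = nrow(records))
}

#' Secular-trend report across organism categories
#'
#' Computes first/last-year incidence rates and the Poisson trend per
#' organism. CDI is excluded from formal trend testing by default (its
#' detection assay changed over typical surveillance periods, confounding
#' the trend); rates are still reported.
#'
#' @param hai data.frame (year, organism, count, patient_days).
#' @param exclude_from_test organism categories to exclude from trend
#'   testing (rates still reported).
#' @return data.frame (organism, n_years, rate_first, rate_last, irr,
#'   ci_low, ci_high, p, tested).
#' @export
hai_trend_report <- function(hai, exclude_from_test = "CDI") {
  orgs <- unique(hai$organism)
  rows <- lapply(orgs, function(o) {
    sub <- hai[hai$organism == o, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    base <- data.frame(
      organism = o, n_years = nrow(sub),
      rate_first = incidence_rate(sub$count[1], sub$patient_days[1]),
      rate_last = incidence_rate(sub$count[nrow(sub)],
                                 sub$patient_days[nrow(sub)]),
      stringsAsFactors = FALSE)
    if (o %in% exclude_from_test) {
      return(cbind(base, data.frame(irr = NA_real_, ci_low = NA_real_,
                                    ci_high = NA_real_, p = NA_real_,
                                    tested = FALSE)))
    }
    tr <- tryCatch(poisson_trend(sub), error = function(e) NULL)
    if (is.null(tr)) {
      return(cbind(base, data.frame(irr = NA_real_, ci_low = NA_real_,
                                    ci_high = NA_real_, p = NA_real_,
                                    tested = FALSE)))
    }
    cbind(base, data.frame(irr = tr$irr, ci_low = tr$ci_low,
                           ci_high = tr$ci_high, p = tr$p, tested = TRUE))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
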