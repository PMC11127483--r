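# Segmented interrupted-time-series regression. A single OLS model
#
#   y_t = b0 + b1 (t - t0) + b2 I[t >= t0] + b3 (t - t0) I[t >= t0] + e
#
# is fitted to a monthly series with change point t0 (the first
# post-intervention month, which carries the level change). Centring time at
# t0 makes b0 the predicted value at t0 without intervention, b2 the
# immediate (level) change, b1 the pre-intervention slope and b3 the slope
# change — the four quantities reported, each with a t-based 95% CI on
# n - 4 residual degrees of freedom.

#' Fit a segmented OLS regression to a monthly series
#'
#' @param y numeric metric values (one per month); NAs are dropped with a
#'   warning naming the months.
#' @param t integer month indices, strictly increasing, no duplicates.
#' @param t0 index of the first post-intervention month (on the scale of
#'   \code{t}).
#' @param level confidence level for the reported intervals.
#' @param newey_west if TRUE, use Newey-West heteroskedasticity- and
#'   autocorrelation-robust standard errors instead of plain OLS ones.
#' @return object of class \code{segmented_fit}: list with \code{coef}
#'   (baseline_value, baseline_slope, level_change, slope_change),
#'   \code{vcov}, \code{df}, \code{n}, \code{t0}, \code{level} and
#'   \code{table} (estimate, se, ci_low, ci_high, p per parameter).
#' @export
fit_segmented <- function(y, t, t0, level = 0.95, newey_west = FALSE) {
  if (length(y) != length(t)) {
    stop("y and t must have equal length", call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("month indices t must be strictly increasing with no duplicates",
         call. = FALSE)
  }
  keep <- !is.na(y)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " missing month(s): ",
            paste(t[!keep], collapse = ", "), call. = FALSE)
    y <- y[keep]; t <- t[keep]
  }
  n_pre <- sum(t < t0); n_post <- sum(t >= t0)
  if (n_pre < 3 || n_post < 3) {
    stop("insufficient data: need >= 3 observations on each side of t0 (",
         n_pre, " pre, ", n_post, " post)", call. = FALSE)
  }
  tc <- t - t0
  post <- as.numeric(t >= t0)
  X <- cbind(1, tc, post, tc * post)
  if (qr(X)$rank < 4) {
    stop("singular design: degenerate time axis", call. = FALSE)
  }
  dat <- data.frame(y = y, tc = tc, post = post)
  fit <- stats::lm(y ~ tc + post + tc:post, data = dat)
  beta <- stats::coef(fit)
  V <- if (newey_west) {
    sandwich::NeweyWest(fit, prewhite = FALSE)
  } else {
    stats::vcov(fit)
  }
  names(beta) <- c("baseline_value", "baseline_slope", "level_change",
                   "slope_change")
  dimnames(V) <- list(names(beta), names(beta))
  df <- fit$df.residual
  se <- sqrt(diag(V))
  crit <- stats::qt(1 - (1 - level) / 2, df)
  tstat <- beta / se
  tab <- data.frame(
    parameter = names(beta), estimate = unname(beta), se = unname(se),
    ci_low = unname(beta - crit * se), ci_high = unname(beta + crit * se),
    p = unname(2 * stats::pt(-abs(tstat), df)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coef = beta, vcov = V, df = df, n = length(y), t0 = t0,
                 level = level, table = tab, lm = fit),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Segmented OLS fit (n =", x$n, ", change point t0 =", x$t0, ")\n")
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Linear combination of segmented-fit parameters
#'
#' Estimates \code{w' beta} with standard error \code{sqrt(w' V w)}, t-based
#' confidence interval and two-sided p-value on the fit's residual degrees of
#' freedom. The reported "calculated change" quantities are such linear
#' combinations of the parameter estimates as predicted at the change point.
#'
#' @param fit a \code{\link{fit_segmented}} result.
#' @param w numeric weight vector of length 4 over (baseline_value,
#'   baseline_slope, level_change, slope_change); not all zero.
#' @param level confidence level (defaults to the fit's).
#' @return one-row data.frame (estimate, se, ci_low, ci_high, p, df).
#' @export
contrast <- function(fit, w, level = fit$level) {
  stopifnot(inherits(fit, "segmented_fit"))
  if (length(w) != 4) {
    stop("weight vector must have length 4", call. = FALSE)
  }
  if (all(w == 0)) {
    stop("weight vector must not be all zero", call. = FALSE)
  }
  est <- sum(w * fit$coef)
  se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
  crit <- stats::qt(1 - (1 - level) / 2, fit$df)
  data.frame(estimate = est, se = se,
             ci_low = est - crit * se, ci_high = est + crit * se,
             p = 2 * stats::pt(-abs(est / se), fit$df), df = fit$df)
}

#' Segmented-regression report over a monthly consumption table
#'
#' Fits the segmented model per drug for the requested metric and formats a
#' report row with the intercept block (predicted baseline value at the
#' change point, immediate change, CI, p) and the slope block (pre slope,
#' slope change, CI, p). Drugs with too few usable months are flagged rather
#' than fatal.
#'
#' @param consumption data.frame from \code{\link{monthly_consumption}}.
#' @param drug_groups named character vector mapping drug name to
#'   "targeted"/"nontargeted".
#' @param metric "mean_duration" or "dot_per_1000pd".
#' @param t0_month first post-intervention month ("YYYY-MM" or Date).
#' @param newey_west passed to \code{\link{fit_segmented}}.
#' @return data.frame, one row per drug: drug, group, metric, n_months,
#'   baseline_value, level_change, level_ci_low, level_ci_high, level_p,
#'   baseline_slope, slope_change, slope_ci_low, slope_ci_high, slope_p,
#'   note.
#' @export
batch_report <- function(consumption, drug_groups,
                         metric = c("mean_duration", "dot_per_1000pd"),
                         t0_month, newey_west = FALSE) {
  metric <- match.arg(metric)
  t0 <- month_number(parse_month(t0_month))
  drugs <- intersect(names(drug_groups), unique(consumption$drug))
  rows <- lapply(drugs, function(dr) {
    sub <- consumption[consumption$drug == dr, , drop = FALSE]
    sub <- sub[order(sub$month), , drop = FALSE]
    t <- month_number(parse_month(sub$month))
    base <- data.frame(drug = dr, group = unname(drug_groups[dr]),
                       metric = metric, stringsAsFactors = FALSE)
    fit <- tryCatch(
      suppressWarnings(fit_segmented(sub[[metric]], t, t0,
                                     newey_west = newey_west)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(cbind(base, data.frame(
        n_months = sum(!is.na(sub[[metric]])), baseline_value = NA_real_,
        level_change = NA_real_, level_ci_low = NA_real_,
        level_ci_high = NA_real_, level_p = NA_real_,
        baseline_slope = NA_real_, slope_change = NA_real_,
        slope_ci_low = NA_real_, slope_ci_high = NA_real_,
        slope_p = NA_real_, note = conditionMessage(fit),
        stringsAsFactors = FALSE)))
    }
    tb <- fit$table
    g <- function(par, col) tb[tb$parameter == par, col]
    cbind(base, data.frame(
      n_months = fit$n,
      baseline_value = g("baseline_value", "estimate"),
      level_change = g("level_change", "estimate"),
      level_ci_low = g("level_change", "ci_low"),
      level_ci_high = g("level_change", "ci_high"),
      level_p = g("level_change", "p"),
      baseline_slope = g("baseline_slope", "estimate"),
      slope_change = g("slope_change", "estimate"),
      slope_ci_low = g("slope_change", "ci_low"),
      slope_ci_high = g("slope_change", "ci_high"),
      slope_p = g("slope_change", "p"),
      note = "", stringsAsFactors = FALSE))
  })
  if (length(rows) == 0) {
    return(data.frame(drug = character(0), group = character(0),
                      metric = character(0), n_months = integer(0),
                      baseline_value = numeric(0), level_change = numeric(0),
                      level_ci_low = numeric(0), level_ci_high = numeric(0),
                      level_p = numeric(0), baseline_slope = numeric(0),
                      slope_change = numeric(0), slope_ci_low = numeric(0),
                      slope_ci_high = numeric(0), slope_p = numeric(0),
                      note = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$group, res$drug), , drop = FALSE]
  rownames(res) <- NULL
  res
}
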