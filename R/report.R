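#' Full performance report for a scored cohort
#'
#' Computes the discrimination block (Harrell's C, time-dependent C at the
#' horizon, Royston's D with its explained variation, and the distribution
#' of the linear predictor) and the calibration block (O/E ratio,
#' pseudo-value calibration intercept and slope, and the binned calibration
#' curve).
#'
#' @param lp linear predictors.
#' @param pred_risk predicted risks at the horizon.
#' @param time,event follow-up and 0/1 indicator.
#' @param horizon years.
#' @param n_groups calibration-curve groups.
#' @return An object of class `ppcvd_performance`.
#' @export
performance_report <- function(lp, pred_risk, time, event, horizon = 10,
                               n_groups = 10) {
  pv <- pseudo_values(time, event, horizon)
  cal <- calibration_intercept_slope(pv, pred_risk)
  structure(list(
    n = length(time), events = sum(event),
    discrimination = list(
      c = harrell_c(lp, time, event),
      c_td = time_dependent_c(lp, time, event, horizon),
      d = royston_d(lp, time, event),
      lp_mean = mean(lp), lp_sd = sd(lp)),
    calibration = list(
      oe = oe_ratio(pred_risk, time, event, horizon),
      intercept = cal$intercept, slope = cal$slope,
      curve = calibration_curve(pred_risk, pv, n_groups)),
    horizon = horizon
  ), class = "ppcvd_performance")
}

#' @export
print.ppcvd_performance <- function(x, ...) {
  d <- x$discrimination; cal <- x$calibration
  fmt <- function(v, ci) sprintf("%.3f (%.3f to %.3f)", v, ci[1], ci[2])
  cat(sprintf("Performance at %g years (n = %d, events = %d)\n",
              x$horizon, x$n, x$events))
  cat("  Harrell's C      ", fmt(d$c$c, d$c$ci), "\n")
  cat("  time-dependent C ", fmt(d$c_td$c, d$c_td$ci), "\n")
  cat("  Royston's D      ", fmt(d$d$d, d$d$ci),
      sprintf(" R2_D %.4f", d$d$r2), "\n")
  cat(sprintf("  LP mean (SD)      %.3f (%.3f)\n", d$lp_mean, d$lp_sd))
  cat("  O/E              ", fmt(cal$oe$oe, cal$oe$ci), "\n")
  cat("  intercept        ", fmt(cal$intercept$est, cal$intercept$ci), "\n")
  cat("  slope            ", fmt(cal$slope$est, cal$slope$ci), "\n")
  invisible(x)
}

#' Tabulate a performance report
#'
#' @param report a [performance_report()].
#' @return A one-row data.frame of the headline metrics.
#' @export
performance_table <- function(report) {
  d <- report$discrimination; cal <- report$calibration
  data.frame(n = report$n, events = report$events,
             harrell_c = d$c$c, c_lo = d$c$ci[1], c_hi = d$c$ci[2],
             c_td = d$c_td$c, royston_d = d$d$d, d_lo = d$d$ci[1],
             d_hi = d$d$ci[2], r2_d = d$d$r2,
             lp_mean = d$lp_mean, lp_sd = d$lp_sd,
             oe = cal$oe$oe, oe_lo = cal$oe$ci[1], oe_hi = cal$oe$ci[2],
             intercept = cal$intercept$est, slope = cal$slope$est)
}

#' Performance within subgroups
#'
#' Recomputes the whole performance report (including pseudo-values) inside
#' each level of a grouping column. Groups with fewer than 10 events are
#' flagged low-information; a group with no events reports undefined
#' metrics rather than erroring.
#'
#' @param cohort data.frame with `time`/`event`.
#' @param lp,pred_risk score vectors aligned with `cohort`.
#' @param grouping name of the grouping column.
#' @param horizon years.
#' @param min_events flag threshold.
#' @return Named list with one element per group, each holding `report`
#'   (a [performance_report()], or `NULL` when the group has no events),
#'   `events`, and a `low_information` flag.
#' @export
subgroup_performance <- function(cohort, lp, pred_risk, grouping,
                                 horizon = 10, min_events = 10) {
  if (!grouping %in% names(cohort))
    stop("no such grouping column: ", grouping, call. = FALSE)
  g <- as.character(cohort[[grouping]])
  out <- list()
  for (lev in sort(unique(g))) {
    i <- g == lev
    ev <- sum(cohort$event[i])
    rep_i <- if (ev == 0) NULL else
      performance_report(lp[i], pred_risk[i], cohort$time[i],
                         cohort$event[i], horizon)
    out[[lev]] <- list(report = rep_i, events = ev,
                       low_information = ev < min_events)
  }
  out
}
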