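#' Harrell's concordance for a risk score
#'
#' Proportion of comparable subject pairs (the shorter follow-up ends in an
#' event) whose predicted risk ordering matches their survival ordering;
#' ties in the score count one half. The confidence interval uses the
#' standard asymptotic (infinitesimal-jackknife) standard error.
#'
#' @param lp linear predictor or any risk-ordering score.
#' @param time,event follow-up and 0/1 indicator.
#' @param conf confidence level.
#' @return list with `c`, `se`, `ci`, and the comparable pair counts.
#' @export
harrell_c <- function(lp, time, event, conf = 0.95) {
  fit <- survival::concordance(survival::Surv(time, event) ~ lp,
                               reverse = TRUE)
  counts <- fit$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no comparable pairs", call. = FALSE)
  se <- sqrt(fit$var)
  z <- qnorm(1 - (1 - conf) / 2)
  list(c = unname(fit$concordance), se = se,
       ci = unname(fit$concordance) + c(-1, 1) * z * se,
       pairs = counts)
}

#' Time-dependent concordance at a horizon (Uno's IPCW estimator)
#'
#' Inverse-probability-of-censoring-weighted concordance truncated at the
#' horizon, with weights from the Kaplan-Meier estimate of the censoring
#' distribution.
#'
#' @inheritParams harrell_c
#' @param horizon truncation time in years.
#' @return list with `c`, `se`, `ci`.
#' @export
time_dependent_c <- function(lp, time, event, horizon, conf = 0.95) {
  if (sum(event[time <= horizon]) == 0)
    stop("no events observed by the horizon", call. = FALSE)
  fit <- survival::concordance(survival::Surv(time, event) ~ lp,
                               reverse = TRUE, timewt = "n/G2",
                               ymax = horizon)
  se <- sqrt(fit$var)
  z <- qnorm(1 - (1 - conf) / 2)
  list(c = unname(fit$concordance), se = se,
       ci = unname(fit$concordance) + c(-1, 1) * z * se)
}

#' Explained variation from Royston's D
#'
#' The closed-form identity `R2_D = (D^2/k^2) / (pi^2/6 + D^2/k^2)` with
#' `k^2 = 8/pi`.
#'
#' @param d Royston's D statistic.
#' @return R-squared(D).
#' @export
r2_d <- function(d) {
  k2 <- 8 / pi
  (d^2 / k2) / (pi^2 / 6 + d^2 / k2)
}

#' Royston's D statistic
#'
#' Ranks the linear predictor, maps ranks to expected standard-normal order
#' statistics (Blom scores), divides by kappa = sqrt(8/pi), and fits a Cox
#' model on that single regressor. The coefficient is D, the log-hazard
#' separation between prognostic halves; `r2_d(D)` gives the explained
#' variation on the log-relative-hazard scale.
#'
#' @inheritParams harrell_c
#' @return list with `d`, `se`, `ci`, `r2`.
#' @export
royston_d <- function(lp, time, event, conf = 0.95) {
  n <- length(lp)
  if (length(unique(lp)) < 2L) {
    warning("constant linear predictor; D = 0")
    return(list(d = 0, se = NA_real_, ci = c(NA_real_, NA_real_), r2 = 0))
  }
  r <- rank(lp, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (n + 1 / 4)) / sqrt(8 / pi)
  fit <- survival::coxph(survival::Surv(time, event) ~ z, ties = "efron")
  d <- unname(coef(fit))
  se <- sqrt(unname(vcov(fit)[1, 1]))
  zq <- qnorm(1 - (1 - conf) / 2)
  list(d = d, se = se, ci = d + c(-1, 1) * zq * se, r2 = r2_d(d))
}

#' Observed/expected ratio at a horizon
#'
#' Mean calibration: the Kaplan-Meier cumulative incidence at the horizon
#' divided by the mean predicted risk. The confidence interval is computed
#' on the log scale by the delta method using the Greenwood standard error
#' of the observed risk.
#'
#' @param pred_risk predicted risks at the horizon.
#' @param time,event follow-up and indicator.
#' @param horizon years.
#' @param conf confidence level.
#' @return list with `oe`, `observed`, `expected`, `ci`.
#' @export
oe_ratio <- function(pred_risk, time, event, horizon, conf = 0.95) {
  e <- mean(pred_risk)
  if (e <= 0) stop("mean predicted risk must be > 0", call. = FALSE)
  km <- km_risk(time, event, horizon)
  o <- km$risk
  z <- qnorm(1 - (1 - conf) / 2)
  log_se <- if (o > 0) km$se / o else NA_real_
  list(oe = o / e, observed = o, expected = e,
       ci = exp(log(o / e) + c(-1, 1) * z * log_se))
}
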