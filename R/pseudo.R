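#' Jackknife pseudo-values of the Kaplan-Meier cumulative incidence
#'
#' For each subject, `PV_i = n * F(t) - (n - 1) * F_{-i}(t)` where `F` is
#' one minus the Kaplan-Meier survival at the horizon and `F_{-i}` the same
#' estimate with subject i removed. Pseudo-values give every subject an
#' individual "observed" 10-year risk usable as a regression outcome under
#' censoring; without censoring they collapse to the event indicator.
#'
#' The leave-one-out estimates are computed exactly in O(n log n) by noting
#' that removing subject i changes each KM factor at event times up to the
#' subject's own time from `(1 - d_j/n_j)` to `(1 - d_j/(n_j - 1))` (and
#' also decrements `d_j` at the subject's own event time), so all n
#' leave-one-out curves share two cumulative sums of log-factors.
#'
#' @param time follow-up times (> 0).
#' @param event 0/1 event indicators.
#' @param horizon time at which the cumulative incidence is evaluated.
#' @return Numeric vector of per-subject pseudo-values.
#' @export
pseudo_values <- function(time, event, horizon) {
  n <- length(time)
  stopifnot(n >= 2L, length(event) == n, all(time > 0),
            all(event %in% c(0, 1)))
  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]
  first <- !duplicated(tt)
  dt <- tt[first]                                   # distinct times
  d <- as.numeric(rowsum(ev, tt)[, 1])              # events per distinct time
  atrisk <- n - c(0, cumsum(as.numeric(rowsum(rep(1, n), tt)[, 1])))
  nj <- atrisk[seq_along(dt)]                       # risk set at each time
  keep <- d > 0
  et <- dt[keep]; dj <- d[keep]; nje <- nj[keep]    # event times only

  logf <- function(num, den) {
    # log(1 - num/den), with an empty risk set contributing nothing
    out <- rep(0, length(num))
    pos <- den > 0
    out[pos] <- log1p(-num[pos] / den[pos])
    out
  }
  B <- cumsum(logf(dj, nje))                        # full-sample log S at et
  A <- cumsum(logf(dj, nje - 1))                    # all-at-risk leave-one-out

  m <- findInterval(horizon, et)                    # event times <= horizon
  F_full <- if (m == 0) 0 else 1 - exp(B[m])
  if (m == 0) return(rep(0, n))                     # horizon before all events

  at <- function(v, k)   # cumulative value at index k, 0 before the start
    ifelse(k >= 1, v[pmax(pmin(k, length(v)), 1)], 0)
  k_i <- findInterval(time, et)                     # event times <= T_i
  k_i_cap <- pmin(k_i, m)

  # at the subject's own event time t_j (delta_i = 1) the loo factor is
  # (1 - (d_j - 1)/(n_j - 1)); handled directly to avoid -Inf + Inf when
  # the loo risk set empties
  in_followup <- time <= horizon
  logS_loo <- at(A, k_i_cap) + (at(B, m) - at(B, k_i_cap))
  logS_loo[!in_followup] <- at(A, m)
  is_ev <- event == 1
  j_own <- match(time, et)                          # NA when not an event time
  has <- which(is_ev & !is.na(j_own) & j_own <= m)
  if (length(has)) {
    j <- j_own[has]
    logS_loo[has] <- at(A, j - 1) + logf(dj[j] - 1, nje[j] - 1) +
      (at(B, m) - at(B, j))
  }
  F_loo <- 1 - exp(logS_loo)
  n * F_full - (n - 1) * F_loo
}

#' Kaplan-Meier cumulative incidence at a horizon
#'
#' @param time follow-up times.
#' @param event 0/1 indicators.
#' @param horizon evaluation time.
#' @return list with `risk` (1 - KM survival at the horizon) and its
#'   Greenwood standard error.
#' @export
km_risk <- function(time, event, horizon) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, times = horizon, extend = TRUE)
  list(risk = 1 - s$surv, se = s$std.err)
}
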