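#' Decision-curve net benefit for a time-to-event risk model
#'
#' At each threshold p_t, subjects with predicted risk at or above p_t are
#' classified positive. The event probability among positives at the
#' horizon is taken from the Kaplan-Meier estimate within that group (the
#' survival-data decision-curve construction), so that
#' `NB = TP - FP * p_t / (1 - p_t)` with
#' `TP = P(positive) * risk_KM(positives)` and
#' `FP = P(positive) * (1 - risk_KM(positives))`. The treat-all strategy
#' classifies everyone positive; treat-none has net benefit zero by
#' definition.
#'
#' @param pred_risk predicted risks at the horizon.
#' @param time,event follow-up and 0/1 indicator.
#' @param horizon years.
#' @param thresholds strictly increasing grid inside (0, 1); the default
#'   steps by 0.01.
#' @return data.frame of class `ppcvd_dcurve` with columns `threshold`,
#'   `nb_model`, `nb_all`, `nb_none`.
#' @export
net_benefit <- function(pred_risk, time, event, horizon,
                        thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  n <- length(pred_risk)
  odds <- thresholds / (1 - thresholds)
  risk_all <- km_risk(time, event, horizon)$risk
  nb_all <- risk_all - (1 - risk_all) * odds

  nb_model <- vapply(seq_along(thresholds), function(k) {
    pos <- pred_risk >= thresholds[k]
    if (!any(pos)) return(0)
    p_pos <- mean(pos)
    r <- km_risk(time[pos], event[pos], horizon)$risk
    p_pos * r - p_pos * (1 - r) * odds[k]
  }, 0)

  structure(data.frame(threshold = thresholds, nb_model = nb_model,
                       nb_all = nb_all, nb_none = 0),
            class = c("ppcvd_dcurve", "data.frame"))
}
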