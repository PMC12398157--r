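sandwich_vcov <- function(fit) {
  X <- stats::model.matrix(fit)
  mu <- fit$fitted.values
  eta <- fit$linear.predictors
  me <- fit$family$mu.eta(eta)
  r <- fit$y - mu
  U <- X * (r * me)                 # estimating-function contributions
  A <- crossprod(X * me)            # bread (constant working variance)
  Ai <- solve(A)
  Ai %*% crossprod(U) %*% Ai
}

pv_glm <- function(pv, cl, free_slope) {
  fam <- quasi(link = "cloglog", variance = "constant")
  ctrl <- stats::glm.control(maxit = 200)
  if (free_slope) {
    glm(pv ~ cl, family = fam, etastart = cl, control = ctrl)
  } else {
    glm(pv ~ 1 + offset(cl), family = fam, etastart = cl, control = ctrl)
  }
}

#' Pseudo-value calibration intercept and slope
#'
#' Regresses jackknife pseudo-values of the 10-year cumulative incidence on
#' the complementary-log-log of the predicted risks, with a cloglog link.
#' The intercept model keeps the transformed predictions as an offset with a
#' free intercept; a negative intercept means the predicted risks are too
#' high, positive too low. The slope model frees the coefficient of the
#' transformed predictions (1 is ideal; below 1 signals overfitting).
#' Pseudo-values are not independent Bernoulli outcomes, so both models use
#' quasi-likelihood estimating equations with robust (sandwich) standard
#' errors.
#'
#' @param pv pseudo-values from [pseudo_values()].
#' @param pred_risk predicted risks, clamped to `[1e-10, 1 - 1e-10]` before
#'   the cloglog transform.
#' @param conf confidence level.
#' @return list with components `intercept` and `slope`, each holding
#'   `est`, `se`, `ci`.
#' @export
calibration_intercept_slope <- function(pv, pred_risk, conf = 0.95) {
  stopifnot(length(pv) == length(pred_risk))
  p <- pmin(pmax(pred_risk, 1e-10), 1 - 1e-10)
  if (any(p <= 0 | p >= 1))
    stop("predicted risks must lie strictly inside (0, 1)", call. = FALSE)
  cl <- cloglog(p)
  z <- qnorm(1 - (1 - conf) / 2)

  m_int <- pv_glm(pv, cl, free_slope = FALSE)
  a <- unname(coef(m_int)[1])
  se_a <- sqrt(sandwich_vcov(m_int)[1, 1])

  m_slope <- pv_glm(pv, cl, free_slope = TRUE)
  b <- unname(coef(m_slope)["cl"])
  se_b <- sqrt(sandwich_vcov(m_slope)[2, 2])

  list(intercept = list(est = a, se = se_a, ci = a + c(-1, 1) * z * se_a),
       slope = list(est = b, se = se_b, ci = b + c(-1, 1) * z * se_b))
}

#' Binned calibration curve
#'
#' Groups subjects into equal-sized risk groups by percentile of predicted
#' risk (group sizes differ by at most one) and contrasts the mean predicted
#' risk with the mean pseudo-value per group, with a normal-approximation
#' confidence interval on the latter.
#'
#' @param pred_risk predicted risks.
#' @param pv pseudo-values at the same horizon.
#' @param n_groups number of risk groups (default 10).
#' @param conf confidence level.
#' @return data.frame with one row per group: `group`, `n`, `mean_pred`,
#'   `observed`, `lower`, `upper`.
#' @export
calibration_curve <- function(pred_risk, pv, n_groups = 10, conf = 0.95) {
  n <- length(pred_risk)
  stopifnot(n_groups >= 1, n_groups <= n, length(pv) == n)
  ord_rank <- rank(pred_risk, ties.method = "first")
  grp <- ceiling(ord_rank * n_groups / n)
  z <- qnorm(1 - (1 - conf) / 2)
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    i <- grp == g
    m <- sum(i)
    se <- sd(pv[i]) / sqrt(m)
    data.frame(group = g, n = m, mean_pred = mean(pred_risk[i]),
               observed = mean(pv[i]),
               lower = mean(pv[i]) - z * se,
               upper = mean(pv[i]) + z * se)
  }))
  rownames(out) <- NULL
  out
}
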