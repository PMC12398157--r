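#' Expand cohort columns into model terms
#'
#' Numeric columns become linear terms; factor/character columns expand into
#' dummy contrasts against their first (reference) level.
#'
#' @param cohort data.frame.
#' @param vars column names.
#' @return A list of term objects (betas unset).
#' @export
cohort_terms <- function(cohort, vars) {
  out <- list()
  for (v in vars) {
    col <- cohort[[v]]
    if (is.null(col)) stop("no such column: ", v, call. = FALSE)
    if (is.factor(col) || is.character(col)) {
      lev <- if (is.factor(col)) levels(col) else sort(unique(col))
      for (l in lev[-1]) out[[length(out) + 1L]] <- term_level(v, l, NA_real_)
    } else {
      out[[length(out) + 1L]] <- term_linear(v, NA_real_)
    }
  }
  out
}

design_matrix <- function(cohort, terms) {
  if (!length(terms)) return(matrix(0, nrow(cohort), 0))
  need <- setdiff(unique(vapply(terms, `[[`, "", "variable")), names(cohort))
  if (length(need))
    stop("model terms reference absent column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  X <- vapply(terms, term_column, numeric(nrow(cohort)), cohort = cohort)
  X <- matrix(X, nrow = nrow(cohort))
  colnames(X) <- vapply(terms, `[[`, "", "name")
  X
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the partial likelihood (Efron tie handling) over the given
#' terms, optionally with a per-subject offset; with an offset and no free
#' terms the null fit with the offset absorbed is returned. The linear
#' predictor is centered at its fit-time mean, which is stored with the
#' model so baseline survival and predicted risks are invariant to
#' location shifts of the covariates.
#'
#' @param cohort data.frame with `time` and `event` columns.
#' @param terms list of term objects or a character vector of column names
#'   (factors expand to dummy contrasts via [cohort_terms()]).
#' @param offset optional numeric vector of per-subject offsets.
#' @return An object of class `ppcvd_cox`: fitted terms with coefficients,
#'   `beta`, `se`, `vcov`, `loglik`, the centering constant, and the data
#'   needed for baseline estimation.
#' @export
fit_cox <- function(cohort, terms = list(), offset = NULL) {
  stopifnot(all(c("time", "event") %in% names(cohort)))
  if (any(cohort$time <= 0)) stop("times must be > 0", call. = FALSE)
  if (sum(cohort$event) == 0) stop("no events in cohort", call. = FALSE)
  if (is.character(terms)) terms <- cohort_terms(cohort, terms)
  if (!is.null(offset) && !all(is.finite(offset)))
    stop("offset must be finite", call. = FALSE)
  off <- offset %||% numeric(nrow(cohort))
  X <- design_matrix(cohort, terms)
  if (ncol(X) > 0) {
    constant <- apply(X, 2, function(v) max(v) == min(v))
    if (any(constant)) {
      warning("dropping constant model term(s): ",
              paste(colnames(X)[constant], collapse = ", "))
      terms <- terms[!constant]
      X <- X[, !constant, drop = FALSE]
    }
  }
  y <- survival::Surv(cohort$time, cohort$event)
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 100)

  if (ncol(X) > 0) {
    fit <- survival::coxph(y ~ X + offset(off), ties = "efron",
                           control = ctrl)
    beta <- unname(coef(fit))
    if (anyNA(beta))
      stop("Cox fit failed to estimate some coefficients (singular design)",
           call. = FALSE)
    V <- unname(vcov(fit))
    se <- sqrt(diag(V))
    eta <- drop(X %*% beta) + off
    ll <- fit$loglik[length(fit$loglik)]
    for (i in seq_along(terms)) terms[[i]]$beta <- beta[i]
  } else {
    fit <- survival::coxph(y ~ offset(off), ties = "efron", control = ctrl)
    beta <- numeric(0); se <- numeric(0)
    V <- matrix(0, 0, 0)
    eta <- off
    ll <- fit$loglik[length(fit$loglik)]
  }
  nm <- vapply(terms, `[[`, "", "name")
  names(beta) <- nm; names(se) <- nm
  if (length(beta)) dimnames(V) <- list(nm, nm)
  structure(list(terms = terms, beta = beta, se = se, vcov = V,
                 loglik = ll, centering = mean(eta), eta = eta,
                 time = cohort$time, event = cohort$event,
                 n = nrow(cohort), nevent = sum(cohort$event)),
            class = "ppcvd_cox")
}

#' @export
print.ppcvd_cox <- function(x, ...) {
  cat(sprintf("Cox model: %d terms, n = %d, events = %d, loglik = %.2f\n",
              length(x$beta), x$n, x$nevent, x$loglik))
  if (length(x$beta)) {
    tab <- data.frame(beta = x$beta, HR = exp(x$beta), se = x$se)
    print(round(tab, 4))
  }
  invisible(x)
}

#' Breslow baseline cumulative hazard and survival
#'
#' Non-parametric baseline: at each distinct event time t_j the cumulative
#' hazard increments by d_j / sum over the risk set of exp(eta_i - center).
#' The reported baseline survival S0(t) = exp(-H0(t)) refers to a subject
#' whose linear predictor equals the centering constant.
#'
#' @param model a fitted [fit_cox()] object.
#' @param horizon time at which S0 is reported.
#' @return list with `time` (distinct event times), `hazard` (H0 steps),
#'   `surv` (S0 steps) and `s0_horizon`. A horizon beyond the last observed
#'   time returns the last value with a warning.
#' @export
breslow_baseline <- function(model, horizon = 10) {
  stopifnot(inherits(model, "ppcvd_cox"))
  eta_c <- model$eta - model$centering
  ord <- order(model$time)
  tt <- model$time[ord]; ev <- model$event[ord]; w <- exp(eta_c[ord])
  # risk-set sums: cumulative from the largest time downwards
  rs <- rev(cumsum(rev(w)))
  first <- !duplicated(tt)            # index of first row at each distinct time
  dt <- tt[first]
  denom <- rs[first]                  # sum of w over {time >= dt}
  d <- as.numeric(rowsum(ev, tt)[, 1])
  keep <- d > 0
  dt <- dt[keep]; inc <- d[keep] / denom[keep]
  H <- cumsum(inc)
  # flat extrapolation past the last observed time is only worth flagging
  # when the gap is material (not a censoring draw at 9.99 vs horizon 10)
  if (horizon - max(model$time) > 0.05 * horizon)
    warning("horizon beyond last observed time; returning last baseline value")
  k <- findInterval(horizon, dt)   # number of event times <= horizon
  s0 <- if (k == 0) 1 else exp(-H[k])
  list(time = dt, hazard = H, surv = exp(-H), s0_horizon = s0)
}

#' Convert a fitted Cox model to a scoring coefficient set
#'
#' Packages the fitted terms, the fit-time centering constant and the
#' Breslow baseline survival at the horizon into a [coefficient_set()] that
#' round-trips through the risk-equation engine.
#'
#' @param model a [fit_cox()] object.
#' @param horizon risk horizon in years.
#' @param name model label.
#' @return A [coefficient_set()].
#' @export
as_coefficient_set <- function(model, horizon = 10, name = "model") {
  bl <- breslow_baseline(model, horizon = horizon)
  coefficient_set(name, model$terms, baseline_survival = bl$s0_horizon,
                  horizon = horizon, centering = model$centering)
}

#' Recalibrate the baseline survival of an existing risk equation
#'
#' Refits the baseline risk in a new cohort while forcing the predictor
#' effects to stay fixed: the equation's linear predictor enters a Cox model
#' as an offset with no free coefficients, and the Breslow baseline survival
#' at the horizon replaces the old one. Predictor coefficients and the
#' centering constant are untouched.
#'
#' @param coeffs the [coefficient_set()] to recalibrate.
#' @param cohort data.frame with predictors plus `time`/`event`.
#' @param horizon risk horizon (defaults to the equation's).
#' @return A new [coefficient_set()] with the recalibrated baseline.
#' @export
recalibrate_baseline <- function(coeffs, cohort, horizon = coeffs$horizon) {
  lp <- linear_predictor(cohort, coeffs)
  m <- fit_cox(cohort, terms = list(), offset = lp - coeffs$centering)
  # keep the original centering: absorb it into the offset, then report S0
  # for a subject at LP = centering
  m$centering <- 0
  bl <- breslow_baseline(m, horizon = horizon)
  coefficient_set(paste0(coeffs$name, "_recalibrated"), coeffs$terms,
                  baseline_survival = bl$s0_horizon, horizon = horizon,
                  centering = coeffs$centering)
}
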