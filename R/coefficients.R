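#' Risk-equation coefficient set
#'
#' Bundles everything needed to score a cohort with a QRISK-style equation:
#' an ordered list of model terms (raw, dummy-contrast or
#' fractional-polynomial columns with their log-hazard coefficients), a
#' centering constant subtracted from the linear predictor before
#' exponentiation, and the baseline survival at the risk horizon.
#'
#' @param name model label.
#' @param terms list of terms from [term_linear()], [term_level()],
#'   [term_fp()].
#' @param baseline_survival S0(t) at the horizon, in (0, 1].
#' @param horizon years.
#' @param centering constant subtracted from the linear predictor (typically
#'   the development-data mean LP).
#' @return An object of class `ppcvd_coefset`.
#' @export
coefficient_set <- function(name, terms, baseline_survival, horizon = 10,
                            centering = 0) {
  if (baseline_survival <= 0 || baseline_survival > 1)
    stop("'baseline_survival' must lie in (0, 1]", call. = FALSE)
  stopifnot(horizon > 0)
  if (!all(vapply(terms, inherits, TRUE, "ppcvd_term")))
    stop("'terms' must be a list of ppcvd_term objects", call. = FALSE)
  structure(list(name = name, terms = terms,
                 baseline_survival = baseline_survival,
                 horizon = horizon, centering = centering),
            class = "ppcvd_coefset")
}

#' @export
print.ppcvd_coefset <- function(x, ...) {
  cat(sprintf("Risk equation '%s': %d terms, S0(%g) = %.6f, centering = %.4f\n",
              x$name, length(x$terms), x$horizon, x$baseline_survival,
              x$centering))
  for (tm in x$terms)
    cat(sprintf("  %-28s beta = %+.5f (HR %.3f)\n",
                tm$name, tm$beta, exp(tm$beta)))
  invisible(x)
}

#' Evaluate a linear predictor
#'
#' Computes `eta_i = sum_k beta_k x_ik` over the terms of a coefficient set.
#' Reference categories contribute zero. Referenced columns must be present
#' and complete; imputation happens upstream.
#'
#' @param cohort data.frame of predictors.
#' @param coeffs a [coefficient_set()].
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(cohort, coeffs) {
  stopifnot(inherits(coeffs, "ppcvd_coefset"))
  missing_cols <- unique(vapply(coeffs$terms, `[[`, "", "variable"))
  missing_cols <- setdiff(missing_cols, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns referenced by the risk equation: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  eta <- numeric(nrow(cohort))
  for (tm in coeffs$terms) {
    x <- term_column(tm, cohort)
    if (anyNA(x))
      stop(sprintf("column '%s' has missing values; impute before scoring",
                   tm$variable), call. = FALSE)
    eta <- eta + tm$beta * x
  }
  eta
}

#' Predicted risk at the horizon
#'
#' `pi_i = 1 - S0(t) ^ exp(eta_i - centering)`, the standard survival-model
#' absolute-risk construction.
#'
#' @param eta linear predictor vector.
#' @param coeffs a [coefficient_set()].
#' @return Numeric vector of risks in `[0, 1]`.
#' @export
predicted_risk <- function(eta, coeffs) {
  stopifnot(inherits(coeffs, "ppcvd_coefset"))
  1 - coeffs$baseline_survival^exp(eta - coeffs$centering)
}

#' Score a cohort with a risk equation
#'
#' @param cohort data.frame of predictors.
#' @param coeffs a [coefficient_set()].
#' @return The cohort with `lp` and `risk` columns appended.
#' @export
score_cohort <- function(cohort, coeffs) {
  eta <- linear_predictor(cohort, coeffs)
  cohort$lp <- eta
  cohort$risk <- predicted_risk(eta, coeffs)
  cohort
}

# --- serialization ---------------------------------------------------------

term_to_list <- function(tm) {
  out <- list(variable = tm$variable, beta = tm$beta, name = tm$name)
  if (!is.null(tm$level)) out$level <- tm$level
  if (!is.null(tm$fp)) {
    out$fp <- list(powers = tm$fp$powers, divisor = tm$fp$divisor,
                   shift = tm$fp$shift)
    out$fp_col <- tm$fp_col
  }
  out
}

term_from_list <- function(x) {
  fp <- NULL
  if (!is.null(x$fp))
    fp <- fp_spec(x$variable, x$fp$powers, divisor = x$fp$divisor,
                  shift = x$fp$shift)
  new_term(x$variable, x$beta, fp = fp, fp_col = x$fp_col %||% 1L,
           level = x$level, name = x$name)
}

#' Read and write coefficient sets as structured text
#'
#' Coefficient sets round-trip through a plain JSON representation so that
#' fitted models can be archived, inspected and re-loaded for scoring.
#'
#' @param coeffs a [coefficient_set()].
#' @param path file path.
#' @return `read_coefficient_set()` returns a [coefficient_set()];
#'   `write_coefficient_set()` returns `path` invisibly.
#' @export
write_coefficient_set <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "ppcvd_coefset"))
  obj <- list(name = coeffs$name,
              horizon = coeffs$horizon,
              baseline_survival = coeffs$baseline_survival,
              centering = coeffs$centering,
              terms = lapply(coeffs$terms, term_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_coefficient_set
#' @export
read_coefficient_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  coefficient_set(
    name = obj$name,
    terms = lapply(obj$terms, term_from_list),
    baseline_survival = obj$baseline_survival,
    horizon = obj$horizon,
    centering = obj$centering
  )
}
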