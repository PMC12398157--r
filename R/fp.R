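#' Fractional-polynomial specification
#'
#' Describes how a continuous predictor enters a risk equation: the value is
#' shifted, divided by a pre-scaling divisor, and raised to one or two powers
#' from the usual FP grid. Power 0 denotes the natural logarithm; a repeated
#' power p yields the pair x^p and x^p * log(x) (log^2(x) when p = 0), the
#' standard Royston-Sauerbrei convention.
#'
#' @param variable column name the transform applies to.
#' @param powers numeric vector of one or two powers.
#' @param divisor pre-scaling divisor (> 0).
#' @param shift value added before scaling (e.g. +4 for a linear-predictor
#'   FP whose support extends below zero).
#' @return An object of class `ppcvd_fp`.
#' @export
fp_spec <- function(variable, powers, divisor = 1, shift = 0) {
  stopifnot(is.character(variable), length(variable) == 1L)
  if (!is.numeric(powers) || length(powers) < 1L || length(powers) > 2L)
    stop("'powers' must hold one or two powers", call. = FALSE)
  if (divisor <= 0) stop("'divisor' must be > 0", call. = FALSE)
  structure(list(variable = variable, powers = powers,
                 divisor = divisor, shift = shift),
            class = "ppcvd_fp")
}

fp_needs_positive <- function(fp) {
  any(fp$powers <= 0 | fp$powers != round(fp$powers)) ||
    anyDuplicated(fp$powers) > 0
}

#' Apply a fractional-polynomial transform
#'
#' @param values numeric vector.
#' @param fp an [fp_spec()].
#' @return A numeric matrix with one column per power; columns named
#'   `<variable>_1`, `<variable>_2`.
#' @export
fp_transform <- function(values, fp) {
  stopifnot(inherits(fp, "ppcvd_fp"))
  x <- (values + fp$shift) / fp$divisor
  if (fp_needs_positive(fp) && any(x <= 0, na.rm = TRUE)) {
    bad <- values[which(x <= 0)[1]]
    stop(sprintf(
      "fractional polynomial for '%s' requires positive values after shift/scale; got %g",
      fp$variable, bad), call. = FALSE)
  }
  one <- function(p) if (p == 0) log(x) else x^p
  cols <- matrix(NA_real_, nrow = length(x), ncol = length(fp$powers))
  cols[, 1] <- one(fp$powers[1])
  if (length(fp$powers) == 2L) {
    cols[, 2] <- if (fp$powers[2] == fp$powers[1])
      cols[, 1] * log(x) else one(fp$powers[2])
  }
  colnames(cols) <- paste0(fp$variable, "_", seq_along(fp$powers))
  cols
}

# --- model terms -----------------------------------------------------------

new_term <- function(variable, beta, fp = NULL, fp_col = 1L,
                     level = NULL, name = NULL) {
  lab <- name %||% if (!is.null(level)) {
    paste0(variable, ":", level)
  } else if (!is.null(fp)) {
    paste0(variable, "_", fp_col)
  } else variable
  structure(list(variable = variable, beta = beta, fp = fp,
                 fp_col = as.integer(fp_col), level = level, name = lab),
            class = "ppcvd_term")
}

#' Model term constructors
#'
#' A risk equation is an ordered list of terms, each contributing
#' `beta * x` to the linear predictor. `term_linear()` uses the raw column,
#' `term_level()` a dummy contrast against a reference level, and
#' `term_fp()` one column of a fractional-polynomial transform.
#'
#' @param variable predictor column name.
#' @param beta log-hazard coefficient.
#' @param level factor level contrasted against the reference.
#' @param divisor,shift,power,log_multiply FP transform parameters; with
#'   `log_multiply = TRUE` the term is `x^power * log(x)` on the
#'   shifted/scaled value.
#' @param name optional term label.
#' @return A term object usable in [coefficient_set()].
#' @export
term_linear <- function(variable, beta, name = NULL) {
  new_term(variable, beta, name = name)
}

#' @rdname term_linear
#' @export
term_level <- function(variable, level, beta, name = NULL) {
  new_term(variable, beta, level = level, name = name)
}

#' @rdname term_linear
#' @export
term_fp <- function(variable, beta, power, divisor = 1, shift = 0,
                    log_multiply = FALSE, name = NULL) {
  powers <- if (log_multiply) c(power, power) else power
  fp <- fp_spec(variable, powers, divisor = divisor, shift = shift)
  new_term(variable, beta, fp = fp, fp_col = if (log_multiply) 2L else 1L,
           name = name)
}

term_column <- function(term, cohort) {
  v <- term$variable
  if (!v %in% names(cohort)) return(NULL)
  col <- cohort[[v]]
  if (!is.null(term$level)) {
    as.numeric(as.character(col) == term$level)
  } else if (!is.null(term$fp)) {
    fp_transform(col, term$fp)[, term$fp_col]
  } else {
    as.numeric(col)
  }
}
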