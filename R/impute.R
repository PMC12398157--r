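#' Missing-data policy
#'
#' Mirrors the single-imputation approach used when a QRISK-style score is
#' applied in routine data: continuous measurements are filled with the mean
#' of observed values within the subject's age band; smoking defaults to
#' non-smoker and ethnicity to white; deprivation takes the cohort median;
#' absent condition flags mean absence (0).
#'
#' @param rules named character vector mapping predictor -> one of
#'   `"age_group_mean"`, `"overall_median"`, `"constant"`, `"zero"`.
#' @param constants named list of fill values for `"constant"` rules.
#' @param age_band_width width in years of the age bands used by
#'   `"age_group_mean"` (default 5).
#' @param drop_threshold proportion missing at or above which a candidate
#'   predictor is excluded from model development (default 0.40, applied
#'   with `>=` so that a rounded 40% is excluded).
#' @return An object of class `ppcvd_impute_policy`.
#' @export
imputation_policy <- function(rules = c(sbp = "age_group_mean",
                                        bmi = "age_group_mean",
                                        tchdl_ratio = "age_group_mean",
                                        sbp_sd = "age_group_mean",
                                        smoking = "constant",
                                        ethnicity = "constant",
                                        townsend = "overall_median"),
                              constants = list(smoking = "non",
                                               ethnicity = "white"),
                              age_band_width = 5,
                              drop_threshold = 0.40) {
  ok <- c("age_group_mean", "overall_median", "constant", "zero")
  if (!all(rules %in% ok))
    stop("unknown imputation rule(s): ",
         paste(setdiff(rules, ok), collapse = ", "), call. = FALSE)
  if (drop_threshold <= 0 || drop_threshold > 1)
    stop("'drop_threshold' must lie in (0, 1]", call. = FALSE)
  structure(list(rules = rules, constants = constants,
                 age_band_width = age_band_width,
                 drop_threshold = drop_threshold),
            class = "ppcvd_impute_policy")
}

#' Single imputation of missing predictor values
#'
#' Applies an [imputation_policy()] once; the operation is idempotent and
#' never alters observed values. Predictors with missing entries that are
#' not covered by any rule raise an error (condition flags should be coded
#' 0/1 upstream, with no record meaning absence).
#'
#' @param cohort data.frame (needs an `age` column if any rule is
#'   `"age_group_mean"`).
#' @param policy an [imputation_policy()].
#' @return The cohort with covered predictors completed; a per-predictor
#'   count of imputed values is attached as `attr(, "imputed")`.
#' @export
single_impute <- function(cohort, policy = imputation_policy()) {
  stopifnot(inherits(policy, "ppcvd_impute_policy"))
  rules <- policy$rules[names(policy$rules) %in% names(cohort)]
  uncovered <- setdiff(names(cohort)[vapply(cohort, anyNA, TRUE)],
                       names(rules))
  uncovered <- setdiff(uncovered, c("time", "event"))
  if (length(uncovered))
    stop("missing values with no imputation rule: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  counts <- integer(0)
  for (nm in names(rules)) {
    x <- cohort[[nm]]
    idx <- which(is.na(x))
    counts[nm] <- length(idx)
    if (!length(idx)) next
    cohort[[nm]] <- switch(
      rules[[nm]],
      age_group_mean = {
        band <- floor(cohort$age / policy$age_band_width)
        fill <- ave(as.numeric(x), band,
                    FUN = function(v) mean(v, na.rm = TRUE))
        # empty bands fall back to the overall mean
        fill[is.nan(fill)] <- mean(as.numeric(x), na.rm = TRUE)
        x[idx] <- fill[idx]
        x
      },
      overall_median = {
        x[idx] <- median(as.numeric(x), na.rm = TRUE)
        x
      },
      constant = {
        x[idx] <- policy$constants[[nm]]
        x
      },
      zero = {
        x[idx] <- 0
        x
      })
  }
  attr(cohort, "imputed") <- counts
  cohort
}

#' Exclude candidate predictors with high missingness
#'
#' @param cohort data.frame.
#' @param candidates predictor columns to screen (defaults to all columns
#'   except `subject_id`, `time`, `event`).
#' @param threshold proportion missing at or above which a predictor is
#'   dropped.
#' @return list with `cohort` (screened columns removed) and `dropped`
#'   (character vector of excluded predictors).
#' @export
drop_high_missingness <- function(cohort, candidates = NULL,
                                  threshold = 0.40) {
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  candidates <- candidates %||%
    setdiff(names(cohort), c("subject_id", "time", "event"))
  prop <- vapply(cohort[candidates], function(x) mean(is.na(x)), 0)
  dropped <- names(prop)[prop >= threshold]
  list(cohort = cohort[setdiff(names(cohort), dropped)], dropped = dropped)
}

#' Restrict to complete cases on the modelled predictors
#'
#' The complete-case sensitivity analysis: rows with any missing value in
#' the given predictor columns are removed.
#'
#' @param cohort data.frame.
#' @param predictors columns that must be observed.
#' @return The filtered cohort.
#' @export
complete_case <- function(cohort, predictors) {
  cohort[complete.cases(cohort[predictors]), , drop = FALSE]
}
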