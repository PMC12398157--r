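#' Construct a cohort simulation specification
#'
#' A `ppcvd_simspec` captures the data-generating truth for a synthetic
#' postpartum cohort: marginal distributions of the predictors, the true
#' log-hazard for each model term, the exponential baseline hazard (or a
#' target 10-year cumulative incidence from which it is calibrated), the
#' censoring mechanism, and per-predictor missingness rates.
#'
#' @param n default number of subjects.
#' @param binary_predictors data.frame with columns `name`, `prevalence`.
#' @param continuous_predictors data.frame with columns `name`, `mean`, `sd`,
#'   `lower`, `upper`, `dist` (`"normal"` with truncation, or `"lognormal"`
#'   where `mean`/`sd` are on the log scale).
#' @param categorical_predictors named list; each element a named probability
#'   vector over levels (first level is the reference).
#' @param ordinal_predictors named list; each element a probability vector
#'   with integer values in `attr(, "values")` (e.g. gravidity counts,
#'   Townsend quintiles).
#' @param true_terms list of model terms (see [coefficient_set()]) defining
#'   the data-generating linear predictor.
#' @param baseline_rate events per person-year of the exponential baseline
#'   hazard, or `NULL` to calibrate it to `target_incidence` at generation
#'   time.
#' @param target_incidence marginal cumulative incidence at `horizon` used to
#'   calibrate `baseline_rate` when the latter is `NULL`.
#' @param horizon risk horizon in years.
#' @param admin_window length-2 numeric; administrative censoring times are
#'   drawn uniformly on this window (years).
#' @param dropout_rate exponential dropout rate per year (0 disables).
#' @param missingness_rates named numeric vector of per-predictor
#'   missing-completely-at-random rates.
#' @param seed default root seed.
#' @return An object of class `ppcvd_simspec`.
#' @export
simulation_spec <- function(n,
                            binary_predictors,
                            continuous_predictors,
                            categorical_predictors = list(),
                            ordinal_predictors = list(),
                            true_terms = list(),
                            baseline_rate = NULL,
                            target_incidence = 0.01,
                            horizon = 10,
                            admin_window = c(1, 10),
                            dropout_rate = 0.094,
                            missingness_rates = numeric(),
                            seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_config("n", "must be a single count >= 1")
  check_prob(binary_predictors$prevalence, "binary_predictors$prevalence")
  for (nm in names(categorical_predictors)) {
    p <- categorical_predictors[[nm]]
    check_prob(p, paste0("categorical_predictors$", nm))
    if (abs(sum(p) - 1) > 1e-9)
      stop_config(paste0("categorical_predictors$", nm),
                  "probabilities must sum to 1")
  }
  for (nm in names(ordinal_predictors)) {
    p <- ordinal_predictors[[nm]]
    check_prob(as.numeric(p), paste0("ordinal_predictors$", nm))
    if (abs(sum(p) - 1) > 1e-9)
      stop_config(paste0("ordinal_predictors$", nm),
                  "probabilities must sum to 1")
    if (is.null(attr(p, "values")))
      stop_config(paste0("ordinal_predictors$", nm),
                  "needs an integer 'values' attribute")
  }
  if (!is.null(baseline_rate) && baseline_rate <= 0)
    stop_config("baseline_rate", "must be > 0")
  if (horizon <= 0) stop_config("horizon", "must be > 0")
  check_prob(target_incidence, "target_incidence")
  if (length(admin_window) != 2L || any(admin_window <= 0) ||
      admin_window[1] > admin_window[2])
    stop_config("admin_window", "must be 0 < lo <= hi")
  if (dropout_rate < 0) stop_config("dropout_rate", "must be >= 0")
  check_prob(unname(missingness_rates), "missingness_rates")

  structure(list(
    n = as.integer(n),
    binary_predictors = binary_predictors,
    continuous_predictors = continuous_predictors,
    categorical_predictors = categorical_predictors,
    ordinal_predictors = ordinal_predictors,
    true_terms = true_terms,
    baseline_rate = baseline_rate,
    target_incidence = target_incidence,
    horizon = horizon,
    admin_window = admin_window,
    dropout_rate = dropout_rate,
    missingness_rates = missingness_rates,
    seed = as.integer(seed)
  ), class = "ppcvd_simspec")
}

#' Default synthetic postpartum cohort world
#'
#' Encodes the published baseline characteristics of a UK primary-care cohort
#' of previously pregnant women aged 15-49 (predictor prevalences,
#' means/SDs, gravidity distribution, missingness proportions) together with
#' the adjusted hazard ratios of the full developed model (established QRISK
#' style predictors plus pregnancy and reproductive factors) as the
#' data-generating truth. Smoking is simulated as non/ex/current; gravidity
#' enters the linear predictor as a continuous count; deprivation as
#' Townsend quintiles 1-5 with median 3.
#'
#' Predictors reported but dropped during the published variable selection
#' (preterm birth, small-for-gestational-age, irregular menses, placental
#' abruption) are simulated with their prevalences but carry a true
#' log-hazard of zero, as do the two high-missingness lipid/BP-variability
#' measurements.
#'
#' @param n subjects to generate by default.
#' @param seed root seed.
#' @param missingness logical; include the published missingness rates
#'   (`FALSE` gives complete data).
#' @return A [simulation_spec()].
#' @export
default_simulation_spec <- function(n = 10000, seed = 1L, missingness = TRUE) {
  bin <- data.frame(
    name = c("fam_cvd", "atrial_fibrillation", "migraine",
             "rheumatoid_arthritis", "ckd", "severe_mental_illness", "sle",
             "diabetes_type1", "diabetes_type2", "atypical_antipsychotics",
             "corticosteroids", "antihypertensives",
             "pre_eclampsia", "gestational_hypertension", "sga",
             "postnatal_depression", "gdm", "stillbirth", "miscarriage",
             "preterm_birth", "placental_abruption",
             "endometriosis", "irregular_menses", "pcos"),
    prevalence = c(0.032, 0.001, 0.090,
                   0.002, 0.001, 0.009, 0.001,
                   0.003, 0.004, 0.003,
                   0.003, 0.003,
                   0.033, 0.030, 0.062,
                   0.054, 0.029, 0.009, 0.224,
                   0.041, 0.005,
                   0.022, 0.119, 0.038),
    stringsAsFactors = FALSE
  )
  cont <- data.frame(
    name  = c("age", "sbp", "bmi", "tchdl_ratio", "sbp_sd"),
    mean  = c(32.01, 115.16, 25.68, log(3.23), log(8.37)),
    sd    = c(6.63, 12.72, 5.71, 0.2922, 0.5109),
    lower = c(15, 70, 13, NA, NA),
    upper = c(49, 200, 60, NA, NA),
    dist  = c("normal", "normal", "normal", "lognormal", "lognormal"),
    stringsAsFactors = FALSE
  )
  cat_p <- list(
    ethnicity = c(white = 0.798, black = 0.075, asian = 0.062,
                  mixed = 0.014, other = 0.051),
    smoking = c(non = 0.660, ex = 0.151, current = 0.189)
  )
  grav <- c(0.452, 0.272, 0.143, 0.072,
            0.061 * c(0.5, 0.25, 0.125, 0.0625, 0.03125, 0.03125))
  attr(grav, "values") <- 1:10
  town <- rep(0.2, 5)
  attr(town, "values") <- 1:5
  ord <- list(gravidity = grav, townsend = town)

  hr <- function(x) log(x)
  terms <- c(
    list(
      term_fp("age", beta = hr(2.04), divisor = 10, power = 1),
      term_fp("bmi", beta = hr(1.29), divisor = 10, power = 1),
      term_fp("sbp", beta = hr(1.83), divisor = 100, power = 2),
      term_linear("townsend", beta = hr(1.18)),
      term_linear("gravidity", beta = hr(1.07)),
      term_level("ethnicity", "black", beta = hr(1.54)),
      term_level("ethnicity", "mixed", beta = hr(1.24)),
      term_level("ethnicity", "asian", beta = hr(1.19)),
      term_level("ethnicity", "other", beta = hr(0.90)),
      term_level("smoking", "ex", beta = hr(0.89)),
      term_level("smoking", "current", beta = hr(1.73))
    ),
    mapply(term_linear,
           c("fam_cvd", "atrial_fibrillation", "migraine",
             "rheumatoid_arthritis", "ckd", "severe_mental_illness", "sle",
             "diabetes_type1", "diabetes_type2", "atypical_antipsychotics",
             "corticosteroids", "antihypertensives", "pre_eclampsia",
             "postnatal_depression", "gdm", "gestational_hypertension",
             "miscarriage", "stillbirth", "endometriosis", "pcos"),
           hr(c(1.48, 2.79, 1.58,
                1.02, 3.82, 1.89, 3.50,
                5.30, 3.94, 0.98,
                1.67, 1.32, 1.52,
                1.33, 1.18, 1.34,
                1.16, 1.37, 1.56, 1.41)),
           SIMPLIFY = FALSE)
  )

  miss <- if (missingness) {
    c(sbp = 0.16, sbp_sd = 0.40, bmi = 0.24, tchdl_ratio = 0.91,
      smoking = 0.18, townsend = 0.0011)
  } else numeric()

  simulation_spec(
    n = n,
    binary_predictors = bin,
    continuous_predictors = cont,
    categorical_predictors = cat_p,
    ordinal_predictors = ord,
    true_terms = terms,
    baseline_rate = NULL,
    target_incidence = 0.01,
    horizon = 10,
    admin_window = c(1, 10),
    dropout_rate = 0.094,
    missingness_rates = miss,
    seed = seed
  )
}

#' @export
print.ppcvd_simspec <- function(x, ...) {
  cat("Synthetic cohort simulation spec\n")
  cat(sprintf("  n = %d, horizon = %g y, target incidence = %g\n",
              x$n, x$horizon, x$target_incidence))
  cat(sprintf("  predictors: %d binary, %d continuous, %d categorical, %d ordinal\n",
              nrow(x$binary_predictors), nrow(x$continuous_predictors),
              length(x$categorical_predictors), length(x$ordinal_predictors)))
  cat(sprintf("  true model terms: %d; missingness on %d predictors\n",
              length(x$true_terms), length(x$missingness_rates)))
  invisible(x)
}
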