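#' Model-term templates for the study models
#'
#' `established_terms()` returns the QRISK-style predictor template
#' (fractional-polynomial age, BMI and SBP; Townsend; ethnicity and smoking
#' contrasts; conditions and medications) used by Models 2a/2b;
#' `pregnancy_candidates()` the pregnancy and reproductive candidate
#' predictors added in Models 1/2b. Coefficients are unset until fitting.
#'
#' @param exclude predictor names to leave out (e.g. dropped for
#'   missingness).
#' @return A list of term objects / character vector of column names.
#' @export
established_terms <- function(exclude = character()) {
  tms <- c(
    list(term_fp("age", NA_real_, power = 1, divisor = 10),
         term_fp("bmi", NA_real_, power = 1, divisor = 10),
         term_fp("sbp", NA_real_, power = 2, divisor = 100),
         term_linear("townsend", NA_real_),
         term_level("ethnicity", "black", NA_real_),
         term_level("ethnicity", "mixed", NA_real_),
         term_level("ethnicity", "asian", NA_real_),
         term_level("ethnicity", "other", NA_real_),
         term_level("smoking", "ex", NA_real_),
         term_level("smoking", "current", NA_real_)),
    lapply(c("fam_cvd", "atrial_fibrillation", "migraine",
             "rheumatoid_arthritis", "ckd", "severe_mental_illness", "sle",
             "diabetes_type1", "diabetes_type2", "atypical_antipsychotics",
             "corticosteroids", "antihypertensives"),
           term_linear, beta = NA_real_)
  )
  keep <- !vapply(tms, function(t) t$variable %in% exclude, TRUE)
  tms[keep]
}

#' @rdname established_terms
#' @export
pregnancy_candidates <- function(exclude = character()) {
  setdiff(c("pre_eclampsia", "postnatal_depression", "gdm",
            "gestational_hypertension", "miscarriage", "preterm_birth",
            "stillbirth", "sga", "gravidity", "endometriosis",
            "irregular_menses", "pcos", "placental_abruption"),
          exclude)
}

#' Fit a synthetic benchmark risk equation
#'
#' Stands in for an externally developed risk score: the established
#' predictor model is fitted on an independently generated cohort (complete
#' data, separate seed substream) and packaged as a [coefficient_set()].
#' No published score coefficients are redistributed.
#'
#' @param spec a [simulation_spec()].
#' @param n development-cohort size.
#' @param seed root seed.
#' @return A [coefficient_set()] named `"benchmark"`.
#' @export
synthetic_benchmark <- function(spec, n = 50000, seed = 99L) {
  dev <- generate_cohort(spec, n = n, seed = substream_seed(seed, "benchmark"),
                         missingness = FALSE)
  m <- fit_cox(dev, established_terms())
  cs <- as_coefficient_set(m, horizon = spec$horizon, name = "benchmark")
  cs
}

#' Study configuration
#'
#' @param spec simulation spec for the synthetic cohort.
#' @param n cohort size.
#' @param seed root seed for the whole study.
#' @param benchmark a [coefficient_set()] standing in for the external risk
#'   equation; built synthetically when `NULL`.
#' @param B bootstrap replicates for internal validation.
#' @param horizon years.
#' @param thresholds decision-curve grid.
#' @param subgroups cohort columns for subgroup performance.
#' @param complete_case drop rows with missing modelled predictors instead
#'   of imputing (sensitivity analysis).
#' @param min_age restrict to subjects at or above this age (sensitivity
#'   analysis; `NULL` = no restriction).
#' @return A config list for [run_study()].
#' @export
study_config <- function(spec = default_simulation_spec(), n = 20000,
                         seed = 1L, benchmark = NULL, B = 500, horizon = 10,
                         thresholds = seq(0.01, 0.10, by = 0.01),
                         subgroups = character(), complete_case = FALSE,
                         min_age = NULL) {
  list(spec = spec, n = n, seed = seed, benchmark = benchmark, B = B,
       horizon = horizon, thresholds = thresholds, subgroups = subgroups,
       complete_case = complete_case, min_age = min_age)
}

#' Run the full model development and validation study
#'
#' Executes the study graph on a synthetic cohort: eligibility filtering,
#' the missing-data policy, external validation of the benchmark equation,
#' baseline recalibration of the benchmark, then three updated models —
#' Model 1 (benchmark linear predictor entered through its two
#' fractional-polynomial terms plus pregnancy candidates), Model 2a
#' (established predictors refit), Model 2b (established predictors plus
#' pregnancy candidates, LASSO-selected) — each validated with the full
#' performance report, decision curves, and bootstrap optimism for the
#' developed models.
#'
#' @param config a [study_config()].
#' @return An object of class `ppcvd_study` with per-model reports, a
#'   hazard-ratio table, comparison tables of discrimination and
#'   calibration, decision curves, the exclusion log and a seed manifest.
#' @export
run_study <- function(config) {
  seed <- config$seed
  horizon <- config$horizon
  spec <- config$spec

  cohort <- generate_cohort(spec, n = config$n, seed = seed,
                            eligibility_flags = TRUE)
  filt <- apply_eligibility_filters(cohort)
  cohort <- filt$cohort
  if (!is.null(config$min_age))
    cohort <- cohort[cohort$age >= config$min_age, , drop = FALSE]

  dropped <- drop_high_missingness(cohort)
  cohort_dev <- dropped$cohort
  if (config$complete_case) {
    model_cols <- intersect(names(cohort_dev),
                            c("age", "sbp", "bmi", "smoking", "townsend",
                              "ethnicity"))
    cohort_dev <- complete_case(cohort_dev, model_cols)
  } else {
    cohort_dev <- single_impute(cohort_dev)
  }

  benchmark <- config$benchmark %||% synthetic_benchmark(spec, seed = seed)

  validate_set <- function(cs, data) {
    lp <- linear_predictor(data, cs)
    risk <- predicted_risk(lp, cs)
    list(report = performance_report(lp, risk, data$time, data$event,
                                     horizon),
         dcurve = net_benefit(risk, data$time, data$event, horizon,
                              config$thresholds),
         subgroups = if (length(config$subgroups))
           lapply(setNames(config$subgroups, config$subgroups), function(g)
             subgroup_performance(data, lp, risk, g, horizon))
         else NULL,
         lp = lp, risk = risk)
  }

  out <- list(exclusion_log = filt$log, dropped_predictors = dropped$dropped,
              n = nrow(cohort_dev), seed = seed, models = list())

  # benchmark external validation + baseline recalibration
  out$models$benchmark <- validate_set(benchmark, cohort_dev)
  recal <- recalibrate_baseline(benchmark, cohort_dev, horizon)
  out$models$recalibrated <- validate_set(recal, cohort_dev)

  ex <- dropped$dropped
  est <- established_terms(exclude = ex)
  preg <- pregnancy_candidates(exclude = ex)

  # Model 1: benchmark LP through its FP pair + pregnancy candidates
  lp_b <- out$models$benchmark$lp - benchmark$centering
  cohort_dev$benchmark_lp <- lp_b
  if (any(lp_b <= -4))
    stop("benchmark linear predictor at or below -4; the (LP+4)^3 ",
         "fractional polynomial is undefined there", call. = FALSE)
  lp_terms <- list(
    term_fp("benchmark_lp", NA_real_, power = 3, shift = 4),
    term_fp("benchmark_lp", NA_real_, power = 3, shift = 4,
            log_multiply = TRUE))
  recipe1 <- function(data) {
    sel <- lasso_select(data, candidates = cohort_terms(data, preg),
                        forced = lp_terms, seed = seed)
    as_coefficient_set(sel$model, horizon, "model1")
  }
  # Model 2a: established predictors refit (no selection)
  recipe2a <- function(data)
    as_coefficient_set(fit_cox(data, est), horizon, "model2a")
  # Model 2b: established + pregnancy candidates via LASSO
  recipe2b <- function(data) {
    sel <- lasso_select(data, candidates = cohort_terms(data, preg),
                        forced = est, seed = seed)
    as_coefficient_set(sel$model, horizon, "model2b")
  }

  recipes <- list(model1 = recipe1, model2a = recipe2a, model2b = recipe2b)
  for (nm in names(recipes)) {
    cs <- recipes[[nm]](cohort_dev)
    out$models[[nm]] <- validate_set(cs, cohort_dev)
    out$models[[nm]]$coefficients <- cs
    out$models[[nm]]$optimism <- bootstrap_optimism(
      cohort_dev, recipes[[nm]], B = config$B,
      seed = substream_seed(seed, paste0("opt:", nm)), horizon = horizon)
  }

  hr_rows <- lapply(c("model1", "model2a", "model2b"), function(nm) {
    cs <- out$models[[nm]]$coefficients
    data.frame(model = nm,
               term = vapply(cs$terms, `[[`, "", "name"),
               hr = exp(vapply(cs$terms, `[[`, 0, "beta")))
  })
  out$hr_table <- do.call(rbind, hr_rows)
  out$comparison <- do.call(rbind, lapply(names(out$models), function(nm)
    cbind(model = nm, performance_table(out$models[[nm]]$report))))
  class(out) <- "ppcvd_study"
  out
}

#' @export
print.ppcvd_study <- function(x, ...) {
  cat(sprintf("Risk-model study: n = %d after exclusions; models: %s\n",
              x$n, paste(names(x$models), collapse = ", ")))
  print(x$comparison[, c("model", "harrell_c", "royston_d", "r2_d",
                         "oe", "intercept", "slope")], digits = 3)
  invisible(x)
}

#' Write study outputs as delimited text
#'
#' @param study a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE)
  w(study$exclusion_log, "exclusion_log.csv")
  w(study$comparison, "performance_comparison.csv")
  w(study$hr_table, "hazard_ratios.csv")
  for (nm in names(study$models)) {
    m <- study$models[[nm]]
    w(m$dcurve, paste0("decision_curve_", nm, ".csv"))
    w(m$report$calibration$curve, paste0("calibration_curve_", nm, ".csv"))
  }
  writeLines(c(sprintf("seed: %d", study$seed),
               sprintf("n: %d", study$n),
               sprintf("dropped: %s",
                       paste(study$dropped_predictors, collapse = ","))),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
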