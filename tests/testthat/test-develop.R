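test_that("Cox fit matches a brute-force partial-likelihood maximizer", {
  co <- fixture_cohort()
  fit <- fit_cox(co, "x")
  b_oracle <- oracle_cox_beta(co$time, co$event, co$x)
  expect_equal(unname(fit$beta), b_oracle, tolerance = 1e-4)
  # and on a 6-subject subset without ties
  co6 <- co[c(1, 2, 4, 6, 7, 8), ]
  fit6 <- fit_cox(co6, "x")
  expect_equal(unname(fit6$beta),
               oracle_cox_beta(co6$time, co6$event, co6$x),
               tolerance = 1e-4)
  expect_equal(fit$centering, mean(fit$eta))
})

test_that("Cox fit guards its preconditions", {
  co <- fixture_cohort()
  expect_error(fit_cox(transform(co, event = 0), "x"), "no events")
  expect_error(fit_cox(transform(co, time = time - 2), "x"), "> 0")
  expect_error(fit_cox(co, "x", offset = rep(Inf, 8)), "finite")
  # offset-only null fit absorbs the offset
  null <- fit_cox(co, list(), offset = co$x * 0.5)
  expect_length(null$beta, 0)
  expect_true(is.finite(null$loglik))
  expect_equal(null$eta, co$x * 0.5)
})

test_that("Breslow baseline matches hand computation and Nelson-Aalen", {
  co <- fixture_cohort()
  # null model: baseline hazard is Nelson-Aalen
  null <- fit_cox(co, list(), offset = rep(0, 8))
  bl <- breslow_baseline(null, horizon = 10)
  expect_equal(bl$hazard[length(bl$hazard)],
               oracle_breslow(co$time, co$event, rep(0, 8), 10),
               tolerance = 1e-12)
  na_fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = co,
                              stype = 2, ctype = 1)
  expect_equal(bl$hazard, na_fit$cumhaz[na_fit$n.event > 0],
               tolerance = 1e-12)
  # with covariates: matches the definition evaluated at the fitted eta
  fit <- fit_cox(co, "x")
  bl2 <- breslow_baseline(fit, horizon = 10)
  expect_equal(bl2$hazard[length(bl2$hazard)],
               oracle_breslow(co$time, co$event, fit$eta - fit$centering, 10),
               tolerance = 1e-12)
  expect_true(all(diff(bl2$hazard) >= 0))
  expect_true(all(bl2$surv <= 1))
  expect_warning(breslow_baseline(fit, horizon = 99), "beyond")
})

test_that("fitting the generating model recovers binary, continuous and ordinal effects", {
  bin <- data.frame(name = c("expo", "null_expo"),
                    prevalence = c(0.3, 0.2))
  cont <- data.frame(name = "z", mean = 0, sd = 1, lower = NA, upper = NA,
                     dist = "normal")
  grav <- c(0.5, 0.3, 0.2); attr(grav, "values") <- 1:3
  spec <- simulation_spec(
    n = 15000,
    binary_predictors = bin, continuous_predictors = cont,
    ordinal_predictors = list(g = grav),
    true_terms = list(term_linear("expo", log(1.8)),
                      term_linear("z", 0.4),
                      term_linear("g", log(1.3))),
    target_incidence = 0.10, admin_window = c(10, 10), dropout_rate = 0,
    seed = 21)
  co <- generate_cohort(spec)
  fit <- fit_cox(co, c("expo", "null_expo", "z", "g"))
  truth <- c(expo = log(1.8), null_expo = 0, z = 0.4, g = log(1.3))
  for (nm in names(truth))
    expect_lt(abs(fit$beta[[nm]] - truth[[nm]]), 2 * fit$se[[nm]])
})

test_that("in-sample mean predicted risk equals the KM risk (Breslow calibration)", {
  spec <- default_simulation_spec(n = 20000, seed = 22, missingness = FALSE)
  spec$admin_window <- c(10, 10); spec$dropout_rate <- 0
  co <- generate_cohort(spec)
  fit <- fit_cox(co, c("pre_eclampsia", "migraine", "age"))
  cs <- as_coefficient_set(fit, horizon = 10, name = "m")
  risk <- predicted_risk(linear_predictor(co, cs), cs)
  expect_equal(mean(risk), km_risk(co$time, co$event, 10)$risk,
               tolerance = 0.02)
})

test_that("offset recalibration restores mean calibration", {
  spec <- default_simulation_spec(n = 30000, seed = 23, missingness = FALSE)
  spec$admin_window <- c(10, 10); spec$dropout_rate <- 0
  co <- generate_cohort(spec)
  fit <- fit_cox(co, c("age", "migraine", "smoking"))
  cs <- as_coefficient_set(fit, horizon = 10, name = "m")
  # corrupt the equation: shift every LP by +log(2), halving implied S0 scale
  shifted <- cs
  shifted$terms <- c(cs$terms, list(term_linear("one", log(2))))
  co$one <- 1
  lp_s <- linear_predictor(co, shifted)
  oe_bad <- oe_ratio(predicted_risk(lp_s, shifted), co$time, co$event, 10)
  expect_lt(oe_bad$oe, 0.8)   # systematic over-prediction
  recal <- recalibrate_baseline(shifted, co)
  oe_ok <- oe_ratio(predicted_risk(lp_s, recal), co$time, co$event, 10)
  expect_lt(abs(oe_ok$oe - 1), 0.03)
  # self-recalibration is a no-op on the baseline
  recal0 <- recalibrate_baseline(cs, co)
  expect_equal(recal0$baseline_survival, cs$baseline_survival,
               tolerance = 1e-6)
})

test_that("FP selection distinguishes linear from log effects by closed test", {
  grid <- c(-1, 0, 0.5, 1, 2)
  cont <- data.frame(name = "x", mean = log(3), sd = 0.4, lower = NA,
                     upper = NA, dist = "lognormal")
  base <- list(n = 8000, binary_predictors = data.frame(name = character(),
                                                        prevalence = numeric()),
               continuous_predictors = cont,
               target_incidence = 0.15, admin_window = c(10, 10),
               dropout_rate = 0)
  # linear truth
  spec_lin <- do.call(simulation_spec,
                      c(base, list(true_terms = list(term_linear("x", 0.35)),
                                   seed = 31)))
  co_lin <- generate_cohort(spec_lin)
  sel_lin <- select_fp(co_lin, "x", powers = grid)
  expect_equal(attr(sel_lin, "form"), "linear")
  expect_equal(sel_lin$powers, 1)
  # log truth
  spec_log <- do.call(simulation_spec,
                      c(base, list(true_terms = list(term_fp("x", 1.4,
                                                             power = 0)),
                                   seed = 32)))
  co_log <- generate_cohort(spec_log)
  sel_log <- select_fp(co_log, "x", powers = grid)
  expect_true(attr(sel_log, "form") %in% c("fp1", "fp2"))
  expect_true(0 %in% sel_log$powers)
  # alpha = 1 degenerates to the best FP2
  sel_all <- select_fp(co_lin, "x", powers = grid, alpha = 1)
  expect_equal(attr(sel_all, "form"), "fp2")
  expect_length(sel_all$powers, 2)
  expect_error(select_fp(transform(co_lin, x = 1), "x"), "constant")
})

test_that("LASSO keeps forced terms, selects true signals, and refits unpenalized", {
  bin <- data.frame(name = c("forced_null", "cand_strong", "cand_null"),
                    prevalence = c(0.3, 0.25, 0.25))
  spec <- simulation_spec(
    n = 12000, binary_predictors = bin,
    continuous_predictors = data.frame(name = character(), mean = numeric(),
                                       sd = numeric(), lower = numeric(),
                                       upper = numeric(), dist = character()),
    true_terms = list(term_linear("cand_strong", log(2.2))),
    target_incidence = 0.12, admin_window = c(10, 10), dropout_rate = 0,
    seed = 33)
  co <- generate_cohort(spec)
  sel <- lasso_select(co, candidates = c("cand_strong", "cand_null"),
                      forced = "forced_null", seed = 5)
  expect_true("forced_null" %in% names(sel$model$beta))
  expect_true("cand_strong" %in% sel$selected)
  # the reported model is an unpenalized refit on forced + selected
  refit <- fit_cox(co, c("forced_null", sel$selected))
  expect_equal(sel$model$beta, refit$beta, tolerance = 1e-10)
  # empty candidate set returns forced only, without error
  sel0 <- lasso_select(co, candidates = character(), forced = "forced_null",
                       seed = 5)
  expect_equal(sel0$selected, character())
  expect_equal(names(sel0$model$beta), "forced_null")
  expect_error(lasso_select(co, candidates = "forced_null",
                            forced = "forced_null"), "overlap")
})
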