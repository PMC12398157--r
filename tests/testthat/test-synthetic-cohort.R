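test_that("simulation spec validates its fields", {
  expect_error(
    simulation_spec(0, data.frame(name = "a", prevalence = 0.1),
                    data.frame()),
    "field 'n'")
  expect_error(
    simulation_spec(10, data.frame(name = "a", prevalence = 1.2),
                    data.frame()),
    "prevalence")
  bad <- c(a = 0.5, b = 0.4)
  expect_error(
    simulation_spec(10, data.frame(name = "a", prevalence = 0.1),
                    data.frame(), categorical_predictors = list(g = bad)),
    "sum to 1")
  expect_error(
    simulation_spec(10, data.frame(name = "a", prevalence = 0.1),
                    data.frame(), horizon = -1),
    "horizon")
})

test_that("generation is a pure function of (spec, seed) with isolated substreams", {
  spec <- default_simulation_spec(n = 500, seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  d <- generate_cohort(spec, seed = 12)
  expect_false(identical(a$time, d$time))
  # turning missingness off must not perturb the survival draws
  e <- generate_cohort(spec, missingness = FALSE)
  expect_identical(a$time, e$time)
  expect_identical(a$event, e$event)
  expect_identical(a$lp_true, e$lp_true)
})

test_that("marginals are recovered at large n", {
  spec <- default_simulation_spec(n = 100000, seed = 2)
  co <- generate_cohort(spec, missingness = FALSE)
  n <- nrow(co)
  # binary prevalence: published pre-eclampsia 3.3%
  p <- 0.033
  expect_lt(abs(mean(co$pre_eclampsia) - p), 3 * sqrt(p * (1 - p) / n))
  # age moments survive the truncation to 15-49
  expect_lt(abs(mean(co$age) - 32.01), 3 * 6.63 / sqrt(n))
  expect_lt(abs(sd(co$age) - 6.63), 3 * 6.63 / sqrt(2 * n))
  # gravidity category shares
  expect_lt(abs(mean(co$gravidity == 1) - 0.452),
            3 * sqrt(0.452 * 0.548 / n))
  # smoking levels
  expect_lt(abs(mean(co$smoking == "current") - 0.189),
            3 * sqrt(0.189 * 0.811 / n))
})

test_that("survival generator matches its closed-form event fraction", {
  n <- 60000
  lam <- -log(0.99) / 10
  s <- simulate_survival(rep(0, n), lam,
                         censoring = list(admin_window = c(10, 10),
                                          dropout_rate = 0),
                         horizon = 10, seed = 4)
  p <- 1 - exp(-lam * 10)   # 1% by construction
  expect_lt(abs(mean(s$event) - p), 2 * sqrt(p * (1 - p) / n))
  expect_true(all(s$time > 0))
  expect_true(all(s$time <= 10))
})

test_that("proportional hazards structure: lp shift multiplies the hazard", {
  n <- 60000
  lam <- 0.01
  s0 <- simulate_survival(rep(0, n), lam,
                          censoring = list(admin_window = c(10, 10),
                                           dropout_rate = 0),
                          horizon = 10, seed = 5)
  s1 <- simulate_survival(rep(log(2), n), lam,
                          censoring = list(admin_window = c(10, 10),
                                           dropout_rate = 0),
                          horizon = 10, seed = 6)
  # cumulative hazard at t = 5: -log S(t) should double
  H0 <- -log(1 - mean(s0$time <= 5 & s0$event == 1))
  H1 <- -log(1 - mean(s1$time <= 5 & s1$event == 1))
  expect_lt(abs(H1 / H0 - 2), 0.15)
  expect_error(simulate_survival(c(0, Inf), lam), "non-finite")
  expect_error(simulate_survival(c(0, 1), 0), "baseline_rate")
})

test_that("default censoring yields the published median follow-up band", {
  spec <- default_simulation_spec(n = 30000, seed = 8)
  co <- generate_cohort(spec, missingness = FALSE)
  expect_gt(median(co$time), 3)
  expect_lt(median(co$time), 4.5)
})

test_that("missingness injection hits its rates and is MCAR", {
  spec <- default_simulation_spec(n = 10000, seed = 9)
  co <- generate_cohort(spec, missingness = FALSE)
  out <- inject_missingness(co, c(tchdl_ratio = 0.91), seed = 9)
  n_miss <- sum(is.na(out$tchdl_ratio))
  expect_lt(abs(n_miss - 9100), 2 * sqrt(10000 * 0.91 * 0.09))
  # unnamed columns and outcomes untouched
  expect_identical(out$time, co$time)
  expect_identical(out$sbp, co$sbp)
  # zero rates are the identity
  expect_identical(inject_missingness(co, c(bmi = 0), seed = 1), co)
  # MCAR: event rate among missing-BMI rows matches overall
  out2 <- inject_missingness(co, c(bmi = 0.24), seed = 10)
  expect_lt(abs(mean(out2$event[is.na(out2$bmi)]) - mean(co$event)),
            3 * sqrt(mean(co$event) / sum(is.na(out2$bmi))))
  expect_error(inject_missingness(co, c(nope = 0.5)), "absent")
  expect_error(inject_missingness(co, c(bmi = 1.5)), "\\[0, 1\\]")
})

test_that("eligibility filters run in the flow-diagram order and log removals", {
  base <- data.frame(
    age = c(50, rep(30, 9)),
    statins = c(0, 1, rep(0, 8)),
    died_before_index = c(0, 0, 1, rep(0, 7)),
    left_practice = c(0, 0, 0, 1, rep(0, 6)),
    last_collection_before_index = c(0, 0, 0, 0, 1, rep(0, 5)),
    prior_cvd = c(0, 0, 0, 0, 0, 1, rep(0, 4))
  )
  res <- apply_eligibility_filters(base)
  expect_equal(res$log$removed, rep(1L, 6))
  expect_equal(res$log$remaining, 9:4)
  expect_equal(nrow(res$cohort), 4)
  # a subject violating several rules is removed at the first applicable step
  multi <- base
  multi$statins[3] <- 1   # also died_before_index
  res2 <- apply_eligibility_filters(multi)
  expect_equal(res2$log$removed[res2$log$filter == "statins"], 2L)
  expect_equal(res2$log$removed[res2$log$filter == "died_before_index"], 0L)
  # age bounds are inclusive 15-49
  ok <- base[-1, ]
  ok$age[1] <- 15; ok$age[2] <- 49
  res3 <- apply_eligibility_filters(ok)
  expect_equal(res3$log$removed[1], 0L)
  expect_error(apply_eligibility_filters(base[, -2]), "statins")
})

test_that("cohort tables round-trip through CSV with empty-field NAs", {
  spec <- default_simulation_spec(n = 200, seed = 13)
  co <- generate_cohort(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$time, co$time)
  expect_equal(is.na(back$tchdl_ratio), is.na(co$tchdl_ratio))
  expect_equal(back$sbp, co$sbp)
})
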