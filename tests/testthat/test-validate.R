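test_that("pseudo-values match the naive jackknife exactly", {
  # 4-subject hand example: times 2, 4 (censored), 6, 12; horizon 10
  t4 <- c(2, 4, 6, 12); e4 <- c(1, 0, 1, 1)
  expect_equal(pseudo_values(t4, e4, 10), oracle_pseudo(t4, e4, 10),
               tolerance = 1e-10)
  # random censored fixtures, with ties
  set.seed(51)
  for (k in 1:5) {
    n <- sample(5:40, 1)
    tt <- ceiling(rexp(n, 0.2))
    ev <- rbinom(n, 1, 0.6)
    expect_equal(pseudo_values(tt, ev, 5), oracle_pseudo(tt, ev, 5),
                 tolerance = 1e-10)
  }
})

test_that("pseudo-values collapse to indicators without censoring and average to the KM risk", {
  set.seed(52)
  tt <- rexp(200, 0.1); ev <- rep(1, 200)
  pv <- pseudo_values(tt, ev, 8)
  expect_equal(pv, as.numeric(tt <= 8))
  # mean identity under censoring
  ev2 <- rbinom(200, 1, 0.5)
  pv2 <- pseudo_values(tt, ev2, 8)
  expect_equal(mean(pv2), km_risk(tt, ev2, 8)$risk, tolerance = 1e-10)
  # horizon before the first event: all zero
  expect_equal(pseudo_values(c(3, 4, 5), c(1, 1, 0), 1), c(0, 0, 0))
})

test_that("Harrell's C agrees with exhaustive pair enumeration", {
  co <- fixture_cohort()
  lp <- c(2.0, 0.1, 1.4, 1.0, 0.3, 0.9, 0.5, 0.2)
  expect_equal(harrell_c(lp, co$time, co$event)$c,
               oracle_harrell_c(lp, co$time, co$event),
               tolerance = 1e-12)
  # with score ties counting one half
  lp_tied <- c(1, 1, 1, 0, 0, 0, 1, 0)
  expect_equal(harrell_c(lp_tied, co$time, co$event)$c,
               oracle_harrell_c(lp_tied, co$time, co$event),
               tolerance = 1e-12)
  # perfect anti-ranking of event times gives C = 1
  tt <- 1:6; ev <- rep(1, 6)
  expect_equal(harrell_c(rev(tt), tt, ev)$c, 1)
  # uninformative score at large n sits near 0.5
  set.seed(53)
  tt <- rexp(4000); lp_r <- rnorm(4000)
  expect_lt(abs(harrell_c(lp_r, tt, rep(1, 4000))$c - 0.5), 0.03)
})

test_that("time-dependent C truncates at the horizon and reduces to Harrell without censoring", {
  set.seed(54)
  n <- 800
  tt <- rexp(n, 0.15); ev <- rep(1, n)
  lp <- -log(tt) + rnorm(n, 0, 0.5)
  tau <- 6
  ctd <- time_dependent_c(lp, tt, ev, tau)$c
  # Harrell restricted to pairs whose earlier time is within the horizon
  keep_time <- pmin(tt, tau + 1e-9)
  ch <- harrell_c(lp, pmin(tt, tau), ifelse(tt <= tau, ev, 0))$c
  expect_equal(ctd, ch, tolerance = 1e-9)
  expect_equal(time_dependent_c(-tt, tt, ev, tau)$c, 1)
  expect_error(time_dependent_c(lp, tt + 10, ev, 5), "no events")
})

test_that("Royston's D behaves at its anchors", {
  expect_warning(d0 <- royston_d(rep(1, 50), rexp(50), rbinom(50, 1, 0.5)),
                 "constant")
  expect_equal(d0$d, 0)
  expect_equal(d0$r2, 0)
  # standard-normal LP as the true log-hazard: D estimates kappa = sqrt(8/pi)
  set.seed(55)
  n <- 20000
  lp <- rnorm(n)
  tt <- rexp(n, exp(lp) * 0.1)
  obs <- pmin(tt, 15)
  ev <- as.integer(tt <= 15)
  d <- royston_d(lp, obs, ev)
  expect_lt(abs(d$d - sqrt(8 / pi)), 3 * d$se + 0.05)
})

test_that("O/E ratio equals hand KM over mean prediction and scales", {
  tt <- c(2, 4, 6, 8, 12); ev <- c(1, 0, 1, 0, 1)
  pred <- c(0.2, 0.1, 0.3, 0.2, 0.25)
  o_hand <- 1 - oracle_km(tt, ev, 10)
  res <- oe_ratio(pred, tt, ev, 10)
  expect_equal(res$oe, o_hand / mean(pred), tolerance = 1e-12)
  # halving all predictions doubles O/E
  expect_equal(oe_ratio(pred / 2, tt, ev, 10)$oe, 2 * res$oe,
               tolerance = 1e-12)
  # predictions equal to the KM risk give O/E = 1
  expect_equal(oe_ratio(rep(o_hand, 5), tt, ev, 10)$oe, 1, tolerance = 1e-12)
  expect_error(oe_ratio(rep(0, 5), tt, ev, 10), "> 0")
})

test_that("calibration slope recovers 1/k when the LP is shrunk by k", {
  set.seed(56)
  n <- 30000
  lp <- rnorm(n, 0, 0.8)
  s0 <- 0.90
  risk_true <- 1 - s0^exp(lp)
  tt <- rexp(n, -log(s0) / 10 * exp(lp))
  obs <- pmin(tt, 10); ev <- as.integer(tt <= 10)
  pv <- pseudo_values(obs, ev, 10)
  for (k in c(0.5, 1, 2)) {
    risk_k <- 1 - exp(-exp(cloglog(risk_true) * k + log(-log(s0)) * (1 - k)))
    cal <- calibration_intercept_slope(pv, risk_k)
    expect_lt(abs(cal$slope$est - 1 / k), 0.08)
  }
  # additive cloglog shift of +0.3 yields intercept near -0.3
  risk_s <- inv_cloglog(cloglog(risk_true) + 0.3)
  cal_s <- calibration_intercept_slope(pv, risk_s)
  expect_lt(abs(cal_s$intercept$est + 0.3), 0.05)
  # well-calibrated predictions: intercept near 0, slope near 1
  cal0 <- calibration_intercept_slope(pv, risk_true)
  expect_lt(abs(cal0$intercept$est), 0.05)
  expect_lt(abs(cal0$slope$est - 1), 0.08)
})

test_that("calibration curve bins by risk percentile with near-equal groups", {
  set.seed(57)
  n <- 1037
  pred <- runif(n, 0.01, 0.3)
  pv <- pred + rnorm(n, 0, 0.05)
  cc <- calibration_curve(pred, pv, n_groups = 10)
  expect_equal(nrow(cc), 10)
  expect_lte(diff(range(cc$n)), 1)
  expect_true(!is.unsorted(cc$mean_pred))
  expect_true(all(cc$lower <= cc$observed & cc$observed <= cc$upper))
  # single group collapses to the overall means
  c1 <- calibration_curve(pred, pv, n_groups = 1)
  expect_equal(c1$mean_pred, mean(pred))
  expect_equal(c1$observed, mean(pv))
})

test_that("performance within subgroups conserves events and flags sparse groups", {
  spec <- default_simulation_spec(n = 8000, seed = 58, missingness = FALSE)
  spec$target_incidence <- 0.08
  co <- generate_cohort(spec)
  lp <- co$lp_true
  risk <- pmin(pmax(0.08 * exp(lp - mean(lp)), 0.001), 0.8)
  sub <- subgroup_performance(co, lp, risk, "smoking", horizon = 10)
  ev <- vapply(sub, `[[`, 0, "events")
  expect_equal(sum(ev), sum(co$event))
  # a single all-encompassing group reproduces the overall metrics
  co$all <- "everyone"
  sub1 <- subgroup_performance(co, lp, risk, "all", horizon = 10)
  overall <- performance_report(lp, risk, co$time, co$event, 10)
  expect_equal(sub1$everyone$report$discrimination$c$c,
               overall$discrimination$c$c)
  # sparse group flagged
  co$tiny <- ifelse(seq_len(nrow(co)) <= 60, "rare", "common")
  # a ~5-event group: expect a flag (and possibly convergence noise)
  sub2 <- suppressWarnings(
    subgroup_performance(co, lp, risk, "tiny", horizon = 10))
  expect_true(sub2$rare$low_information ||
                is.null(sub2$rare$report))
  expect_error(subgroup_performance(co, lp, risk, "nope"), "nope")
})

test_that("net benefit obeys its limits and dominance properties", {
  set.seed(59)
  n <- 6000
  event_frac <- 0.10
  truth <- rbinom(n, 1, event_frac)
  tt <- ifelse(truth == 1, runif(n, 0, 10), 10)
  ev <- truth
  # treat-none is identically zero; treat-all tends to the KM incidence
  perfect <- ifelse(truth == 1, 0.9, 0.01)
  dc <- net_benefit(perfect, tt, ev, 10, thresholds = seq(0.01, 0.5, 0.01))
  expect_true(all(dc$nb_none == 0))
  km10 <- km_risk(tt, ev, 10)$risk
  expect_lt(abs(dc$nb_all[1] - (km10 - (1 - km10) * 0.01 / 0.99)), 1e-12)
  expect_lt(abs(dc$nb_all[1] - km10), 0.01)
  # a perfect discrete predictor dominates treat-all above the event fraction
  above <- dc$threshold > km10 + 0.02 & dc$threshold < 0.5
  expect_true(all(dc$nb_model[above] >= dc$nb_all[above]))
  expect_true(all(dc$nb_model >= 0))
  expect_error(net_benefit(perfect, tt, ev, 10, thresholds = c(0, 0.5)),
               "strictly")
  expect_error(net_benefit(perfect, tt, ev, 10, thresholds = c(0.3, 0.2)),
               "increasing")
})
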