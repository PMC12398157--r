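#' Generate a synthetic postpartum cohort
#'
#' Draws predictors from the marginal distributions of a
#' [simulation_spec()] (independently by default, since only marginals are
#' reported for the population being emulated), builds the true linear
#' predictor from the spec's terms, simulates proportional-hazards event
#' times over an exponential baseline, applies administrative censoring and
#' dropout, and (optionally) injects missingness.
#'
#' All randomness flows from the root seed through named substreams, so the
#' same seed always yields a byte-identical table and changing, say, the
#' missingness rates does not disturb the event-time draws.
#'
#' @param spec a [simulation_spec()].
#' @param n number of subjects (defaults to `spec$n`).
#' @param seed root seed (defaults to `spec$seed`).
#' @param missingness apply `spec$missingness_rates` (default `TRUE`).
#' @param eligibility_flags add the administrative flag columns consumed by
#'   [apply_eligibility_filters()], drawn at realistic rates.
#' @return A data.frame with `subject_id`, one column per predictor, the
#'   true linear predictor `lp_true`, follow-up `time` (years, > 0) and
#'   `event` (0/1). The calibrated baseline rate is stored in
#'   `attr(, "baseline_rate")`.
#' @export
generate_cohort <- function(spec, n = spec$n, seed = spec$seed,
                            missingness = TRUE, eligibility_flags = FALSE) {
  stopifnot(inherits(spec, "ppcvd_simspec"), n >= 1)
  cohort <- data.frame(subject_id = seq_len(n))

  bp <- spec$binary_predictors
  for (i in seq_len(nrow(bp))) {
    cohort[[bp$name[i]]] <- with_substream(
      seed, paste0("bin:", bp$name[i]),
      rbinom(n, 1L, bp$prevalence[i]))
  }
  cp <- spec$continuous_predictors
  for (i in seq_len(nrow(cp))) {
    nm <- cp$name[i]
    cohort[[nm]] <- with_substream(seed, paste0("cont:", nm), {
      if (cp$dist[i] == "lognormal") {
        exp(rnorm(n, cp$mean[i], cp$sd[i]))
      } else {
        rtruncnorm_matched(n, cp$mean[i], cp$sd[i], cp$lower[i], cp$upper[i])
      }
    })
  }
  for (nm in names(spec$categorical_predictors)) {
    p <- spec$categorical_predictors[[nm]]
    cohort[[nm]] <- with_substream(
      seed, paste0("cat:", nm),
      factor(sample(names(p), n, replace = TRUE, prob = p),
             levels = names(p)))
  }
  for (nm in names(spec$ordinal_predictors)) {
    p <- spec$ordinal_predictors[[nm]]
    cohort[[nm]] <- with_substream(
      seed, paste0("ord:", nm),
      sample(attr(p, "values"), n, replace = TRUE, prob = as.numeric(p)))
  }

  truth <- coefficient_set("truth", spec$true_terms, baseline_survival = 1,
                           horizon = spec$horizon)
  lp <- linear_predictor(cohort, truth)
  rate <- spec$baseline_rate %||%
    calibrate_baseline_rate(lp, spec$target_incidence, spec$horizon)

  surv <- simulate_survival(lp, rate,
                            censoring = list(admin_window = spec$admin_window,
                                             dropout_rate = spec$dropout_rate),
                            horizon = spec$horizon, seed = seed)
  cohort$lp_true <- lp
  cohort$time <- surv$time
  cohort$event <- surv$event

  if (eligibility_flags) {
    flag_rates <- c(statins = 0.0031, died_before_index = 0.00045,
                    left_practice = 0.17,
                    last_collection_before_index = 0.07, prior_cvd = 0.0013)
    for (nm in names(flag_rates)) {
      cohort[[nm]] <- with_substream(seed, paste0("flag:", nm),
                                     rbinom(n, 1L, flag_rates[[nm]]))
    }
  }

  if (missingness && length(spec$missingness_rates))
    cohort <- inject_missingness(cohort, spec$missingness_rates, seed = seed)

  attr(cohort, "baseline_rate") <- rate
  cohort
}

truncnorm_moments <- function(mu, sig, lo, hi) {
  a <- (lo - mu) / sig; b <- (hi - mu) / sig
  Z <- pnorm(b) - pnorm(a)
  dphi <- (stats::dnorm(a) - stats::dnorm(b)) / Z
  m <- mu + sig * dphi
  v <- sig^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / Z - dphi^2)
  c(mean = m, sd = sqrt(v))
}

# parent (mu, sigma) whose truncation to [lo, hi] has the target moments,
# so configured means/SDs are recovered despite the truncation
truncnorm_params <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (mm["mean"] - mean)^2 + (mm["sd"] - sd)^2
  }
  p <- stats::optim(c(mean, log(sd)), obj,
                    control = list(reltol = 1e-14, maxit = 2000))$par
  c(mu = p[1], sigma = exp(p[2]))
}

rtruncnorm_matched <- function(n, mean, sd, lo, hi) {
  if (is.na(lo) && is.na(hi)) return(rnorm(n, mean, sd))
  p <- truncnorm_params(mean, sd, lo, hi)
  u <- runif(n, pnorm(lo, p["mu"], p["sigma"]), pnorm(hi, p["mu"], p["sigma"]))
  qnorm(u, p["mu"], p["sigma"])
}

#' Calibrate the exponential baseline rate to a target incidence
#'
#' Solves `mean(1 - exp(-rate * exp(lp) * horizon)) = target` for the
#' baseline rate, so that the marginal cumulative incidence at the horizon
#' matches the target in expectation over the realised linear predictors.
#'
#' @param lp numeric vector of linear predictors.
#' @param target marginal cumulative incidence at the horizon.
#' @param horizon years.
#' @return The baseline rate (events per person-year).
#' @export
calibrate_baseline_rate <- function(lp, target, horizon) {
  stopifnot(all(is.finite(lp)), target > 0, target < 1, horizon > 0)
  f <- function(lr) mean(1 - exp(-exp(lr) * exp(lp) * horizon)) - target
  exp(uniroot(f, c(-40, 5), tol = 1e-12)$root)
}

#' Simulate proportional-hazards survival times
#'
#' Latent event times are exponential with rate `baseline_rate * exp(lp)`;
#' the observed time is the minimum of the event time, a uniform
#' administrative-censoring draw on `censoring$admin_window`, an exponential
#' dropout draw at `censoring$dropout_rate`, and the horizon. `event = 1`
#' iff the latent event time attains the minimum.
#'
#' @param lp finite linear predictors.
#' @param baseline_rate exponential baseline rate (> 0).
#' @param censoring list with `admin_window` (length-2) and `dropout_rate`.
#' @param horizon years.
#' @param seed root seed (substream `"survival"`).
#' @return data.frame with `time` and `event` columns.
#' @export
simulate_survival <- function(lp, baseline_rate,
                              censoring = list(admin_window = c(1, 10),
                                               dropout_rate = 0),
                              horizon = 10, seed = 1L) {
  if (!all(is.finite(lp))) stop("non-finite linear predictors", call. = FALSE)
  if (baseline_rate <= 0) stop("'baseline_rate' must be > 0", call. = FALSE)
  n <- length(lp)
  with_substream(seed, "survival", {
    t_event <- rexp(n, rate = 1) / (baseline_rate * exp(lp))
    t_admin <- runif(n, censoring$admin_window[1], censoring$admin_window[2])
    t_drop <- if (censoring$dropout_rate > 0)
      rexp(n, censoring$dropout_rate) else rep(Inf, n)
    t_cens <- pmin(t_admin, t_drop, horizon)
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  })
}

#' Inject missingness completely at random
#'
#' Sets each named predictor missing (NA) independently at its configured
#' rate; follow-up time and event status are never touched.
#'
#' @param cohort data.frame.
#' @param rates named numeric vector of rates in `[0, 1]`; names must be
#'   predictor columns.
#' @param seed root seed (substreams `"miss:<name>"`).
#' @return The cohort with NAs injected.
#' @export
inject_missingness <- function(cohort, rates, seed = 1L) {
  check_prob(unname(rates), "rates")
  bad <- setdiff(names(rates), names(cohort))
  if (length(bad))
    stop("missingness rates name absent predictors: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(names(rates) %in% c("time", "event")))
    stop("cannot inject missingness into time/event", call. = FALSE)
  for (nm in names(rates)) {
    hit <- with_substream(seed, paste0("miss:", nm),
                          runif(nrow(cohort)) < rates[[nm]])
    cohort[[nm]][hit] <- NA
  }
  cohort
}

#' Apply the study eligibility filters
#'
#' Filters are applied in the published flow-diagram order: outside the age
#' window, on statins, died before the index date, left the practice, last
#' practice data collection before index, prior CVD. Each step's removals
#' and the running remaining count are logged.
#'
#' @param cohort data.frame with `age` plus 0/1 flag columns `statins`,
#'   `died_before_index`, `left_practice`, `last_collection_before_index`,
#'   `prior_cvd`.
#' @param age_range inclusive eligible age bounds.
#' @return list with elements `cohort` (eligible rows) and `log` (a
#'   data.frame of `filter`, `removed`, `remaining`).
#' @export
apply_eligibility_filters <- function(cohort, age_range = c(15, 49)) {
  flags <- c("statins", "died_before_index", "left_practice",
             "last_collection_before_index", "prior_cvd")
  need <- c("age", flags)
  absent <- setdiff(need, names(cohort))
  if (length(absent))
    stop("eligibility filtering needs missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  steps <- c("age_outside_range", flags)
  log <- data.frame(filter = steps, removed = NA_integer_,
                    remaining = NA_integer_)
  keep <- cohort$age >= age_range[1] & cohort$age <= age_range[2]
  log$removed[1] <- sum(!keep)
  cohort <- cohort[keep, , drop = FALSE]
  log$remaining[1] <- nrow(cohort)
  for (i in seq_along(flags)) {
    drop <- cohort[[flags[i]]] == 1
    log$removed[i + 1] <- sum(drop)
    cohort <- cohort[!drop, , drop = FALSE]
    log$remaining[i + 1] <- nrow(cohort)
  }
  list(cohort = cohort, log = log)
}

#' Read and write cohort tables as delimited text
#'
#' Plain CSV with a header row; missing values are empty fields.
#'
#' @param cohort data.frame.
#' @param path file path.
#' @return `read_cohort()` returns a data.frame; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}
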