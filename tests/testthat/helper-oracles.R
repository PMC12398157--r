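# Brute-force oracles used to verify the analytic implementations on tiny
# fixtures. These are deliberately naive and independent of the package's
# code paths.

# Efron partial log-likelihood for a single covariate, evaluated directly
# from its definition.
oracle_efron_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (t_j in sort(unique(time[event == 1]))) {
    D <- which(time == t_j & event == 1)
    R <- which(time >= t_j)
    d <- length(D)
    sumR <- sum(exp(eta[R]))
    sumD <- sum(exp(eta[D]))
    for (l in seq_len(d) - 1) {
      ll <- ll + sum(eta[D]) / d - log(sumR - (l / d) * sumD)
    }
  }
  ll
}

# maximiser of the Efron partial likelihood by 1-d optimisation
oracle_cox_beta <- function(time, event, x, interval = c(-5, 5)) {
  stats::optimize(function(b) oracle_efron_loglik(b, time, event, x),
                  interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# Kaplan-Meier survival at tau from its product definition
oracle_km <- function(time, event, tau) {
  s <- 1
  for (t_j in sort(unique(time[event == 1]))) {
    if (t_j > tau) break
    d <- sum(time == t_j & event == 1)
    n <- sum(time >= t_j)
    s <- s * (1 - d / n)
  }
  s
}

# naive leave-one-out jackknife pseudo-values of the KM incidence
oracle_pseudo <- function(time, event, tau) {
  n <- length(time)
  F_full <- 1 - oracle_km(time, event, tau)
  vapply(seq_len(n), function(i)
    n * F_full - (n - 1) * (1 - oracle_km(time[-i], event[-i], tau)), 0)
}

# Harrell's C by exhaustive pair enumeration (ties in score count 1/2)
oracle_harrell_c <- function(lp, time, event) {
  num <- den <- 0
  n <- length(lp)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # comparable iff the (effectively) shorter time is an event; a tied
    # event/censored pair counts with the event as the earlier time
    if (time[i] == time[j]) {
      if (event[i] + event[j] != 1) next
      a <- if (event[i] == 1) i else j
      b <- if (event[i] == 1) j else i
    } else {
      a <- if (time[i] < time[j]) i else j
      b <- if (time[i] < time[j]) j else i
      if (event[a] == 0) next
    }
    den <- den + 1
    if (lp[a] > lp[b]) num <- num + 1
    else if (lp[a] == lp[b]) num <- num + 0.5
  }
  num / den
}

# Breslow baseline cumulative hazard from its definition
oracle_breslow <- function(time, event, eta, tau) {
  H <- 0
  for (t_j in sort(unique(time[event == 1]))) {
    if (t_j > tau) break
    d <- sum(time == t_j & event == 1)
    H <- H + d / sum(exp(eta[time >= t_j]))
  }
  H
}

# small deterministic survival fixture with ties and censoring
fixture_cohort <- function() {
  data.frame(
    subject_id = 1:8,
    x = c(1, 0, 1, 0, 1, 0, 1, 0),
    time = c(2, 4, 4, 5, 6, 6, 9, 12),
    event = c(1, 0, 1, 1, 0, 1, 1, 0)
  )
}
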