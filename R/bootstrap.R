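eval_core_metrics <- function(coeffs, cohort, horizon) {
  lp <- linear_predictor(cohort, coeffs)
  risk <- predicted_risk(lp, coeffs)
  pv <- pseudo_values(cohort$time, cohort$event, horizon)
  c(C = harrell_c(lp, cohort$time, cohort$event)$c,
    D = royston_d(lp, cohort$time, cohort$event)$d,
    slope = calibration_intercept_slope(pv, risk)$slope$est)
}

#' Bootstrap optimism correction
#'
#' Internal validation by the bootstrap: each replicate resamples subjects
#' with replacement, reruns the entire modelling recipe (including any
#' variable selection) on the resample, and evaluates the resulting model
#' both on the resample and on the original cohort. The per-replicate
#' optimism is the difference, and the optimism-adjusted statistic is the
#' apparent value minus the mean optimism. Replicates that fail (e.g. a
#' resample with no events) are logged and skipped.
#'
#' @param cohort development data with `time`/`event`.
#' @param recipe function taking a cohort and returning a
#'   [coefficient_set()] — the full modelling process to be repeated.
#' @param B number of bootstrap replicates (the study default is 500; use a
#'   small B for smoke tests).
#' @param seed root seed (substream `"bootstrap"`).
#' @param horizon years.
#' @return An object of class `ppcvd_bootstrap`: per metric (C, D,
#'   calibration slope) the apparent value, mean optimism, and adjusted
#'   value; plus replicate bookkeeping.
#' @export
bootstrap_optimism <- function(cohort, recipe, B = 500, seed = 1L,
                               horizon = 10) {
  stopifnot(is.function(recipe), B >= 1)
  apparent <- eval_core_metrics(recipe(cohort), cohort, horizon)
  n <- nrow(cohort)
  idx <- with_substream(seed, "bootstrap",
                        replicate(B, sample.int(n, n, replace = TRUE),
                                  simplify = FALSE))
  opt <- matrix(NA_real_, B, 3, dimnames = list(NULL, names(apparent)))
  failures <- character()
  for (b in seq_len(B)) {
    # warnings inside replicates (near-separation in resamples, glmnet
    # path chatter) are expected at bootstrap scale; failures are logged
    res <- tryCatch(suppressWarnings({
      boot <- cohort[idx[[b]], , drop = FALSE]
      fit_b <- recipe(boot)
      eval_core_metrics(fit_b, boot, horizon) -
        eval_core_metrics(fit_b, cohort, horizon)
    }), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", b, res$message))
    } else {
      opt[b, ] <- res
    }
  }
  done <- sum(!is.na(opt[, 1]))
  if (done == 0) stop("all bootstrap replicates failed", call. = FALSE)
  mean_opt <- colMeans(opt, na.rm = TRUE)
  structure(list(apparent = apparent, optimism = mean_opt,
                 adjusted = apparent - mean_opt,
                 B = B, completed = done, failures = failures,
                 seed = seed),
            class = "ppcvd_bootstrap")
}

#' @export
print.ppcvd_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap optimism (%d/%d replicates)\n", x$completed, x$B))
  tab <- data.frame(apparent = x$apparent, optimism = x$optimism,
                    adjusted = x$adjusted)
  print(round(tab, 4))
  invisible(x)
}
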