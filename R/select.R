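#' Fractional-polynomial power grid
#'
#' The standard Royston-Sauerbrei grid.
#' @export
fp_power_grid <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp_loglik <- function(cohort, variable, powers, divisor, shift) {
  fp <- fp_spec(variable, powers, divisor = divisor, shift = shift)
  Z <- fp_transform(cohort[[variable]], fp)
  y <- survival::Surv(cohort$time, cohort$event)
  fit <- survival::coxph(y ~ Z, ties = "efron")
  fit$loglik[2]
}

#' Select a fractional-polynomial form by closed testing
#'
#' Finds the best-fitting FP2 (pair of powers, duplicates allowed) and FP1
#' (single power) from the power grid by partial log-likelihood, then runs
#' the Royston-Sauerbrei closed test at level `alpha`: FP2 vs omitting the
#' variable (4 df), FP2 vs linear (3 df), FP2 vs FP1 (2 df). The first
#' non-significant comparison decides the returned form.
#'
#' @param cohort data.frame with `time`, `event` and the variable.
#' @param variable column name (strictly positive after shift/scale).
#' @param powers candidate power grid.
#' @param alpha test level (1 forces the full FP2 best fit).
#' @param divisor,shift pre-scaling applied before the powers.
#' @return An [fp_spec()] for the chosen form (power 1 for linear), or
#'   `NULL` when the variable is omitted; the chosen form label is in
#'   `attr(, "form")`.
#' @export
select_fp <- function(cohort, variable, powers = fp_power_grid,
                      alpha = 0.05, divisor = 1, shift = 0) {
  x <- cohort[[variable]]
  if (is.null(x)) stop("no such column: ", variable, call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("'", variable, "' is constant; cannot select an FP form",
         call. = FALSE)
  ll1 <- vapply(powers, function(p)
    fp_loglik(cohort, variable, p, divisor, shift), 0)
  best1 <- powers[which.max(ll1)]
  pairs <- expand.grid(p1 = powers, p2 = powers)
  pairs <- pairs[pairs$p1 <= pairs$p2, ]
  ll2 <- mapply(function(a, b)
    fp_loglik(cohort, variable, c(a, b), divisor, shift),
    pairs$p1, pairs$p2)
  best2 <- as.numeric(pairs[which.max(ll2), ])
  ll_fp2 <- max(ll2); ll_fp1 <- max(ll1)
  ll_lin <- fp_loglik(cohort, variable, 1, divisor, shift)
  ll_null <- {
    y <- survival::Surv(cohort$time, cohort$event)
    survival::coxph(y ~ 1, ties = "efron")$loglik[1]
  }
  pval <- function(ll_big, ll_small, df)
    pchisq(2 * (ll_big - ll_small), df = df, lower.tail = FALSE)

  form <- "fp2"; chosen <- best2
  if (alpha < 1) {
    if (pval(ll_fp2, ll_null, 4) >= alpha) {
      out <- NULL; attr(out, "form") <- "omit"; return(out)
    }
    if (pval(ll_fp2, ll_lin, 3) >= alpha) {
      form <- "linear"; chosen <- 1
    } else if (pval(ll_fp2, ll_fp1, 2) >= alpha) {
      form <- "fp1"; chosen <- best1
    }
  }
  out <- fp_spec(variable, chosen, divisor = divisor, shift = shift)
  attr(out, "form") <- form
  out
}

#' LASSO variable selection with forced-in predictors
#'
#' Penalised Cox regression over forced plus candidate terms with zero
#' penalty on the forced ones; the penalty weight is chosen by 10-fold
#' cross-validated partial likelihood (fold assignment seeded). Candidates
#' with a non-zero penalised coefficient at the chosen weight are selected,
#' and the reported model is an unpenalised Cox refit on forced plus
#' selected terms, so no shrunken coefficient ever leaves this function.
#'
#' @param cohort data.frame with `time`, `event` and predictors.
#' @param candidates character vector of candidate columns (or term list).
#' @param forced character vector of forced-in columns (or term list).
#' @param lambda_rule `"lambda.min"` (default) or `"lambda.1se"`.
#' @param nfolds cross-validation folds.
#' @param seed seed for the fold assignment.
#' @return list of class `ppcvd_selection`: `forced`, `candidates`,
#'   `selected` (term-name vectors), `lambda` (grid, chosen value, rule)
#'   and `model`, the final unpenalised [fit_cox()].
#' @export
lasso_select <- function(cohort, candidates, forced,
                         lambda_rule = c("lambda.min", "lambda.1se"),
                         nfolds = 10, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  f_terms <- if (is.character(forced)) cohort_terms(cohort, forced) else forced
  c_terms <- if (is.character(candidates))
    cohort_terms(cohort, candidates) else candidates
  f_names <- vapply(f_terms, `[[`, "", "name")
  c_names <- vapply(c_terms, `[[`, "", "name")
  if (length(intersect(f_names, c_names)))
    stop("candidates and forced terms overlap", call. = FALSE)

  if (!length(c_terms)) {
    model <- fit_cox(cohort, f_terms)
    return(structure(list(forced = f_names, candidates = character(),
                          selected = character(), lambda = NULL,
                          model = model), class = "ppcvd_selection"))
  }
  terms <- c(f_terms, c_terms)
  X <- design_matrix(cohort, terms)
  y <- survival::Surv(cohort$time, cohort$event)
  pf <- c(rep(0, length(f_terms)), rep(1, length(c_terms)))
  foldid <- with_substream(seed, "lasso_folds",
                           sample(rep_len(seq_len(nfolds), nrow(cohort))))
  glmnet_warnings <- 0L
  cvfit <- withCallingHandlers(
    glmnet::cv.glmnet(X, y, family = "cox", penalty.factor = pf,
                      foldid = foldid),
    warning = function(w) {
      glmnet_warnings <<- glmnet_warnings + 1L
      invokeRestart("muffleWarning")
    })
  if (glmnet_warnings > 0)
    warning(sprintf(
      "glmnet reported %d numerical warning(s) along the penalty path; %s",
      glmnet_warnings, "selection used the returned solutions"))
  lam <- cvfit[[lambda_rule]]
  b <- as.numeric(coef(cvfit, s = lam))
  selected <- c_names[b[length(f_terms) + seq_along(c_terms)] != 0]
  final_terms <- c(f_terms, c_terms[c_names %in% selected])
  model <- fit_cox(cohort, final_terms)
  structure(list(forced = f_names, candidates = c_names,
                 selected = selected,
                 lambda = list(grid = cvfit$lambda, chosen = lam,
                               rule = lambda_rule),
                 model = model),
            class = "ppcvd_selection")
}

#' @export
print.ppcvd_selection <- function(x, ...) {
  cat(sprintf("LASSO selection: %d forced, %d/%d candidates selected\n",
              length(x$forced), length(x$selected), length(x$candidates)))
  if (length(x$selected))
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
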