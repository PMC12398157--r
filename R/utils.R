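#' @keywords internal
"_PACKAGE"

#' @importFrom stats qnorm rnorm runif rexp rbinom median quantile coef vcov
#'   pnorm pchisq glm quasi as.formula sd setNames aggregate ave uniroot
#'   predict complete.cases
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one root seed; each operation
#' draws from its own named substream so that, e.g., adding missingness does
#' not perturb the event-time draws.
#'
#' @param seed integer root seed.
#' @param name character substream label.
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 48271 + h) %% 2147483629)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid simulation spec: field '%s' %s", field, msg),
       call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_config(field, "must lie in [0, 1]")
  invisible(x)
}

#' Complementary log-log and its inverse
#'
#' @param p probabilities in (0, 1).
#' @param x values on the cloglog scale.
#' @return Transformed numeric vector.
#' @export
cloglog <- function(p) log(-log(1 - p))

#' @rdname cloglog
#' @export
inv_cloglog <- function(x) 1 - exp(-exp(x))
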