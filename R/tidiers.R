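#' Tidy a ssripgx model fit
#'
#' Returns one row per model term with the log-odds estimate, Wald standard
#' error, two-sided Wald p-value, and the odds ratio with its 95% (or
#' `conf_level`) Wald confidence interval `exp(beta +/- z * se)`. Threshold
#' terms of cumulative-logit fits are labelled in `coefficient_type`.
#'
#' @param x A `pgx_fit` object from [fit_cumulative_logit()],
#'   [fit_logistic()] or [fit_random_intercept()].
#' @param conf_level Confidence level.
#' @param ... Unused.
#' @return A tibble with columns `term`, `coefficient_type`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `or`, `conf.low`, `conf.high`.
#' @exportS3Method generics::tidy
tidy.pgx_fit <- function(x, conf_level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(pmax(diag(x$vcov), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  stat <- est / se
  tibble(
    term = names(est),
    coefficient_type = ifelse(names(est) %in% (x$threshold_terms %||%
                                                 character(0)),
                              "threshold", "location"),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * pnorm(-abs(stat))),
    or = unname(exp(est)),
    conf.low = unname(exp(est - z * se)),
    conf.high = unname(exp(est + z * se))
  )
}

#' Glance at a ssripgx model fit
#'
#' @param x A `pgx_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `n` (records), `n_groups` and
#'   `sigma` where applicable, `converged` and `flag`.
#' @exportS3Method generics::glance
glance.pgx_fit <- function(x, ...) {
  tibble(
    model = x$model,
    logLik = x$logLik,
    n = x$n,
    n_groups = x$n_groups %||% NA_integer_,
    sigma = x$sigma %||% NA_real_,
    converged = x$converged,
    flag = x$flag
  )
}

#' @export
print.pgx_fit <- function(x, ...) {
  cat(sprintf("<%s> n=%d logLik=%.3f (%s)\n", x$model, x$n,
              x$logLik %||% NA_real_, x$flag))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
logLik.pgx_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
coef.pgx_fit <- function(object, ...) object$coefficients

#' @export
vcov.pgx_fit <- function(object, ...) object$vcov
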