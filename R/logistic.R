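#' Fit a logistic regression with convergence flagging
#'
#' Standard maximum-likelihood logistic regression (via [stats::glm()])
#' wrapped into the package's common fit container, with explicit flagging
#' of non-identifiable (constant-outcome) and quasi-separated data instead
#' of exceptions, matching the contract of [fit_cumulative_logit()].
#'
#' @param data A data frame.
#' @param formula Model formula with a binary (0/1 or two-level factor)
#'   response.
#' @return An object of class `pgx_logit`/`pgx_fit`.
#' @export
#' @examples
#' d <- data.frame(y = rbinom(50, 1, 0.4), x = rnorm(50))
#' tidy(fit_logistic(d, y ~ x))
fit_logistic <- function(data, formula) {
  mf <- model.frame(formula, data, na.action = stats::na.omit)
  y <- model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1))) abort("the response must be binary (0/1).")
  skeleton <- function(flag, coefs, vc, ll, converged) {
    structure(
      list(coefficients = coefs, vcov = vc, logLik = ll, n = length(y),
           converged = converged, flag = flag, model = "logistic",
           formula = formula),
      class = c("pgx_logit", "pgx_fit")
    )
  }
  X <- model.matrix(attr(mf, "terms"), mf)
  if (length(unique(y)) < 2) {
    p <- ncol(X)
    return(skeleton(
      "non_identifiable",
      setNames(rep(NA_real_, p), colnames(X)),
      matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X))),
      NA_real_, FALSE
    ))
  }
  if (qr(X)$rank < ncol(X)) abort("the design matrix is rank deficient.")
  fit <- suppressWarnings(
    glm(formula, family = binomial(), data = mf,
        control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  vc <- vcov(fit)
  se <- sqrt(diag(vc))
  flag <- if (!fit$converged) "non_convergence"
          else if (any(abs(coef(fit)) > 15) || any(se > 50)) {
            "possible_separation"
          } else "ok"
  skeleton(flag, coef(fit), vc, as.numeric(logLik(fit)), fit$converged)
}
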