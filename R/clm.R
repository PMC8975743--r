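#' Category probabilities under the cumulative-logit model
#'
#' For thresholds `theta` (strictly increasing, length K-1) and a linear
#' predictor `eta`, returns the K category probabilities implied by
#' `logit P(y <= k) = theta_k - eta`. Positive `eta` shifts mass towards
#' higher categories.
#'
#' @param theta Numeric vector of K-1 increasing thresholds.
#' @param eta Numeric vector of linear predictors.
#' @return A `length(eta)` x K matrix of probabilities; rows sum to 1.
#' @export
#' @examples
#' cumulative_logit_probs(qlogis(c(1 / 3, 2 / 3)), 0)
cumulative_logit_probs <- function(theta, eta) {
  if (is.unsorted(theta, strictly = TRUE)) {
    abort("`theta` must be strictly increasing.")
  }
  cum <- plogis(outer(-eta, theta, `+`))
  cbind(cum, 1) - cbind(0, cum)
}

# log-likelihood, gradient and Hessian of the proportional-odds model at
# psi = (theta_1..theta_{K-1}, beta). Fully vectorised; infinite bounds for
# the outer categories contribute zero density terms.
clm_derivs <- function(psi, y, X, K) {
  q <- K - 1
  theta <- psi[seq_len(q)]
  beta <- psi[-seq_len(q)]
  eta <- if (length(beta)) drop(X %*% beta) else numeric(length(y))
  a <- c(theta, Inf)[y] - eta
  b <- c(-Inf, theta)[y] - eta
  Fa <- plogis(a); Fb <- plogis(b)
  P <- pmax(Fa - Fb, 1e-300)
  ga <- ifelse(is.finite(a), dlogis(a), 0)
  gb <- ifelse(is.finite(b), dlogis(b), 0)
  ha <- ga * (1 - 2 * Fa)
  hb <- gb * (1 - 2 * Fb)
  ra <- ga / P; rb <- gb / P
  waa <- ha / P - ra^2
  wbb <- -hb / P - rb^2
  wab <- ra * rb

  p <- length(beta)
  grad <- numeric(q + p)
  H <- matrix(0, q + p, q + p)
  sum_by <- function(v, k) sum(v[y == k])
  for (k in seq_len(q)) {
    grad[k] <- sum_by(ra, k) - sum_by(rb, k + 1)
    H[k, k] <- sum_by(waa, k) + sum_by(wbb, k + 1)
    if (k > 1) {
      H[k, k - 1] <- H[k - 1, k] <- sum_by(wab, k)
    }
    if (p) {
      hk <- -(colSums(X[y == k, , drop = FALSE] *
                        (waa + wab)[y == k]) +
              colSums(X[y == k + 1, , drop = FALSE] *
                        (wbb + wab)[y == k + 1]))
      H[k, q + seq_len(p)] <- H[q + seq_len(p), k] <- hk
    }
  }
  if (p) {
    grad[q + seq_len(p)] <- -colSums(X * (ra - rb))
    H[q + seq_len(p), q + seq_len(p)] <-
      crossprod(X, X * (waa + wbb + 2 * wab))
  }
  list(ll = sum(log(P)), grad = grad, hess = H)
}

# Newton fit with step-halving; convergence at gradient sup-norm < tol.
clm_newton <- function(y, X, K, tol = 1e-8, max_iter = 100) {
  q <- K - 1
  p <- ncol(X)
  counts <- tabulate(y, K)
  theta0 <- qlogis(pmin(pmax(cumsum(counts)[seq_len(q)] / length(y),
                             1e-6), 1 - 1e-6))
  psi <- c(theta0, rep(0, p))
  d <- clm_derivs(psi, y, X, K)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (max(abs(d$grad)) < tol) {
      converged <- TRUE
      break
    }
    delta <- tryCatch(-solve(d$hess, d$grad), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      psi_new <- psi + step * delta
      ok <- all(is.finite(psi_new)) &&
        !is.unsorted(psi_new[seq_len(q)], strictly = TRUE)
      if (ok) {
        d_new <- clm_derivs(psi_new, y, X, K)
        ok <- is.finite(d_new$ll) && d_new$ll >= d$ll - 1e-12
      }
      if (ok || step < 1e-10) break
      step <- step / 2
    }
    if (step < 1e-10) break
    psi <- psi_new
    d <- d_new
  }
  list(psi = psi, derivs = d, converged = converged, iter = iter)
}

#' Fit a proportional-odds (cumulative-logit) regression
#'
#' Maximum-likelihood fit of `logit P(y <= k) = theta_k - x'beta` by Newton
#' iteration with step-halving, with standard errors from the observed
#' information. A positive coefficient means higher odds of a higher
#' response category, so `exp(beta)` is reported as the odds ratio in
#' [tidy()].
#'
#' @param data A data frame.
#' @param formula Model formula; the response must be an ordered factor or
#'   integer-coded ordinal outcome with at least two observed levels. The
#'   intercept is absorbed into the thresholds.
#' @param tol Convergence tolerance on the gradient sup-norm.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `pgx_clm`/`pgx_fit` with elements
#'   `coefficients`, `vcov`, `logLik`, `n`, `converged` and `flag`
#'   (`"ok"`, `"non_convergence"` or `"possible_separation"`).
#'   Non-convergence and separation are flagged, never raised.
#' @seealso [tidy.pgx_fit()], [fit_logistic()], [fit_random_intercept()]
#' @export
#' @examples
#' d <- data.frame(y = rep(1:3, c(10, 12, 8)), g = rep(0:1, 15))
#' fit <- fit_cumulative_logit(d, y ~ g)
#' tidy(fit)
fit_cumulative_logit <- function(data, formula, tol = 1e-8, max_iter = 100) {
  mf <- model.frame(formula, data, na.action = stats::na.omit)
  y_raw <- model.response(mf)
  y <- as.integer(if (is.factor(y_raw)) y_raw else factor(y_raw))
  K <- max(y)
  if (length(unique(y)) < 2) {
    abort("the ordinal response has fewer than 2 observed levels.")
  }
  X <- model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) && qr(X)$rank < ncol(X)) {
    abort("the design matrix is rank deficient.")
  }
  fit <- clm_newton(y, X, K, tol = tol, max_iter = max_iter)
  q <- K - 1
  lev <- levels(if (is.factor(y_raw)) y_raw else factor(y_raw))
  names(fit$psi) <- c(paste0(lev[-K], "|", lev[-1]), colnames(X))
  vc <- tryCatch(solve(-fit$derivs$hess), error = function(e) {
    matrix(NA_real_, length(fit$psi), length(fit$psi))
  })
  dimnames(vc) <- list(names(fit$psi), names(fit$psi))
  se <- sqrt(pmax(diag(vc), 0))
  flag <- if (!fit$converged) "non_convergence"
          else if (any(abs(fit$psi) > 15) || any(is.na(se)) || any(se > 50)) {
            "possible_separation"
          } else "ok"
  structure(
    list(
      coefficients = fit$psi, vcov = vc, logLik = fit$derivs$ll,
      n = length(y), n_levels = K, threshold_terms = names(fit$psi)[seq_len(q)],
      converged = fit$converged, flag = flag, iter = fit$iter,
      model = "cumulative_logit", formula = formula
    ),
    class = c("pgx_clm", "pgx_fit")
  )
}
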