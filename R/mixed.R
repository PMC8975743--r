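# Random-intercept models by adaptive Gauss-Hermite quadrature.
#
# The marginal likelihood of participant i with records j is
#   L_i = \int phi(u; 0, sigma^2) prod_j p_ij(u) du,
# approximated by recentering the Gauss-Hermite rule at the per-participant
# posterior mode with scale from the curvature there (inner Newton step,
# vectorised across participants), then summing over the nodes on the log
# scale. Both logistic and cumulative-logit record likelihoods share this
# machinery. The analytic parameter gradient is computed at the recentred
# nodes (the dependence of the adaptive centre and scale on the parameters
# contributes only at the order of the quadrature error and is omitted).

log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

# record-level log-likelihood and derivatives wrt the linear predictor;
# dlogis/plogis handle the infinite outer-category bounds (density 0)
family_funs <- function(family, theta = NULL) {
  if (family == "binomial") {
    list(
      ll = function(lp, y) y * lp - log1pexp(lp),
      d12 = function(lp, y) {
        p <- plogis(lp)
        list(d1 = y - p, d2 = -p * (1 - p))
      },
      # gradient pieces at fixed lp: d1 plus (for ordinal) threshold terms
      dtheta = NULL
    )
  } else {
    up <- c(theta, Inf)
    lo <- c(-Inf, theta)
    parts <- function(lp, y) {
      a <- up[y] - lp; b <- lo[y] - lp
      Fa <- plogis(a); Fb <- plogis(b)
      P <- pmax(Fa - Fb, 1e-300)
      ga <- dlogis(a); gb <- dlogis(b)
      ga[!is.finite(a)] <- 0
      gb[!is.finite(b)] <- 0
      list(P = P, Fa = Fa, Fb = Fb, ga = ga, gb = gb)
    }
    list(
      ll = function(lp, y) {
        pr <- parts(lp, y)
        log(pr$P)
      },
      d12 = function(lp, y) {
        pr <- parts(lp, y)
        ha <- pr$ga * (1 - 2 * pr$Fa)
        hb <- pr$gb * (1 - 2 * pr$Fb)
        d1 <- (pr$gb - pr$ga) / pr$P
        list(d1 = d1, d2 = (ha - hb) / pr$P - d1^2)
      },
      dtheta = function(lp, y, n_theta) {
        pr <- parts(lp, y)
        ra <- pr$ga / pr$P
        rb <- pr$gb / pr$P
        list(ra = ra, rb = rb, n_theta = n_theta)
      }
    )
  }
}

# Adaptive Gauss-Hermite marginal log-likelihood (and, optionally, its
# analytic gradient wrt c(theta, beta, log sigma)). `idx` maps records to
# participants 1..m; `eta0` = X beta per record. The participant modes are
# attached as attribute "u"; with `grad = TRUE` the gradient is attached as
# attribute "gradient".
aghq_loglik <- function(y, eta0, idx, m, sigma, family = "binomial",
                        theta = NULL, nodes = 15, u_start = NULL,
                        grad = FALSE, X = NULL) {
  fam <- family_funs(family, theta = theta)
  gh <- statmod::gauss.quad(nodes, kind = "hermite")
  u <- u_start %||% numeric(m)
  inv_var <- 1 / sigma^2
  hess <- rep(-inv_var, m)
  for (it in seq_len(30)) {
    d <- fam$d12(eta0 + u[idx], y)
    g <- drop(rowsum(d$d1, idx)) - u * inv_var
    hess <- drop(rowsum(d$d2, idx)) - inv_var
    if (max(abs(g)) < 1e-8) break
    u <- u + pmin(pmax(-g / hess, -10), 10)
  }
  s <- 1 / sqrt(-hess)
  root2 <- sqrt(2)
  logM <- matrix(0, m, nodes)
  lp_cache <- if (grad) vector("list", nodes)
  uq_cache <- if (grad) vector("list", nodes)
  for (q in seq_len(nodes)) {
    uq <- u + root2 * s * gh$nodes[q]
    lp <- eta0 + uq[idx]
    hq <- drop(rowsum(fam$ll(lp, y), idx)) +
      stats::dnorm(uq, 0, sigma, log = TRUE)
    logM[, q] <- log(gh$weights[q]) + gh$nodes[q]^2 + hq
    if (grad) {
      lp_cache[[q]] <- lp
      uq_cache[[q]] <- uq
    }
  }
  row_max <- apply(logM, 1, max)
  w_post <- exp(logM - row_max)
  denom <- rowSums(w_post)
  out <- sum(log(root2 * s) + row_max + log(denom))
  attr(out, "u") <- u
  if (grad) {
    w_post <- w_post / denom
    n_theta <- length(theta %||% numeric(0))
    p <- if (is.null(X)) 0L else ncol(X)
    gr <- numeric(n_theta + p + 1)
    for (q in seq_len(nodes)) {
      wq <- w_post[, q]
      wrec <- wq[idx]
      lp <- lp_cache[[q]]
      d1 <- fam$d12(lp, y)$d1
      if (n_theta) {
        dt <- fam$dtheta(lp, y, n_theta)
        for (k in seq_len(n_theta)) {
          gr[k] <- gr[k] + sum(wrec[y == k] * dt$ra[y == k]) -
            sum(wrec[y == k + 1] * dt$rb[y == k + 1])
        }
      }
      if (p) {
        gr[n_theta + seq_len(p)] <- gr[n_theta + seq_len(p)] +
          colSums(X * (d1 * wrec))
      }
      # d/dlogsigma of log phi(u; 0, sigma^2) = u^2/sigma^2 - 1
      gr[n_theta + p + 1] <- gr[n_theta + p + 1] +
        sum(wq * (uq_cache[[q]]^2 * inv_var - 1))
    }
    attr(out, "gradient") <- gr
  }
  out
}

#' Fit a participant-level random-intercept model
#'
#' Maximum-likelihood fit of a logistic or cumulative-logit (proportional
#' odds) regression with a participant-level random intercept, integrating
#' the marginal likelihood by adaptive Gauss-Hermite quadrature (default 15
#' nodes). Used for analyses pooling repeated drug records per participant.
#'
#' @param data A data frame in long format (one row per record).
#' @param formula Model formula for the fixed effects; for
#'   `family = "cumulative"` the intercept is absorbed into the thresholds.
#' @param id Name of the column identifying participants.
#' @param family `"binomial"` or `"cumulative"`.
#' @param nodes Number of quadrature nodes.
#' @return An object of class `pgx_mixed`/`pgx_fit` with elements
#'   `coefficients` (thresholds first for the cumulative family), `sigma`
#'   (random-intercept SD), `sigma_se`, `vcov`, `logLik`, `n` (records),
#'   `n_groups`, `converged`, `flag`. If no participant has two or more
#'   records the fixed-effect model is returned with `sigma = 0` and flag
#'   `"no_repeated_measures"`.
#' @export
#' @examples
#' d <- data.frame(
#'   pid = rep(1:30, each = 2),
#'   y = rbinom(60, 1, 0.5),
#'   x = rnorm(60)
#' )
#' fit <- fit_random_intercept(d, y ~ x, id = "pid", family = "binomial")
#' glance(fit)
fit_random_intercept <- function(data, formula, id,
                                 family = c("binomial", "cumulative"),
                                 nodes = 15) {
  family <- match.arg(family)
  if (!id %in% names(data)) abort(sprintf("id column '%s' not found.", id))
  vars <- unique(c(all.vars(formula), id))
  data <- data[complete.cases(data[vars]), , drop = FALSE]
  mf <- model.frame(formula, data, na.action = NULL)
  y_raw <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (family == "cumulative") {
    y <- as.integer(if (is.factor(y_raw)) y_raw else factor(y_raw))
    K <- max(y)
    lev <- levels(if (is.factor(y_raw)) y_raw else factor(y_raw))
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else {
    y <- if (is.factor(y_raw)) as.integer(y_raw) - 1L else as.integer(y_raw)
    if (!all(y %in% c(0, 1))) abort("the response must be binary (0/1).")
    K <- 2L
  }
  if (ncol(X) && qr(X)$rank < ncol(X)) {
    abort("the design matrix is rank deficient.")
  }
  ids <- data[[id]]
  idx <- match(ids, unique(ids))
  m <- max(idx)

  fixed <- if (family == "cumulative") {
    fit_cumulative_logit(data, formula)
  } else {
    fit_logistic(data, formula)
  }
  if (max(tabulate(idx)) < 2) {
    fixed$sigma <- 0
    fixed$sigma_se <- NA_real_
    fixed$n_groups <- m
    fixed$nodes <- nodes
    fixed$family <- family
    fixed$flag <- "no_repeated_measures"
    fixed$model <- paste0("random_intercept_", family)
    class(fixed) <- c("pgx_mixed", "pgx_fit")
    return(fixed)
  }

  q <- if (family == "cumulative") K - 1L else 0L
  p <- ncol(X)
  u_warm <- NULL
  eval_aghq <- function(par, grad) {
    theta <- if (q) par[seq_len(q)] else NULL
    if (q && is.unsorted(theta, strictly = TRUE)) return(NULL)
    beta <- par[q + seq_len(p)]
    sigma <- exp(par[q + p + 1])
    eta0 <- if (p) drop(X %*% beta) else numeric(length(y))
    ll <- aghq_loglik(y, eta0, idx, m, sigma, family = family,
                      theta = theta, nodes = nodes, u_start = u_warm,
                      grad = grad, X = X)
    u_warm <<- attr(ll, "u")
    ll
  }
  negll <- function(par) {
    ll <- eval_aghq(par, grad = FALSE)
    if (is.null(ll)) return(1e10)
    -as.numeric(ll)
  }
  neggrad <- function(par) {
    ll <- eval_aghq(par, grad = TRUE)
    if (is.null(ll)) return(rep(0, length(par)))
    -attr(ll, "gradient")
  }
  start <- c(fixed$coefficients, log_sigma = 0)
  start[is.na(start)] <- 0
  opt <- nlminb(start, negll, gradient = neggrad,
                lower = c(rep(-Inf, q + p), -7),
                upper = c(rep(Inf, q + p), 3),
                control = list(iter.max = 500, eval.max = 2000))
  par <- opt$par
  H <- tryCatch(stats::optimHess(par, negll, gr = neggrad),
                error = function(e) NULL)
  np <- q + p + 1
  vc_all <- if (!is.null(H)) {
    tryCatch(solve(H), error = function(e) matrix(NA_real_, np, np))
  } else {
    matrix(NA_real_, np, np)
  }
  coefs <- par[seq_len(q + p)]
  names(coefs) <- c(if (q) paste0(lev[-K], "|", lev[-1]), colnames(X))
  vc <- vc_all[seq_len(q + p), seq_len(q + p), drop = FALSE]
  dimnames(vc) <- list(names(coefs), names(coefs))
  sigma <- unname(exp(par[np]))
  sigma_se <- unname(sigma * sqrt(vc_all[np, np])) # delta method on log sigma
  se <- sqrt(pmax(diag(vc), 0))
  flag <- if (opt$convergence != 0 && max(abs(neggrad(par))) > 1e-3) {
    "non_convergence"
  } else if (any(abs(coefs) > 15) || any(is.na(se)) || any(se > 50)) {
    "possible_separation"
  } else "ok"
  structure(
    list(
      coefficients = coefs, vcov = vc, sigma = sigma, sigma_se = sigma_se,
      logLik = -opt$objective, n = length(y), n_groups = m,
      n_levels = if (q) K else NULL,
      threshold_terms = if (q) names(coefs)[seq_len(q)] else character(0),
      converged = flag != "non_convergence", flag = flag, nodes = nodes,
      family = family, model = paste0("random_intercept_", family),
      formula = formula
    ),
    class = c("pgx_mixed", "pgx_fit")
  )
}
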