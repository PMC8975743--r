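# small deterministic fixture: 5 participants x 2 records
mixed_fixture <- function() {
  list(
    y_bin = c(1L, 0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 0L),
    y_ord = c(2L, 1L, 3L, 2L, 1L, 3L, 3L, 2L, 1L, 2L),
    x = c(0.5, -1.2, 0.3, 0.9, -0.4, 1.6, -0.8, 0.1, -1.1, 0.7),
    idx = rep(1:5, each = 2)
  )
}

test_that("the quadrature marginal likelihood matches brute-force integration", {
  fx <- mixed_fixture()
  beta <- c(-0.4, 0.7)
  eta0 <- beta[1] + beta[2] * fx$x
  sigma <- 0.8
  ours <- as.numeric(ssripgx:::aghq_loglik(
    fx$y_bin, eta0, fx$idx, 5, sigma, family = "binomial"
  ))
  oracle <- oracle_mixed_loglik(fx$y_bin, eta0, fx$idx, sigma, "binomial")
  expect_equal(ours, oracle, tolerance = 1e-5)

  theta <- c(-0.5, 0.9)
  eta0c <- 0.7 * fx$x
  ours_c <- as.numeric(ssripgx:::aghq_loglik(
    fx$y_ord, eta0c, fx$idx, 5, sigma, family = "cumulative", theta = theta
  ))
  oracle_c <- oracle_mixed_loglik(fx$y_ord, eta0c, fx$idx, sigma,
                                  "cumulative", theta = theta)
  expect_equal(ours_c, oracle_c, tolerance = 1e-5)
})

test_that("the analytic gradient matches finite differences", {
  fx <- mixed_fixture()
  X <- cbind(1, fx$x)
  par_ll <- function(par) {
    as.numeric(ssripgx:::aghq_loglik(
      fx$y_bin, drop(X %*% par[1:2]), fx$idx, 5, exp(par[3]),
      family = "binomial"
    ))
  }
  par <- c(-0.3, 0.5, log(0.9))
  got <- attr(ssripgx:::aghq_loglik(
    fx$y_bin, drop(X %*% par[1:2]), fx$idx, 5, exp(par[3]),
    family = "binomial", grad = TRUE, X = X
  ), "gradient")
  fd <- vapply(1:3, function(j) {
    h <- 1e-6
    e <- numeric(3); e[j] <- h
    (par_ll(par + e) - par_ll(par - e)) / (2 * h)
  }, numeric(1))
  expect_equal(got, fd, tolerance = 1e-4)
})

test_that("vanishing random-intercept variance recovers the fixed model", {
  fx <- mixed_fixture()
  d <- data.frame(y = fx$y_bin, x = fx$x, pid = fx$idx)
  fixed <- fit_logistic(d, y ~ x)
  eta0 <- fixed$coefficients[1] + fixed$coefficients[2] * fx$x
  near_zero <- as.numeric(ssripgx:::aghq_loglik(
    fx$y_bin, eta0, fx$idx, 5, 1e-3, family = "binomial"
  ))
  expect_equal(near_zero, fixed$logLik, tolerance = 1e-3)
})

test_that("estimates agree with an independent AGHQ implementation", {
  skip_if_not_installed("lme4")
  withr::with_seed(2, {
    m <- 300; k <- 3
    d <- data.frame(pid = rep(1:m, each = k), x = rnorm(m * k))
    u <- rnorm(m, 0, 1)
    d$y <- rbinom(m * k, 1, plogis(-0.3 + 0.6 * d$x + u[d$pid]))
  })
  ours <- fit_random_intercept(d, y ~ x, id = "pid", family = "binomial")
  ref <- lme4::glmer(y ~ x + (1 | pid), data = d, family = binomial,
                     nAGQ = 15)
  expect_equal(unname(ours$coefficients), unname(lme4::fixef(ref)),
               tolerance = 1e-3)
  expect_equal(ours$sigma, sqrt(unlist(lme4::VarCorr(ref)))[[1]],
               tolerance = 1e-3)
  expect_equal(ours$logLik, as.numeric(logLik(ref)), tolerance = 1e-5)
})

test_that("quadrature estimates are stable to node-count doubling", {
  withr::with_seed(44, {
    m <- 150
    d <- data.frame(pid = rep(1:m, each = 2), x = rnorm(2 * m))
    u <- rnorm(m, 0, 1)
    p <- cumulative_logit_probs(c(-0.4, 0.9), 0.5 * d$x + u[d$pid])
    d$y <- apply(p, 1, function(pr) sample(1:3, 1, prob = pr))
  })
  f15 <- fit_random_intercept(d, y ~ x, id = "pid", family = "cumulative",
                              nodes = 15)
  f31 <- fit_random_intercept(d, y ~ x, id = "pid", family = "cumulative",
                              nodes = 31)
  expect_equal(f15$coefficients, f31$coefficients, tolerance = 1e-4)
  expect_equal(f15$sigma, f31$sigma, tolerance = 1e-4)
})

test_that("the random-intercept SD is recovered within sampling error", {
  withr::with_seed(45, {
    m <- 800
    d <- data.frame(pid = rep(1:m, each = 2), x = rnorm(2 * m))
    u <- rnorm(m, 0, 1)
    d$y <- rbinom(2 * m, 1, plogis(0.2 + 0.5 * d$x + u[d$pid]))
  })
  fit <- fit_random_intercept(d, y ~ x, id = "pid", family = "binomial")
  expect_lt(abs(fit$sigma - 1) / fit$sigma_se, 3)
})

test_that("single-record data reduce to the fixed model with sigma zero", {
  d <- data.frame(pid = 1:40, y = rbinom(40, 1, 0.5), x = rnorm(40))
  fit <- fit_random_intercept(d, y ~ x, id = "pid", family = "binomial")
  expect_identical(fit$sigma, 0)
  expect_identical(fit$flag, "no_repeated_measures")
  fixed <- fit_logistic(d, y ~ x)
  expect_equal(fit$coefficients, fixed$coefficients)
})
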