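#' Configuration for the simulation-based power analysis
#'
#' Defines the population and procedure for estimating power to detect
#' metaboliser-status effects on 3-level ordinal efficacy. Defaults mirror
#' the study conditions: observed group sizes (199 poor, 2460 intermediate,
#' 3869 normal, 2555 rapid, 448 ultrarapid), proportional-odds thresholds
#' matching the normal-metaboliser efficacy marginal (35%/37%/28%), a
#' log-odds effect grid corresponding to odds ratios of about
#' 1.05, 1.1, 1.16, 1.22, 1.5, 1.65 and 1.82, nominal alpha 0.05, and 1000
#' replicates per grid point.
#'
#' @param group_sizes Named counts per metaboliser status (must include
#'   `normal`).
#' @param thresholds Two increasing cumulative-logit thresholds for the
#'   baseline (normal-metaboliser) efficacy distribution.
#' @param effect_grid Strictly increasing log-odds effect sizes.
#' @param statuses Statuses whose effects are examined (one at a time, all
#'   other groups at zero effect); defaults to every non-reference group in
#'   `group_sizes`.
#' @param alpha Nominal significance level of the per-replicate test.
#' @param n_replicates Simulation replicates per (status, effect) cell.
#' @param beta_age,beta_sex Covariate effects entering both the generating
#'   model and the fitted model.
#' @param age_mean,age_sd,age_range,prop_female Covariate population, as in
#'   [cohort_config()].
#' @param seed Optional seed making [estimate_power()] deterministic.
#' @return A validated list of class `power_config`.
#' @export
power_config <- function(
    group_sizes = c(poor = 199, intermediate = 2460, normal = 3869,
                    rapid = 2555, ultrarapid = 448),
    thresholds = qlogis(c(0.35, 0.72)),
    effect_grid = c(0.05, 0.10, 0.15, 0.20, 0.405, 0.50, 0.60),
    statuses = NULL,
    alpha = 0.05,
    n_replicates = 1000,
    beta_age = 0, beta_sex = 0,
    age_mean = 42.8, age_sd = 15.1, age_range = c(18, 90),
    prop_female = 0.76,
    seed = NULL) {
  if (!"normal" %in% names(group_sizes)) {
    abort("`group_sizes` must include the reference group `normal`.")
  }
  if (any(group_sizes < 1)) abort("all group sizes must be at least 1.")
  if (length(thresholds) != 2 || diff(thresholds) <= 0) {
    abort("`thresholds` must be two strictly increasing values.")
  }
  if (is.unsorted(effect_grid, strictly = TRUE)) {
    abort("`effect_grid` must be strictly increasing.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  statuses <- statuses %||%
    intersect(c("poor", "intermediate", "rapid", "ultrarapid"),
              names(group_sizes))
  if (!length(statuses) ||
      !all(statuses %in% setdiff(names(group_sizes), "normal"))) {
    abort("`statuses` must be non-reference groups present in `group_sizes`.")
  }
  structure(
    list(group_sizes = group_sizes, thresholds = thresholds,
         effect_grid = effect_grid, statuses = statuses, alpha = alpha,
         n_replicates = n_replicates, beta_age = beta_age,
         beta_sex = beta_sex, age_mean = age_mean, age_sd = age_sd,
         age_range = age_range, prop_female = prop_female, seed = seed),
    class = "power_config"
  )
}

# fixed status composition + freshly drawn covariates for one replicate
power_population <- function(cfg) {
  status <- factor(
    rep(names(cfg$group_sizes), times = cfg$group_sizes),
    levels = c("normal", setdiff(names(cfg$group_sizes), "normal"))
  )
  demo <- sample_demographics(cohort_config(
    n = length(status), age_mean = cfg$age_mean, age_sd = cfg$age_sd,
    age_range = cfg$age_range, prop_female = cfg$prop_female
  ))
  tibble(status = status, age = demo$age,
         sex = factor(demo$sex, levels = c("male", "female")))
}

#' Per-observation cumulative-logit linear predictors for the power model
#'
#' Builds the two threshold equations `eta_k = theta_k - (effect *
#' 1[status == target] + beta_age * age + beta_sex * 1[female])`; the
#' inverse logits of `eta_1` and `eta_2` are the cumulative probabilities
#' P(y <= 1) and P(y <= 2) used to draw simulated efficacy scores.
#'
#' @param cfg A [power_config()].
#' @param effect Log-odds effect of the target status.
#' @param target_status Non-reference status carrying the effect.
#' @param population Data frame with `status`, `age`, `sex`; defaults to a
#'   fresh draw from the configured population.
#' @return A tibble `eta1`, `eta2` (one row per observation).
#' @export
power_linear_predictors <- function(cfg, effect, target_status,
                                    population = power_population(cfg)) {
  eta <- effect * (population$status == target_status) +
    cfg$beta_age * population$age +
    cfg$beta_sex * (population$sex == "female")
  tibble(eta1 = cfg$thresholds[1] - eta, eta2 = cfg$thresholds[2] - eta)
}

# one simulate-and-refit replicate; returns c(reject, converged)
power_rep <- function(cfg, effect, target_status) {
  pop <- power_population(cfg)
  lp <- power_linear_predictors(cfg, effect, target_status, pop)
  uu <- runif(nrow(pop))
  pop$y <- 1L + (uu > plogis(lp$eta1)) + (uu > plogis(lp$eta2))
  fit <- fit_cumulative_logit(pop, y ~ status + age + sex)
  p <- tidy(fit) |>
    dplyr::filter(.data$term == paste0("status", target_status)) |>
    dplyr::pull("p.value")
  c(reject = fit$converged && length(p) == 1 && p < cfg$alpha,
    converged = fit$converged)
}

#' Estimate power for ordinal efficacy by simulation
#'
#' For each (status, effect) cell, repeatedly simulates 3-level efficacy
#' scores from the proportional-odds model -- the target status carrying
#' the log-odds effect, all other groups at zero -- refits the
#' cumulative-logit regression with status, age and sex, and records the
#' fraction of replicates in which the target contrast is rejected at the
#' nominal alpha. Non-convergent replicates count as non-rejections (and
#' are tallied). The 80%-power effect threshold per status is obtained by
#' linear interpolation of power against effect.
#'
#' @param cfg A [power_config()].
#' @param statuses,effects Optional subsets of the configured statuses and
#'   effect grid.
#' @param n_replicates Override for the configured replicate count.
#' @param seed Override for the configured seed.
#' @param quiet Suppress per-cell progress messages.
#' @return A tibble of class `power_grid`: `status`, `effect`, `or`,
#'   `power`, `mc_se`, `n_replicates`, `n_nonconverged`, `n` (simulated
#'   sample size), with the per-status interpolated 80%-power thresholds in
#'   attribute `"thresholds"` (also a tibble).
#' @export
#' @examples
#' cfg <- power_config(
#'   group_sizes = c(normal = 150, poor = 150),
#'   statuses = "poor", effect_grid = c(0.2, 0.8), n_replicates = 20,
#'   seed = 1
#' )
#' estimate_power(cfg)
estimate_power <- function(cfg = power_config(), statuses = cfg$statuses,
                           effects = cfg$effect_grid,
                           n_replicates = cfg$n_replicates,
                           seed = cfg$seed, quiet = FALSE) {
  stopifnot(inherits(cfg, "power_config"))
  run <- function() {
    grid <- tidyr::expand_grid(status = statuses, effect = effects)
    cells <- purrr::pmap(grid, function(status, effect) {
      reps <- vapply(seq_len(n_replicates), function(i) {
        power_rep(cfg, effect, status)
      }, numeric(2))
      pow <- mean(reps["reject", ])
      if (!quiet) {
        inform(sprintf("power[%s, effect=%.3f] = %.3f (%d reps)",
                       status, effect, pow, n_replicates))
      }
      tibble(
        status = status, effect = effect, or = exp(effect), power = pow,
        mc_se = sqrt(pow * (1 - pow) / n_replicates),
        n_replicates = n_replicates,
        n_nonconverged = sum(1 - reps["converged", ]),
        n = sum(cfg$group_sizes)
      )
    })
    out <- purrr::list_rbind(cells)
    thr <- out |>
      dplyr::group_by(.data$status) |>
      dplyr::summarise(
        threshold_80 = interpolate_threshold(.data$effect, .data$power, 0.8),
        .groups = "drop"
      )
    attr(out, "thresholds") <- thr
    class(out) <- c("power_grid", class(out))
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# first upward crossing of `target` along the effect grid, linearly
# interpolated; NA when never reached, grid minimum when always above
interpolate_threshold <- function(effect, power, target = 0.8) {
  ord <- order(effect)
  effect <- effect[ord]
  power <- power[ord]
  if (all(power < target)) return(NA_real_)
  i <- which(power >= target)[1]
  if (i == 1) return(effect[1])
  effect[i - 1] + (target - power[i - 1]) *
    (effect[i] - effect[i - 1]) / (power[i] - power[i - 1])
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf("<power_grid> %d cells, %d replicates each\n",
              nrow(x), x$n_replicates[1]))
  NextMethod()
  thr <- attr(x, "thresholds")
  if (!is.null(thr)) {
    cat("80%-power effect thresholds (log-odds):\n")
    print(as.data.frame(thr), row.names = FALSE)
  }
  invisible(x)
}
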