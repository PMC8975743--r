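#' Run the primary metaboliser-status association battery
#'
#' For each outcome family, fits per-drug fixed-effect models and a pooled
#' random-intercept model across drugs, extracting the four metaboliser
#' contrasts (poor, intermediate, rapid, ultrarapid vs normal) with
#' age/sex adjustment, and annotates each family with its Bonferroni
#' threshold. Families:
#'
#' * `efficacy` - 3-level ordinal efficacy, proportional-odds models.
#' * `discontinued` - stopping due to side effects (inverse tolerability),
#'   logistic models.
#' * `any_side_effect` - logistic models.
#' * `n_side_effects` - number of reported specific side effects, binned
#'   0 / 1-2 / 3+ and modelled with the same proportional-odds machinery.
#' * `side_effect_scan` - one logistic model per (drug, specific side
#'   effect); this family uses `alpha / scan_n_tests`.
#'
#' The first four families each compare 4 statuses against normal, so their
#' threshold is `alpha / 4`; the scan threshold defaults to `alpha / 300`
#' (25 side-effect outcomes x 3 drugs x 4 statuses).
#'
#' @param records Long outcome table (one row per participant-drug record)
#'   with `sample_id`, `drug`, `efficacy`, `discontinued`,
#'   `any_side_effect` and optional specific side-effect binaries; or a
#'   `pgx_cohort`, in which case `participants` is taken from it.
#' @param participants Table with `sample_id`, `age`, `sex`, `status`.
#'   Participants with missing or indeterminate status are excluded (with a
#'   reported count).
#' @param families Which families to run; defaults to all whose columns are
#'   present (the side-effect families are skipped when no specific
#'   side-effect columns exist). Requesting a family whose outcome column
#'   is missing is an error.
#' @param pooled Fit the pooled random-intercept models (set `FALSE` to run
#'   only the per-drug fixed models).
#' @param alpha Family-wise error rate.
#' @param scan_n_tests Bonferroni divisor for the side-effect scan.
#' @param nodes Quadrature nodes for the pooled models.
#' @param side_effect_bins Upper edges of the lower bins for the
#'   number-of-side-effects outcome; the default `c(0, 2)` gives bins
#'   0, 1-2 and 3+.
#' @param quiet Suppress progress/exclusion messages.
#' @return A tibble of class `pgx_results`: one row per (family, outcome,
#'   scope, contrast) with estimate, SE, OR, Wald 95% CI, p-value,
#'   convergence flag, the family threshold, and `nominal` / `significant`
#'   indicators. Exclusion counts are attached as attribute `"exclusions"`.
#' @export
run_primary_analysis <- function(records, participants = NULL,
                                 families = NULL, pooled = TRUE,
                                 alpha = 0.05, scan_n_tests = 300,
                                 nodes = 15, side_effect_bins = c(0, 2),
                                 quiet = FALSE) {
  if (inherits(records, "pgx_cohort")) {
    participants <- records$participants
    records <- records$records
  }
  if (is.null(participants)) abort("`participants` is required.")
  for (col in c("sample_id", "age", "sex", "status")) {
    if (!col %in% names(participants)) {
      abort(paste0("`participants` lacks column: ", col))
    }
  }
  if (!all(c("sample_id", "drug") %in% names(records))) {
    abort("`records` must have `sample_id` and `drug` columns.")
  }

  se_cols <- setdiff(
    names(records),
    c("sample_id", "drug", "efficacy", "discontinued", "any_side_effect")
  )
  all_families <- c("efficacy", "discontinued", "any_side_effect",
                    "n_side_effects", "side_effect_scan")
  if (is.null(families)) {
    families <- if (length(se_cols)) all_families else all_families[1:3]
  }
  families <- match.arg(families, all_families, several.ok = TRUE)
  for (fam in intersect(families, c("efficacy", "discontinued",
                                    "any_side_effect"))) {
    if (!fam %in% names(records)) {
      abort(paste0("`records` lacks required outcome column: ", fam))
    }
  }
  if (any(c("n_side_effects", "side_effect_scan") %in% families) &&
      !length(se_cols)) {
    abort("no specific side-effect columns found for the side-effect families.")
  }

  pp <- dplyr::mutate(
    participants,
    status = factor(as.character(.data$status),
                    levels = c("normal", "poor", "intermediate", "rapid",
                               "ultrarapid")),
    sex = factor(.data$sex, levels = c("male", "female"))
  )
  n_excluded <- sum(is.na(pp$status))
  if (!quiet && n_excluded) {
    inform(sprintf(
      "excluding %d participant(s) with missing/indeterminate status", n_excluded
    ))
  }
  pp <- pp[!is.na(pp$status), c("sample_id", "age", "sex", "status")]
  dat <- dplyr::inner_join(records, pp, by = "sample_id")
  drugs <- unique(dat$drug)
  if (length(se_cols)) {
    n_se <- rowSums(dat[se_cols])
    dat$.n_side_effects <- cut(n_se, c(-Inf, side_effect_bins, Inf),
                               labels = FALSE)
  }

  contrast_rows <- function(fit, family, outcome, scope, threshold) {
    tidy(fit) |>
      dplyr::filter(grepl("^status", .data$term)) |>
      dplyr::mutate(
        family = family, outcome = outcome, scope = scope,
        contrast = sub("^status", "", .data$term),
        n = fit$n, converged = fit$converged, flag = fit$flag,
        threshold = threshold,
        nominal = .data$p.value < alpha,
        significant = .data$p.value < threshold
      ) |>
      dplyr::select("family", "outcome", "scope", "contrast", "estimate",
                    "std.error", "or", "conf.low", "conf.high", "p.value",
                    "n", "converged", "flag", "threshold", "nominal",
                    "significant")
  }

  # drop status/sex levels unobserved in a model's subset so small strata
  # cannot make the design rank deficient; absent contrasts are absent rows
  drop_unused <- function(d) {
    d$status <- droplevels(d$status)
    d$sex <- droplevels(d$sex)
    d
  }

  fit_family <- function(outcome_col, family, kind) {
    threshold <- bonferroni_threshold(alpha, 4)
    fml_terms <- "status + age + sex"
    fixed_fml <- stats::as.formula(paste(outcome_col, "~", fml_terms))
    out <- purrr::map(drugs, function(d) {
      fit <- if (kind == "cumulative") {
        fit_cumulative_logit(drop_unused(dat[dat$drug == d, ]), fixed_fml)
      } else {
        fit_logistic(drop_unused(dat[dat$drug == d, ]), fixed_fml)
      }
      contrast_rows(fit, family, family, d, threshold)
    })
    if (pooled) {
      pooled_terms <- if (length(drugs) > 1) {
        paste(fml_terms, "+ drug")
      } else {
        fml_terms
      }
      pfit <- fit_random_intercept(
        drop_unused(dat),
        stats::as.formula(paste(outcome_col, "~", pooled_terms)),
        id = "sample_id",
        family = if (kind == "cumulative") "cumulative" else "binomial",
        nodes = nodes
      )
      out <- c(out, list(contrast_rows(pfit, family, family, "pooled",
                                       threshold)))
    }
    purrr::list_rbind(out)
  }

  results <- list()
  if ("efficacy" %in% families) {
    results$efficacy <- fit_family("efficacy", "efficacy", "cumulative")
  }
  if ("discontinued" %in% families) {
    results$discontinued <- fit_family("discontinued", "discontinued",
                                       "binomial")
  }
  if ("any_side_effect" %in% families) {
    results$any_side_effect <- fit_family("any_side_effect",
                                          "any_side_effect", "binomial")
  }
  if ("n_side_effects" %in% families) {
    results$n_side_effects <- fit_family(".n_side_effects",
                                         "n_side_effects", "cumulative")
  }
  if ("side_effect_scan" %in% families) {
    threshold <- bonferroni_threshold(alpha, scan_n_tests)
    results$scan <- purrr::list_rbind(purrr::map(se_cols, function(se) {
      purrr::list_rbind(purrr::map(drugs, function(d) {
        fit <- fit_logistic(
          drop_unused(dat[dat$drug == d, ]),
          stats::as.formula(paste(se, "~ status + age + sex"))
        )
        contrast_rows(fit, "side_effect_scan", se, d, threshold)
      }))
    }))
  }
  out <- purrr::list_rbind(results)
  attr(out, "exclusions") <- c(missing_status = n_excluded)
  class(out) <- c("pgx_results", class(out))
  out
}
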