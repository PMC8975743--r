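#' Configuration for an end-to-end pipeline run
#'
#' @param cohort A [cohort_config()] for the simulate stage, or `NULL` when
#'   analysing existing files.
#' @param power A [power_config()] for the power stage, or `NULL` to skip
#'   it.
#' @param stages Stages to run, in order, from `"simulate"`, `"call"`,
#'   `"associate"`, `"power"`.
#' @param vcf,phenotypes,participants Input paths used when `"simulate"` is
#'   not among the stages.
#' @param dosage_tolerance Hard-call tolerance for the call stage.
#' @param alpha,scan_n_tests,pooled Passed to [run_primary_analysis()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            power = NULL,
                            stages = c("simulate", "call", "associate",
                                       "power"),
                            vcf = NULL, phenotypes = NULL,
                            participants = NULL,
                            dosage_tolerance = 0.1,
                            alpha = 0.05, scan_n_tests = 300,
                            pooled = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!"simulate" %in% stages) {
    missing_inputs <- c(vcf = is.null(vcf), phenotypes = is.null(phenotypes),
                        participants = is.null(participants))
    if (any(missing_inputs)) {
      abort(paste0(
        "with the simulate stage disabled, input path(s) must be given: ",
        paste(names(missing_inputs)[missing_inputs], collapse = ", ")
      ))
    }
  }
  structure(
    list(cohort = cohort, power = power, stages = stages, vcf = vcf,
         phenotypes = phenotypes, participants = participants,
         dosage_tolerance = dosage_tolerance, alpha = alpha,
         scan_n_tests = scan_n_tests, pooled = pooled),
    class = "pipeline_config"
  )
}

# documented sub-seed rule: stage i (1-based position in the canonical
# stage order) runs under seed + 1000 * i, so stages can be rerun alone
stage_seed <- function(seed, stage) {
  i <- match(stage, c("simulate", "call", "associate", "power"))
  as.integer(seed + 1000L * i)
}

#' Run the full pipeline
#'
#' Executes simulate -> call-metaboliser -> associate -> power (any subset,
#' in that order), writing all outputs and a JSON run manifest into
#' `out_dir`. Every source of randomness derives from `seed` through a
#' fixed per-stage rule, so identical config and seed reproduce identical
#' output tables. Attrition (missing genotypes, indeterminate diplotypes,
#' missing statuses at analysis) is logged and recorded in the manifest.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer master seed.
#' @param out_dir Output directory.
#' @param quiet Suppress progress logging.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_kv <- function(stage, ...) {
    if (!quiet) {
      kv <- c(...)
      inform(paste0("stage=", stage, " ",
                    paste(names(kv), kv, sep = "=", collapse = " ")))
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ssripgx")),
    config_hash = rlang::hash(unclass(config)),
    seed = seed,
    stage_seeds = setNames(
      lapply(config$stages, stage_seed, seed = seed), config$stages
    ),
    stages = config$stages,
    outputs = list(),
    exclusions = list(),
    n = list()
  )

  paths <- c(vcf = config$vcf, phenotypes = config$phenotypes,
             participants = config$participants)
  if ("simulate" %in% config$stages) {
    run_stage("simulate", {
      cfg <- config$cohort
      cfg$seed <- stage_seed(seed, "simulate")
      cohort <- simulate_cohort(cfg)
      paths <- write_cohort(cohort, file.path(out_dir, "data"))
      log_kv("simulate", n = cfg$n, records = nrow(cohort$records))
      manifest$n$simulated <- cfg$n
      manifest$outputs$data <- as.list(paths)
      paths <- paths
    })
  }

  statuses <- NULL
  if ("call" %in% config$stages) {
    run_stage("call", {
      statuses <- call_metabolizers(paths[["vcf"]],
                                     dosage_tolerance = config$dosage_tolerance,
                                     quiet = TRUE)
      excl <- attr(statuses, "exclusions")
      status_path <- file.path(out_dir, "statuses.tsv")
      readr::write_tsv(statuses, status_path)
      log_kv("call", n_total = nrow(statuses),
             n_called = sum(is.na(statuses$exclusion)),
             missing_genotype = excl[["missing_genotype"]],
             indeterminate = excl[["indeterminate_diplotype"]])
      manifest$outputs$statuses <- status_path
      manifest$exclusions$call <- as.list(excl)
      manifest$n$called <- sum(is.na(statuses$exclusion))
    })
  }

  results <- NULL
  if ("associate" %in% config$stages) {
    run_stage("associate", {
      records <- readr::read_tsv(paths[["phenotypes"]],
                                 show_col_types = FALSE)
      demo <- readr::read_tsv(paths[["participants"]],
                              show_col_types = FALSE)
      if (is.null(statuses)) {
        statuses <- call_metabolizers(paths[["vcf"]],
                                      dosage_tolerance = config$dosage_tolerance,
                                      quiet = TRUE)
      }
      pp <- dplyr::inner_join(demo[c("sample_id", "age", "sex")],
                              statuses[c("sample_id", "status")],
                              by = "sample_id")
      withr::with_seed(stage_seed(seed, "associate"), {
        results <- run_primary_analysis(
          records, pp, pooled = config$pooled, alpha = config$alpha,
          scan_n_tests = config$scan_n_tests, quiet = TRUE
        )
      })
      results_path <- file.path(out_dir, "results.tsv")
      readr::write_tsv(results, results_path)
      log_kv("associate", n_records = nrow(records),
             n_analysed = max(results$n),
             excluded_status = attr(results, "exclusions")[["missing_status"]])
      manifest$outputs$results <- results_path
      manifest$exclusions$associate <-
        as.list(attr(results, "exclusions"))
      manifest$n$analysed_records <- nrow(records)
    })
  }

  if ("power" %in% config$stages && !is.null(config$power)) {
    run_stage("power", {
      grid <- estimate_power(config$power, seed = stage_seed(seed, "power"),
                             quiet = TRUE)
      power_path <- file.path(out_dir, "power.tsv")
      readr::write_tsv(grid, power_path)
      thr_path <- file.path(out_dir, "power_thresholds.tsv")
      readr::write_tsv(attr(grid, "thresholds"), thr_path)
      log_kv("power", cells = nrow(grid),
             replicates = grid$n_replicates[1])
      manifest$outputs$power <- list(grid = power_path,
                                      thresholds = thr_path)
    })
  }

  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Render a text summary of association results
#'
#' Produces a compact markdown table per outcome family in the layout of a
#' forest-plot legend: one row per contrast and scope, showing
#' `OR [95% CI]` with `*` marking nominal significance (p < `alpha`) and
#' `**` significance after the family's multiple-testing correction.
#'
#' @param results A `pgx_results` tibble (or path to a results TSV).
#' @param alpha Nominal significance level for the `*` flag.
#' @return Invisibly, the report lines; they are also printed.
#' @export
report_results <- function(results, alpha = 0.05) {
  if (is.character(results)) {
    results <- readr::read_tsv(results, show_col_types = FALSE)
  }
  req <- c("family", "outcome", "scope", "contrast", "or", "conf.low",
           "conf.high", "p.value", "threshold")
  if (!all(req %in% names(results))) {
    abort(paste0("malformed results: missing column(s) ",
                 paste(setdiff(req, names(results)), collapse = ", ")))
  }
  fmt_row <- function(r) {
    flag <- if (r$p.value < r$threshold) "**"
            else if (r$p.value < alpha) "*"
            else ""
    sprintf("| %s | %s | %.2f [%.2f-%.2f] | %.3g%s |",
            r$scope, r$contrast, r$or, r$conf.low, r$conf.high,
            r$p.value, flag)
  }
  lines <- character(0)
  for (fam in unique(results$family)) {
    sub <- results[results$family == fam, ]
    lines <- c(lines, paste0("## ", fam), "",
               "| scope | contrast | OR [95% CI] | p |",
               "|---|---|---|---|")
    for (i in seq_len(nrow(sub))) {
      lines <- c(lines, fmt_row(sub[i, ]))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines,
             sprintf("`*` p < %.3g; `**` significant after correction.",
                     alpha))
  cat(lines, sep = "\n")
  invisible(lines)
}
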