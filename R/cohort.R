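#' Configuration for the synthetic SSRI cohort generator
#'
#' Bundles and validates all parameters of the cohort simulator. Defaults
#' emulate a large adult depression cohort: tier-1 CYP2C19
#' haplotype frequencies (*2 14%, *3 0.02%, *17 21.4%), age roughly
#' N(42.8, 15.1^2) truncated to adults, 76% female, and overlapping exposure
#' to sertraline, citalopram and escitalopram (about 69%/25%/6% of
#' participants taking one/two/three of the drugs). Outcome intercepts are
#' calibrated so that, with all effects zero, marginals match the observed
#' normal-metaboliser rows: per-drug 3-level efficacy splits, and
#' discontinuation / any-side-effect rates per drug.
#'
#' @param n Number of participants.
#' @param hap_freqs Named haplotype frequencies for `*2`, `*3`, `*17`; the
#'   `*1` frequency is the complement.
#' @param age_mean,age_sd,age_range Age distribution (years): normal,
#'   truncated to `age_range`.
#' @param prop_female Proportion of female participants.
#' @param drugs Drug names.
#' @param drug_weights Relative selection weights for each drug (defaults
#'   proportional to observed per-drug sample sizes).
#' @param n_drugs_dist Probabilities of taking exactly 1, 2 or 3 of the
#'   drugs; must sum to 1.
#' @param efficacy_thresholds Named list of two increasing cumulative-logit
#'   thresholds per drug (on the latent scale `logit P(y <= k) =
#'   theta_k - eta`).
#' @param discontinued_intercept,any_side_effect_intercept Named logit-scale
#'   baseline rates per drug for stopping due to side effects and for
#'   reporting any side effect.
#' @param status_betas Named list (`efficacy`, `discontinued`,
#'   `any_side_effect`, `side_effects`), each a named numeric of log-odds
#'   effects for `poor`, `intermediate`, `rapid`, `ultrarapid` relative to
#'   normal metabolisers. Defaults to all zero (a null cohort).
#' @param beta_age,beta_sex Covariate log-odds effects (age in years,
#'   uncentred; sex coded female = 1) shared across outcomes.
#' @param random_intercept_sd Standard deviation of the participant-level
#'   random intercept shared by all of a participant's records.
#' @param side_effect_names Names of the specific side-effect binaries.
#' @param side_effect_rate Baseline probability for each specific side
#'   effect (scalar or one value per name); set `side_effect_names = NULL`
#'   to skip simulating them.
#' @param seed Optional integer seed; when set, [simulate_cohort()] is fully
#'   deterministic.
#' @return A validated list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n = 200, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' cohort$records
cohort_config <- function(
    n = 9531,
    hap_freqs = c("*2" = 0.14, "*3" = 0.0002, "*17" = 0.214),
    age_mean = 42.8, age_sd = 15.1, age_range = c(18, 90),
    prop_female = 0.76,
    drugs = c("sertraline", "citalopram", "escitalopram"),
    drug_weights = c(sertraline = 5680, citalopram = 2503,
                     escitalopram = 4342) / 9531,
    n_drugs_dist = c(0.69, 0.25, 0.06),
    efficacy_thresholds = list(
      sertraline = qlogis(c(0.37, 0.73)),
      citalopram = qlogis(c(0.36, 0.75)),
      escitalopram = qlogis(c(0.32, 0.70))
    ),
    discontinued_intercept = c(sertraline = qlogis(0.46),
                               citalopram = qlogis(0.45),
                               escitalopram = qlogis(0.38)),
    any_side_effect_intercept = c(sertraline = qlogis(0.70),
                                  citalopram = qlogis(0.65),
                                  escitalopram = qlogis(0.71)),
    status_betas = NULL,
    beta_age = 0, beta_sex = 0,
    random_intercept_sd = 1,
    side_effect_names = default_side_effects(),
    side_effect_rate = 0.15,
    seed = NULL) {
  zero_betas <- c(poor = 0, intermediate = 0, rapid = 0, ultrarapid = 0)
  default_sb <- list(efficacy = zero_betas, discontinued = zero_betas,
                     any_side_effect = zero_betas, side_effects = zero_betas)
  status_betas <- utils::modifyList(default_sb, as.list(status_betas %||% list()))
  status_betas <- lapply(status_betas, function(b) {
    out <- zero_betas
    out[names(b)] <- b
    out
  })

  cfg <- list(
    n = n, hap_freqs = hap_freqs,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    prop_female = prop_female,
    drugs = drugs, drug_weights = drug_weights, n_drugs_dist = n_drugs_dist,
    efficacy_thresholds = efficacy_thresholds,
    discontinued_intercept = discontinued_intercept,
    any_side_effect_intercept = any_side_effect_intercept,
    status_betas = status_betas, beta_age = beta_age, beta_sex = beta_sex,
    random_intercept_sd = random_intercept_sd,
    side_effect_names = side_effect_names,
    side_effect_rate = side_effect_rate,
    seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
      abort("`n` must be a single non-negative integer.")
    }
    if (!all(c("*2", "*3", "*17") %in% names(hap_freqs))) {
      abort("`hap_freqs` must name *2, *3 and *17.")
    }
    if (any(hap_freqs < 0) || any(hap_freqs > 1) || sum(hap_freqs) > 1) {
      abort("haplotype frequencies must lie in [0, 1] and sum to at most 1 (the *1 frequency is the complement).")
    }
    if (abs(sum(n_drugs_dist) - 1) > 1e-8 || any(n_drugs_dist < 0)) {
      abort("`n_drugs_dist` must be non-negative and sum to 1.")
    }
    if (prop_female < 0 || prop_female > 1) abort("`prop_female` must be in [0, 1].")
    if (age_sd < 0) abort("`age_sd` must be non-negative.")
    if (random_intercept_sd < 0) abort("`random_intercept_sd` must be non-negative.")
    for (d in drugs) {
      th <- efficacy_thresholds[[d]]
      if (is.null(th) || length(th) != 2 || diff(th) <= 0) {
        abort(sprintf("`efficacy_thresholds` for %s must be two strictly increasing values.", d))
      }
    }
  })
  invisible(cfg)
}

#' @rdname cohort_config
#' @export
default_side_effects <- function() {
  c("weight_loss", "fatigue", "drowsiness", "nausea", "headache",
    "insomnia", "dizziness", "dry_mouth", "sweating", "tremor",
    "anxiety", "agitation", "weight_gain", "reduced_libido",
    "sexual_dysfunction", "diarrhoea", "constipation", "blurred_vision",
    "palpitations", "restlessness", "vivid_dreams", "bruxism",
    "irritability")
}

#' Draw CYP2C19 genotypes by random mating
#'
#' Each participant receives two independent haplotype draws from
#' \{*1, *2, *3, *17\} at the configured frequencies; alternate-allele
#' counts at the three defining variants follow from the pair. Under this
#' scheme a genotype never carries more than two variant alleles, so the
#' diplotype is always phase-resolvable.
#'
#' @param cfg A [cohort_config()].
#' @return A tibble `sample_id`, `rs12248560`, `rs4244285`, `rs4986893`,
#'   `true_diplotype`.
#' @export
sample_genotypes <- function(cfg) {
  freqs <- c("*1" = 1 - sum(cfg$hap_freqs),
             "*2" = unname(cfg$hap_freqs["*2"]),
             "*3" = unname(cfg$hap_freqs["*3"]),
             "*17" = unname(cfg$hap_freqs["*17"]))
  hap <- matrix(sample(names(freqs), 2 * cfg$n, replace = TRUE, prob = freqs),
                ncol = 2)
  count_of <- function(allele) rowSums(hap == allele)
  dip <- apply(hap, 1, function(h) {
    paste(h[order(match(h, .star_levels))], collapse = "/")
  })
  tibble(
    sample_id = sprintf("S%05d", seq_len(cfg$n)),
    rs12248560 = as.integer(count_of("*17")),
    rs4244285 = as.integer(count_of("*2")),
    rs4986893 = as.integer(count_of("*3")),
    true_diplotype = if (cfg$n) dip else character(0)
  )
}

#' Draw participant demographics
#'
#' Age is drawn from a normal distribution truncated to the adult
#' `age_range` by inverse-CDF sampling. Because one-sided truncation would
#' otherwise bias the realised mean upward, the latent location is
#' calibrated (by root finding) so that the truncated distribution has mean
#' `age_mean` exactly; `age_sd` is the latent scale. Sex is Bernoulli in
#' the configured female proportion.
#'
#' @param cfg A [cohort_config()].
#' @return A tibble `sample_id`, `age`, `sex` (`"female"`/`"male"`).
#' @export
sample_demographics <- function(cfg) {
  n <- cfg$n
  if (cfg$age_sd == 0) {
    age <- rep(cfg$age_mean, n)
  } else {
    mu <- truncnorm_location(cfg$age_mean, cfg$age_sd, cfg$age_range)
    lo <- pnorm(cfg$age_range[1], mu, cfg$age_sd)
    hi <- pnorm(cfg$age_range[2], mu, cfg$age_sd)
    age <- stats::qnorm(runif(n, lo, hi), mu, cfg$age_sd)
  }
  tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    age = age,
    sex = ifelse(rbinom(n, 1, cfg$prop_female) == 1, "female", "male")
  )
}

#' Assign SSRI exposures
#'
#' Draws the number of drugs taken (1, 2 or 3) from `n_drugs_dist`, then
#' chooses that many distinct drugs with probability proportional to
#' `drug_weights`. This two-stage scheme reproduces the observed exposure
#' overlap (about 25% on two drugs, 6% on all three), which independent
#' per-drug Bernoulli draws at the printed marginals cannot.
#'
#' @param cfg A [cohort_config()].
#' @return A long tibble `sample_id`, `drug`.
#' @export
assign_drugs <- function(cfg) {
  n <- cfg$n
  k <- sample.int(3, n, replace = TRUE, prob = cfg$n_drugs_dist)
  w <- cfg$drug_weights[cfg$drugs]
  picks <- purrr::map(k, ~ sample(cfg$drugs, .x, prob = w))
  tibble(
    sample_id = rep(sprintf("S%05d", seq_len(n)), times = k),
    drug = if (n) unlist(picks) else character(0)
  )
}

#' Simulate treatment outcomes
#'
#' Given participant statuses and drug assignments, draws one record per
#' participant-drug pair. A participant-level random intercept
#' `u ~ N(0, random_intercept_sd^2)` is shared across that participant's
#' records. Efficacy follows a proportional-odds model against the drug's
#' thresholds (`logit P(y <= k) = theta_k - eta`, so positive effects shift
#' responses upward); discontinuation, any-side-effect and the 23 specific
#' side-effect binaries follow logistic models. With all effects and
#' `random_intercept_sd` zero, every outcome reduces to independent draws at
#' the intercept-implied marginals.
#'
#' @param cfg A [cohort_config()].
#' @param participants Tibble with `sample_id`, `age`, `sex`, `status`.
#' @param drug_assignments Long tibble with `sample_id`, `drug`.
#' @return A long tibble of records: `sample_id`, `drug`, `efficacy` (1-3),
#'   `discontinued`, `any_side_effect` (0/1) and one 0/1 column per specific
#'   side effect. The latent intercepts are returned in the `u` column of
#'   the participant table by [simulate_cohort()].
#' @export
simulate_outcomes <- function(cfg, participants, drug_assignments) {
  validate_cohort_config(cfg)
  pp <- dplyr::mutate(
    participants,
    u = rnorm(dplyr::n(), 0, cfg$random_intercept_sd)
  )
  rec <- dplyr::inner_join(drug_assignments, pp, by = "sample_id")
  m <- nrow(rec)

  beta_for <- function(outcome) {
    b <- cfg$status_betas[[outcome]]
    ifelse(rec$status == "normal", 0, b[as.character(rec$status)])
  }
  covar <- cfg$beta_age * rec$age + cfg$beta_sex * (rec$sex == "female")

  # ordinal efficacy via the cumulative-logit inverse draw
  eta_eff <- beta_for("efficacy") + covar + rec$u
  th <- do.call(rbind, cfg$efficacy_thresholds[rec$drug])
  if (m == 0) th <- matrix(numeric(0), 0, 2)
  p1 <- plogis(th[, 1] - eta_eff)
  p2 <- plogis(th[, 2] - eta_eff)
  uu <- runif(m)
  efficacy <- 1L + (uu > p1) + (uu > p2)

  draw_binary <- function(intercepts, outcome) {
    eta <- unname(intercepts[rec$drug]) + beta_for(outcome) + covar + rec$u
    rbinom(m, 1, plogis(eta))
  }
  out <- tibble(
    sample_id = rec$sample_id,
    drug = rec$drug,
    efficacy = as.integer(efficacy),
    discontinued = draw_binary(cfg$discontinued_intercept, "discontinued"),
    any_side_effect = draw_binary(cfg$any_side_effect_intercept,
                                  "any_side_effect")
  )
  if (length(cfg$side_effect_names)) {
    rates <- rep(cfg$side_effect_rate,
                 length.out = length(cfg$side_effect_names))
    eta_se <- beta_for("side_effects") + covar + rec$u
    for (j in seq_along(cfg$side_effect_names)) {
      out[[cfg$side_effect_names[j]]] <-
        rbinom(m, 1, plogis(qlogis(rates[j]) + eta_se))
    }
  }
  attr(out, "u") <- pp[c("sample_id", "u")]
  out
}

#' Simulate a full pharmacogenomic cohort
#'
#' Runs the whole generator: random-mating genotypes, diplotype and
#' metaboliser-status calling (through the same translation code used for
#' real data), demographics, drug assignment and outcome simulation.
#'
#' @param cfg A [cohort_config()].
#' @return An object of class `pgx_cohort`: a list with `participants`
#'   (`sample_id`, `age`, `sex`, `diplotype`, `status`, latent `u`),
#'   `records` (long outcome table), `genotypes`, and `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  validate_cohort_config(cfg)
  run <- function() {
    genotypes <- sample_genotypes(cfg)
    called <- call_diplotypes(genotypes[1:4])
    demo <- sample_demographics(cfg)
    participants <- dplyr::inner_join(
      demo, called[c("sample_id", "diplotype", "status")], by = "sample_id"
    )
    participants$status <- droplevels_keep(participants$status)
    drugs <- assign_drugs(cfg)
    records <- simulate_outcomes(cfg, participants, drugs)
    participants <- dplyr::left_join(participants, attr(records, "u"),
                                     by = "sample_id")
    attr(records, "u") <- NULL
    structure(
      list(participants = participants, records = records,
           genotypes = genotypes, config = cfg),
      class = "pgx_cohort"
    )
  }
  if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, run()) else run()
}

# latent location mu such that a Normal(mu, sd) truncated to `range` has
# the requested mean
truncnorm_location <- function(target_mean, sd, range) {
  trunc_mean <- function(mu) {
    a <- (range[1] - mu) / sd
    b <- (range[2] - mu) / sd
    z <- pnorm(b) - pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target_mean,
                 interval = target_mean + c(-3, 3) * sd, tol = 1e-8)$root
}

# keep the five phenotype levels (drop only the indeterminate level, which
# random-mating draws cannot produce)
droplevels_keep <- function(status) {
  factor(as.character(status), levels = .status_levels)
}

#' @export
print.pgx_cohort <- function(x, ...) {
  cat(sprintf("<pgx_cohort> %d participants, %d drug records\n",
              nrow(x$participants), nrow(x$records)))
  tab <- table(x$participants$status)
  cat("metaboliser status:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes a plain-text VCF 4.2 with the three CYP2C19 sites (GT field), a
#' long-format phenotype TSV (one row per participant-drug record) and a
#' wide participant TSV. Output is deterministic given the cohort.
#'
#' @param cohort A `pgx_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths
#'   (`vcf`, `phenotypes`, `participants`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pgx_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    participants = file.path(dir, "participants.tsv")
  )
  write_cyp2c19_vcf(cohort$genotypes, paths[["vcf"]])
  readr::write_tsv(cohort$records, paths[["phenotypes"]])
  readr::write_tsv(
    dplyr::select(cohort$participants, -dplyr::any_of("u")),
    paths[["participants"]]
  )
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `genotypes.vcf`, `phenotypes.tsv` and
#'   `participants.tsv`.
#' @return A list with `participants`, `records` and `genotypes` tibbles.
#' @export
read_cohort <- function(dir) {
  participants <- readr::read_tsv(file.path(dir, "participants.tsv"),
                                  show_col_types = FALSE)
  if (nrow(participants)) {
    participants$status <- factor(participants$status, levels = .status_levels)
  }
  list(
    participants = participants,
    records = readr::read_tsv(file.path(dir, "phenotypes.tsv"),
                              show_col_types = FALSE),
    genotypes = read_cyp2c19_vcf(file.path(dir, "genotypes.vcf"))
  )
}

# Plain-text single-chromosome VCF writer for the three-site genotype table.
write_cyp2c19_vcf <- function(genotypes, path) {
  sites <- cyp2c19_sites()
  gt_string <- function(count) {
    dplyr::case_when(is.na(count) ~ "./.", count == 0 ~ "0/0",
                     count == 1 ~ "0/1", TRUE ~ "1/1")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ssripgx",
    "##contig=<ID=10>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_id), collapse = "\t")
  )
  sites <- sites[order(sites$pos), ]
  body <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    paste(c(s$chrom, s$pos, s$rsid, s$ref, s$alt, ".", "PASS", ".", "GT",
            gt_string(genotypes[[s$rsid]])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
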