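test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(hap_freqs = c(`*2` = 0.6, `*3` = 0.3,
                                           `*17` = 0.3)), "sum")
  expect_error(cohort_config(n_drugs_dist = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(
    cohort_config(efficacy_thresholds = list(
      sertraline = c(1, 0), citalopram = c(0, 1), escitalopram = c(0, 1)
    )),
    "increasing"
  )
  expect_error(cohort_config(prop_female = 1.2), "prop_female")
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cohort(cohort_config(n = 150, seed = 42))
  b <- simulate_cohort(cohort_config(n = 150, seed = 42))
  expect_identical(a$records, b$records)
  expect_identical(a$participants, b$participants)
  expect_identical(a$genotypes, b$genotypes)
  c2 <- simulate_cohort(cohort_config(n = 150, seed = 43))
  expect_false(identical(a$records, c2$records))
})

test_that("degenerate haplotype frequencies give an all-*1/*1 cohort", {
  cfg <- cohort_config(n = 50, hap_freqs = c(`*2` = 0, `*3` = 0, `*17` = 0),
                       seed = 1)
  co <- simulate_cohort(cfg)
  expect_true(all(co$participants$diplotype == "*1/*1"))
  expect_true(all(co$participants$status == "normal"))
})

test_that("demographics hit the target marginals", {
  withr::with_seed(7, {
    demo <- sample_demographics(cohort_config(n = 1e5))
  })
  # truncation-calibrated: realised mean equals the target within MC error
  expect_lt(abs(mean(demo$age) - 42.8), 0.2)
  expect_true(all(demo$age >= 18 & demo$age <= 90))
  expect_lt(abs(mean(demo$sex == "female") - 0.76), 0.01)
  # degenerate settings
  d0 <- sample_demographics(cohort_config(n = 20, age_sd = 0))
  expect_true(all(d0$age == 42.8))
  withr::with_seed(8, {
    df <- sample_demographics(cohort_config(n = 200, prop_female = 1))
  })
  expect_true(all(df$sex == "female"))
})

test_that("drug assignment reproduces the exposure overlap", {
  cfg1 <- cohort_config(n = 300, n_drugs_dist = c(1, 0, 0))
  withr::with_seed(3, {
    one <- assign_drugs(cfg1)
  })
  expect_identical(max(table(one$sample_id)), 1L)

  withr::with_seed(4, {
    multi <- assign_drugs(cohort_config(n = 20000))
  })
  k <- table(factor(table(multi$sample_id), levels = 1:3)) / 20000
  expect_lt(abs(k[["2"]] - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))
  expect_lt(abs(k[["3"]] - 0.06), 3 * sqrt(0.06 * 0.94 / 20000))
})

test_that("null outcomes reproduce the intercept-implied marginals", {
  cfg <- cohort_config(n = 12000, random_intercept_sd = 0, seed = 12)
  co <- simulate_cohort(cfg)
  s <- co$records[co$records$drug == "sertraline", ]
  n <- nrow(s)
  eff <- prop.table(table(s$efficacy))
  for (k in 1:3) {
    target <- c(0.37, 0.36, 0.27)[k]
    expect_lt(abs(eff[[k]] - target),
              3 * sqrt(target * (1 - target) / n) + 0.011)
  }
  expect_lt(abs(mean(s$discontinued) - 0.46), 3 * sqrt(0.25 / n))
  expect_lt(abs(mean(s$any_side_effect) - 0.70), 3 * sqrt(0.21 / n))
})

test_that("a strong efficacy effect saturates the top category", {
  cfg <- cohort_config(
    n = 2000, random_intercept_sd = 0,
    status_betas = list(efficacy = c(poor = 10, intermediate = 10,
                                     rapid = 10, ultrarapid = 10)),
    seed = 5
  )
  co <- simulate_cohort(cfg)
  d <- cohort_analysis_frame(co)
  affected <- d[d$status != "normal", ]
  expect_gt(mean(affected$efficacy == 3), 0.99)
})

test_that("null cohorts give crude ORs near 1 and a single beta is recovered", {
  # null: all betas zero, sigma 0 -> empirical OR within 3 SD of 1
  co0 <- simulate_cohort(cohort_config(n = 8000, random_intercept_sd = 0,
                                       seed = 21))
  d0 <- cohort_analysis_frame(co0)
  tab <- table(d0$status %in% "intermediate", d0$any_side_effect)
  o <- crude_or(tab[2, 2], tab[2, 1], tab[1, 2], tab[1, 1])
  expect_lt(abs(o$log_or) / o$se, 3)

  # parameter-recovery seed: one nonzero beta, sigma 0 -> crude OR ~ exp(beta)
  beta <- log(1.8)
  co1 <- simulate_cohort(cohort_config(
    n = 20000, random_intercept_sd = 0,
    status_betas = list(discontinued = c(intermediate = beta)), seed = 22
  ))
  d1 <- cohort_analysis_frame(co1)
  d1 <- d1[d1$status %in% c("normal", "intermediate"), ]
  tab <- table(d1$status == "intermediate", d1$discontinued)
  o <- crude_or(tab[2, 2], tab[2, 1], tab[1, 2], tab[1, 1])
  expect_lt(abs(o$log_or - beta) / o$se, 3)
})

test_that("cumulative-logit category probabilities are coherent", {
  withr::with_seed(9, {
    for (rep in 1:20) {
      theta <- sort(rnorm(2, 0, 2))
      if (diff(theta) == 0) next
      eta <- rnorm(50, 0, 2)
      p <- cumulative_logit_probs(theta, eta)
      expect_equal(rowSums(p), rep(1, 50), tolerance = 1e-12)
      expect_true(all(p >= 0))
      cum <- t(apply(p, 1, cumsum))
      expect_true(all(diff(t(cum)) >= -1e-12))
    }
  })
  expect_error(cumulative_logit_probs(c(1, 0), 0), "increasing")
})

test_that("write/read round-trips and empty cohorts produce valid files", {
  co <- simulate_cohort(cohort_config(n = 80, seed = 31))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$records), as.data.frame(co$records))
  expect_equal(back$genotypes, co$genotypes[1:4])
  expect_equal(
    as.data.frame(back$participants),
    as.data.frame(dplyr::select(co$participants, -u))
  )

  # byte-identical phenotype TSV under a fixed seed
  dir2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cohort_config(n = 80, seed = 31)), dir2)
  expect_identical(readLines(file.path(dir, "phenotypes.tsv")),
                   readLines(file.path(dir2, "phenotypes.tsv")))

  # n = 0 still writes headers
  dir0 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cohort_config(n = 0, seed = 1)), dir0)
  pheno <- readLines(file.path(dir0, "phenotypes.tsv"))
  expect_length(pheno, 1)
  expect_match(pheno, "^sample_id\tdrug\tefficacy")
})
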