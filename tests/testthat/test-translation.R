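test_that("dosage hardening rounds within tolerance and is missing beyond it", {
  expect_identical(harden_dosage(1.97, 0.1), 2L)
  expect_identical(harden_dosage(1.5, 0.1), NA_integer_)
  expect_identical(harden_dosage(0.08, 0.1), 0L)
  expect_identical(harden_dosage(c(0, 1, 2)), c(0L, 1L, 2L))
  expect_identical(harden_dosage(NA_real_), NA_integer_)
  expect_error(harden_dosage(2.3), "outside")
  expect_error(harden_dosage(1, tolerance = 0.6), "tolerance")
})

test_that("dosage hardening is idempotent on integers and symmetric about 1", {
  withr::with_seed(11, {
    d <- runif(500, 0, 2)
    h <- harden_dosage(d, 0.2)
    # idempotence: hardening a hard call returns it unchanged
    ok <- !is.na(h)
    expect_identical(harden_dosage(as.numeric(h[ok]), 0.2), h[ok])
    # symmetry: reflecting the dosage about 1 reflects the call
    h_ref <- harden_dosage(2 - d, 0.2)
    expect_identical(h_ref, ifelse(is.na(h), NA_integer_, 2L - h))
  })
})

test_that("diplotype translation handles the canonical cases", {
  expect_identical(genotypes_to_diplotype(0, 0, 0), "*1/*1")
  expect_identical(genotypes_to_diplotype(0, 2, 0), "*2/*2")
  # double heterozygote resolves in trans under the no-cis rule
  expect_identical(genotypes_to_diplotype(1, 1, 0), "*2/*17")
  expect_identical(genotypes_to_diplotype(1, 0, 1), "*3/*17")
  expect_identical(genotypes_to_diplotype(NA, 0, 0), NA_character_)
  expect_error(genotypes_to_diplotype(3, 0, 0), "counts")
})

test_that("every one of the 27 genotype patterns maps consistently", {
  patterns <- expand.grid(c17 = 0:2, c2 = 0:2, c3 = 0:2)
  dip <- genotypes_to_diplotype(patterns$c17, patterns$c2, patterns$c3)
  expect_false(anyNA(dip))
  total <- patterns$c17 + patterns$c2 + patterns$c3
  # phase-consistent iff at most two variant alleles in total
  expect_identical(dip == "indeterminate", total > 2)
  # oracle: enumerate all unordered haplotype pairs and invert the counts
  alleles <- c("*1", "*2", "*3", "*17")
  counts_of <- function(pair) {
    c(c17 = sum(pair == "*17"), c2 = sum(pair == "*2"),
      c3 = sum(pair == "*3"))
  }
  pairs <- expand.grid(a = alleles, b = alleles, stringsAsFactors = FALSE)
  for (i in which(total <= 2)) {
    match_pairs <- pairs[apply(pairs, 1, function(pr) {
      all(counts_of(pr) == unlist(patterns[i, c("c17", "c2", "c3")]))
    }), ]
    canon <- unique(apply(match_pairs, 1, function(pr) {
      paste(pr[order(match(pr, alleles))], collapse = "/")
    }))
    expect_identical(dip[i], canon)
  }
})

test_that("the CPIC diplotype-to-phenotype map is implemented in full", {
  expected <- c(
    "*1/*1" = "normal", "*1/*17" = "rapid", "*17/*17" = "ultrarapid",
    "*1/*2" = "intermediate", "*1/*3" = "intermediate",
    "*2/*17" = "intermediate", "*3/*17" = "intermediate",
    "*2/*2" = "poor", "*2/*3" = "poor", "*3/*3" = "poor"
  )
  got <- diplotype_to_status(names(expected))
  expect_identical(as.character(got), unname(expected))
  expect_identical(as.character(diplotype_to_status("indeterminate")),
                   "indeterminate")
  expect_error(diplotype_to_status("*4/*1"), "unrecognised")
})

test_that("status prevalences follow Hardy-Weinberg closed forms", {
  f <- c(`*2` = 0.14, `*3` = 0.0002, `*17` = 0.214)
  p1 <- 1 - sum(f)
  plof <- f[["*2"]] + f[["*3"]]
  p17 <- f[["*17"]]
  expected <- c(
    poor = plof^2,
    intermediate = 2 * p1 * plof + 2 * p17 * plof,
    normal = p1^2,
    rapid = 2 * p1 * p17,
    ultrarapid = p17^2
  )
  n <- 20000
  withr::with_seed(101, {
    gt <- sample_genotypes(cohort_config(n = n, hap_freqs = f))
  })
  called <- call_diplotypes(gt[1:4])
  obs <- table(called$status)[names(expected)] / n
  for (s in names(expected)) {
    tol <- 3 * sqrt(expected[s] * (1 - expected[s]) / n)
    expect_lt(abs(obs[[s]] - expected[[s]]), max(tol, 1e-4))
  }
})

test_that("VCF calling matches hand-derived diplotypes on the toy cohort", {
  path <- write_toy_vcf()
  res <- call_metabolizers(path, quiet = TRUE)
  expect_identical(res$sample_id, c("S1", "S2", "S3", "S4"))
  expect_identical(res$diplotype, c("*1/*1", "*2/*17", "*2/*2", "*17/*17"))
  expect_identical(as.character(res$status),
                   c("normal", "intermediate", "poor", "ultrarapid"))
  expect_identical(sum(attr(res, "exclusions")), 0L)
})

test_that("VCF calling reads dosages, flags missing sites and empty files", {
  # dosage (DS) representation of the same samples, one fuzzy value
  lines <- toy_vcf_lines()
  lines[3] <- '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">'
  lines[5] <- sub("GT\t0/0\t0/1\t0/0\t1/1", "DS\t0.02\t0.96\t0.03\t1.98",
                  lines[5], fixed = TRUE)
  lines[6] <- sub("GT\t0/0\t0/0\t0/0\t0/0", "DS\t0.01\t0.00\t0.04\t0.02",
                  lines[6], fixed = TRUE)
  lines[7] <- sub("GT\t0/0\t0/1\t1/1\t0/0", "DS\t0.05\t1.03\t1.55\t0.00",
                  lines[7], fixed = TRUE)
  ds_path <- tempfile(fileext = ".vcf")
  writeLines(lines, ds_path)
  res <- call_metabolizers(ds_path, quiet = TRUE)
  # S3 dosage 1.55 is not hard-callable -> excluded, not dropped
  expect_identical(res$diplotype, c("*1/*1", "*2/*17", NA, "*17/*17"))
  expect_identical(res$exclusion[3], "missing_genotype")
  expect_identical(attr(res, "exclusions")[["missing_genotype"]], 1L)

  # a VCF lacking one of the three sites names the missing rsID
  short <- tempfile(fileext = ".vcf")
  writeLines(toy_vcf_lines()[-7], short)
  expect_error(call_metabolizers(short, quiet = TRUE), "rs4244285")

  empty <- tempfile(fileext = ".vcf")
  writeLines(toy_vcf_lines()[1:4], empty)
  expect_error(call_metabolizers(empty, quiet = TRUE))
})

test_that("site matching falls back to chrom:pos when IDs are absent", {
  lines <- toy_vcf_lines()
  lines[5:7] <- vapply(lines[5:7], function(l) {
    parts <- strsplit(l, "\t")[[1]]
    parts[3] <- "."
    paste(parts, collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  res <- call_metabolizers(path, quiet = TRUE)
  expect_identical(res$diplotype, c("*1/*1", "*2/*17", "*2/*2", "*17/*17"))
})
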