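#' Tier-1 CYP2C19 variant sites
#'
#' The three CYP2C19 polymorphisms that define the tier-1 star alleles
#' recommended as the minimum pharmacogenomic panel by the Association for
#' Molecular Pathology: rs12248560 (*17, promoter gain-of-function),
#' rs4244285 (*2, splicing defect) and rs4986893 (*3, premature stop).
#' Coordinates are GRCh38; matching by rsID is attempted first, so the
#' build only matters for positional fallback.
#'
#' @return A tibble with columns `rsid`, `star_allele`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @export
#' @examples
#' cyp2c19_sites()
cyp2c19_sites <- function() {
  tibble(
    rsid = c("rs12248560", "rs4244285", "rs4986893"),
    star_allele = c("*17", "*2", "*3"),
    chrom = c("10", "10", "10"),
    pos = c(94761900L, 94781859L, 94780653L),
    ref = c("C", "G", "G"),
    alt = c("T", "A", "A")
  )
}

# Canonical allele order used when printing a diplotype: *1/*17, never *17/*1.
.star_levels <- c("*1", "*2", "*3", "*17")

.status_levels <- c("poor", "intermediate", "normal", "rapid", "ultrarapid")

#' Convert imputed allele dosages to hard genotype calls
#'
#' An imputed dosage in \[0, 2\] is rounded to the nearest integer allele
#' count when it lies within `tolerance` of that integer; otherwise the call
#' is set to missing (`NA`). Integer inputs pass through unchanged.
#'
#' @param dosage Numeric vector of alternate-allele dosages in \[0, 2\].
#'   `NA` values propagate.
#' @param tolerance Maximum allowed distance from an integer; must lie in
#'   (0, 0.5).
#' @return Integer vector of hard calls in \{0, 1, 2\}, with `NA` where the
#'   dosage is too far from an integer.
#' @export
#' @examples
#' harden_dosage(c(1.97, 1.5, 0.08))
harden_dosage <- function(dosage, tolerance = 0.1) {
  if (!is.numeric(dosage)) abort("`dosage` must be numeric.")
  if (!is.numeric(tolerance) || length(tolerance) != 1 ||
      tolerance <= 0 || tolerance >= 0.5) {
    abort("`tolerance` must be a single number in (0, 0.5).")
  }
  bad <- !is.na(dosage) & (dosage < 0 | dosage > 2)
  if (any(bad)) {
    abort(sprintf("dosages outside [0, 2]: e.g. %g", dosage[which(bad)[1]]))
  }
  hard <- as.integer(round(dosage))
  hard[!is.na(dosage) & abs(dosage - hard) > tolerance] <- NA_integer_
  hard
}

#' Translate CYP2C19 genotypes to a star-allele diplotype
#'
#' Assigns the unique diplotype consistent with the alternate-allele counts
#' at rs12248560 (*17), rs4244285 (*2) and rs4986893 (*3) under the standard
#' star-allele phase assumption that each haplotype carries at most one of
#' the variant-defining alleles. A compound heterozygote for *2 and *17 is
#' therefore called *2/*17 (trans). Patterns whose total variant-allele
#' count exceeds two admit no phase-consistent pair and are returned as
#' `"indeterminate"`. Missing calls at any site give `NA`.
#'
#' @param rs12248560,rs4244285,rs4986893 Integer vectors of alternate-allele
#'   counts in \{0, 1, 2\} (recycled to a common length).
#' @return Character vector of canonicalised diplotypes (e.g. `"*1/*17"`),
#'   `"indeterminate"`, or `NA` for missing input.
#' @export
#' @examples
#' genotypes_to_diplotype(1, 1, 0) # trans: "*2/*17"
genotypes_to_diplotype <- function(rs12248560, rs4244285, rs4986893) {
  counts <- vctrs_recycle(rs12248560, rs4244285, rs4986893)
  c17 <- counts[[1]]; c2 <- counts[[2]]; c3 <- counts[[3]]
  all_counts <- c(c17, c2, c3)
  if (any(!is.na(all_counts) & (all_counts < 0 | all_counts > 2 |
                                all_counts != round(all_counts)))) {
    abort("allele counts must be integers in {0, 1, 2} or NA.")
  }
  total <- c17 + c2 + c3
  out <- rep(NA_character_, length(total))
  ok <- !is.na(total)
  indet <- ok & total > 2
  out[indet] <- "indeterminate"
  det <- ok & !indet
  if (any(det)) {
    out[det] <- vapply(which(det), function(i) {
      haps <- rep(.star_levels, times = c(2L - total[i], c2[i], c3[i], c17[i]))
      paste(haps, collapse = "/")
    }, character(1))
  }
  out
}

#' Translate a diplotype to CYP2C19 metaboliser status
#'
#' Implements the CPIC diplotype-to-phenotype mapping over the tier-1
#' alleles: *17/*17 is ultrarapid, *1/*17 rapid, *1/*1 normal; one
#' loss-of-function allele (*2 or *3) paired with *1 or *17 is intermediate
#' (the CPIC "likely intermediate" sub-label for *2/*17 and *3/*17 is
#' collapsed into intermediate); two loss-of-function alleles give a poor
#' metaboliser.
#'
#' @param diplotype Character vector of canonical diplotypes as returned by
#'   [genotypes_to_diplotype()]; `"indeterminate"` and `NA` pass through.
#' @return Factor with levels poor, intermediate, normal, rapid, ultrarapid,
#'   indeterminate.
#' @export
#' @examples
#' diplotype_to_status(c("*1/*1", "*2/*2", "*2/*17"))
diplotype_to_status <- function(diplotype) {
  map <- c(
    "*1/*1" = "normal",
    "*1/*17" = "rapid",
    "*17/*17" = "ultrarapid",
    "*1/*2" = "intermediate",
    "*1/*3" = "intermediate",
    "*2/*17" = "intermediate",
    "*3/*17" = "intermediate",
    "*2/*2" = "poor",
    "*2/*3" = "poor",
    "*3/*3" = "poor",
    "indeterminate" = "indeterminate"
  )
  known <- is.na(diplotype) | diplotype %in% names(map)
  if (!all(known)) {
    abort(sprintf("unrecognised diplotype: '%s'", diplotype[!known][1]))
  }
  factor(unname(map[diplotype]), levels = c(.status_levels, "indeterminate"))
}

#' Call diplotypes and metaboliser status for a genotype table
#'
#' Takes a per-sample genotype table for the three tier-1 CYP2C19 variants
#' (hard allele counts or imputed dosages), hardens dosages where needed,
#' and appends the star-allele diplotype and metaboliser status. Samples
#' with a missing call at any site are retained with `NA` status and an
#' `exclusion` label, never silently dropped.
#'
#' @param genotypes Data frame with columns `sample_id`, `rs12248560`,
#'   `rs4244285`, `rs4986893` (allele counts 0-2 or dosages in \[0, 2\]).
#' @param dosage_tolerance Passed to [harden_dosage()] when any genotype
#'   value is non-integer.
#' @return A tibble with the input columns (hardened) plus `diplotype`,
#'   `status` and `exclusion` (`NA`, `"missing_genotype"` or
#'   `"indeterminate_diplotype"`). Exclusion counts are attached as the
#'   `"exclusions"` attribute.
#' @export
call_diplotypes <- function(genotypes, dosage_tolerance = 0.1) {
  req <- c("sample_id", "rs12248560", "rs4244285", "rs4986893")
  missing_cols <- setdiff(req, names(genotypes))
  if (length(missing_cols)) {
    abort(paste0("`genotypes` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  gt <- as_tibble(genotypes)[req]
  rs_cols <- req[-1]
  vals <- unlist(gt[rs_cols], use.names = FALSE)
  if (any(!is.na(vals) & vals != round(vals))) {
    gt <- dplyr::mutate(gt, dplyr::across(
      dplyr::all_of(rs_cols), ~ harden_dosage(.x, dosage_tolerance)
    ))
  } else {
    gt <- dplyr::mutate(gt, dplyr::across(dplyr::all_of(rs_cols), as.integer))
  }
  out <- gt |>
    dplyr::mutate(
      diplotype = genotypes_to_diplotype(
        .data$rs12248560, .data$rs4244285, .data$rs4986893
      ),
      status = diplotype_to_status(.data$diplotype),
      exclusion = dplyr::case_when(
        is.na(diplotype) ~ "missing_genotype",
        diplotype == "indeterminate" ~ "indeterminate_diplotype",
        TRUE ~ NA_character_
      )
    )
  attr(out, "exclusions") <- c(
    missing_genotype = sum(out$exclusion %in% "missing_genotype"),
    indeterminate_diplotype = sum(out$exclusion %in% "indeterminate_diplotype")
  )
  out
}

#' Read the three CYP2C19 sites from a VCF
#'
#' Extracts per-sample genotypes for rs12248560, rs4244285 and rs4986893
#' from a VCF 4.x file. Sites are located by the ID column first, then by
#' chromosome and 1-based position using `sites`. Either hard genotypes
#' (`GT`) or imputed dosages (`DS`) can be used.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param field `"auto"` (use `DS` when present, else `GT`), `"GT"` or
#'   `"DS"`.
#' @param sites Site table in the format of [cyp2c19_sites()], used for
#'   positional fallback.
#' @return A tibble with `sample_id` and one column of alternate-allele
#'   counts (or dosages, if `DS` was read) per rsID.
#' @export
read_cyp2c19_vcf <- function(path, field = c("auto", "GT", "DS"),
                             sites = cyp2c19_sites()) {
  field <- match.arg(field)
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to read VCF: ", conditionMessage(e)))
  )
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records.")
  row_for <- function(rsid) {
    i <- which(fix$ID == rsid)
    if (length(i) == 0) {
      site <- sites[sites$rsid == rsid, ]
      i <- which(fix$CHROM == site$chrom & as.integer(fix$POS) == site$pos)
    }
    if (length(i) == 0) {
      abort(paste0("VCF lacks required CYP2C19 site: ", rsid))
    }
    i[1]
  }
  rows <- vapply(sites$rsid, row_for, integer(1))

  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  use_ds <- switch(field,
    DS = TRUE,
    GT = FALSE,
    auto = "DS" %in% fmt
  )
  if (use_ds && !"DS" %in% fmt) abort("VCF FORMAT has no DS field.")
  if (!use_ds && !"GT" %in% fmt) abort("VCF FORMAT has no GT field.")

  mat <- if (use_ds) {
    apply(vcfR::extract.gt(vcf, element = "DS"), 2, as.numeric)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    apply(gt, 2, function(g) {
      vapply(strsplit(g, "[/|]"), function(a) {
        if (length(a) == 0 || any(a == ".") || anyNA(a)) return(NA_real_)
        sum(a != "0")
      }, numeric(1))
    })
  }
  mat <- matrix(mat, nrow = nrow(fix),
                dimnames = list(NULL, colnames(vcf@gt)[-1]))
  out <- tibble(sample_id = colnames(mat))
  for (j in seq_along(sites$rsid)) {
    out[[sites$rsid[j]]] <- unname(mat[rows[j], ])
  }
  out
}

#' Call metaboliser status for a cohort
#'
#' End-to-end genotype-to-phenotype calling: reads genotypes (from a VCF
#' path or an in-memory genotype table), hardens dosages, translates to
#' star-allele diplotypes and CPIC metaboliser status, and reports exclusion
#' counts for missing or indeterminate calls.
#'
#' @param x Path to a VCF file, or a genotype data frame as accepted by
#'   [call_diplotypes()].
#' @param dosage_tolerance Hard-call tolerance for imputed dosages.
#' @param field VCF FORMAT field selection, see [read_cyp2c19_vcf()].
#' @param quiet Suppress the exclusion-count message.
#' @return A tibble `sample_id`, `diplotype`, `status`, `exclusion`, with
#'   exclusion counts in the `"exclusions"` attribute.
#' @export
call_metabolizers <- function(x, dosage_tolerance = 0.1,
                              field = c("auto", "GT", "DS"), quiet = FALSE) {
  genotypes <- if (is.character(x) && length(x) == 1) {
    read_cyp2c19_vcf(x, field = match.arg(field))
  } else if (is.data.frame(x)) {
    x
  } else {
    abort("`x` must be a VCF path or a genotype data frame.")
  }
  called <- call_diplotypes(genotypes, dosage_tolerance = dosage_tolerance)
  excl <- attr(called, "exclusions")
  if (!quiet) {
    inform(sprintf(
      "called %d/%d samples (excluded: missing_genotype=%d indeterminate_diplotype=%d)",
      sum(is.na(called$exclusion)), nrow(called),
      excl[["missing_genotype"]], excl[["indeterminate_diplotype"]]
    ))
  }
  out <- called[c("sample_id", "diplotype", "status", "exclusion")]
  attr(out, "exclusions") <- excl
  out
}

# minimal common-length recycling for a fixed set of vectors
vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x
    else if (length(x) == 1) rep(x, n)
    else abort("inputs must have equal length or length 1.")
  })
}
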