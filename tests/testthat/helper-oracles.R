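# Independent oracles and fixture builders shared across tests. These
# reimplement the likelihoods from scratch (scalar loops, no reuse of
# package internals) so model fits can be checked against brute force.

# proportional-odds log-likelihood, scalar implementation
oracle_clm_loglik <- function(theta, beta, y, X) {
  ll <- 0
  for (i in seq_along(y)) {
    eta <- sum(X[i, ] * beta)
    upper <- if (y[i] <= length(theta)) plogis(theta[y[i]] - eta) else 1
    lower <- if (y[i] >= 2) plogis(theta[y[i] - 1] - eta) else 0
    ll <- ll + log(upper - lower)
  }
  ll
}

# brute-force ML for the proportional-odds model: coarse grid search for a
# starting region, then Nelder-Mead polish (derivative-free, independent of
# the package's Newton path)
oracle_clm_ml <- function(y, X, grid = seq(-2, 2, by = 0.25)) {
  best <- NULL
  for (t1 in grid) {
    for (t2 in grid) {
      if (t2 <= t1) next
      for (b in grid) {
        ll <- oracle_clm_loglik(c(t1, t2), b, y, X)
        if (is.null(best) || ll > best$ll) {
          best <- list(par = c(t1, t2, b), ll = ll)
        }
      }
    }
  }
  opt <- optim(
    best$par,
    function(p) {
      if (p[2] <= p[1]) return(1e10)
      -oracle_clm_loglik(p[1:2], p[3], y, X)
    },
    method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-14)
  )
  list(theta = opt$par[1:2], beta = opt$par[3], logLik = -opt$value)
}

# marginal log-likelihood of a random-intercept model by fine trapezoid
# integration over the latent intercept
oracle_mixed_loglik <- function(y, eta0, idx, sigma, family = "binomial",
                                theta = NULL, half_width = 8,
                                n_points = 20001) {
  u_grid <- seq(-half_width * sigma, half_width * sigma,
                length.out = n_points)
  step <- diff(u_grid)[1]
  total <- 0
  for (i in unique(idx)) {
    yi <- y[idx == i]
    ei <- eta0[idx == i]
    f <- vapply(u_grid, function(u) {
      lp <- ei + u
      ll <- if (family == "binomial") {
        sum(yi * lp - log1p(exp(lp)))
      } else {
        up <- c(theta, Inf)[yi] - lp
        lo <- c(-Inf, theta)[yi] - lp
        sum(log(plogis(up) - plogis(lo)))
      }
      exp(ll + dnorm(u, 0, sigma, log = TRUE))
    }, numeric(1))
    total <- total + log(sum((f[-1] + f[-length(f)]) / 2) * step)
  }
  total
}

# deterministic 4-sample toy VCF with hand-derived diplotypes:
#   S1 *1/*1 (normal), S2 *2/*17 (intermediate), S3 *2/*2 (poor),
#   S4 *17/*17 (ultrarapid)
toy_vcf_lines <- function() {
  c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=10>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"),
    paste("10", "94761900", "rs12248560", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "0/0", "1/1", sep = "\t"),
    paste("10", "94780653", "rs4986893", "G", "A", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/0", "0/0", sep = "\t"),
    paste("10", "94781859", "rs4244285", "G", "A", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "0/0", sep = "\t")
  )
}

write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(toy_vcf_lines(), path)
  path
}

# analysis-ready record/participant pair from a simulated cohort
cohort_analysis_frame <- function(cohort) {
  d <- dplyr::inner_join(cohort$records, cohort$participants,
                         by = "sample_id")
  d$status <- factor(as.character(d$status),
                     levels = c("normal", "poor", "intermediate", "rapid",
                                "ultrarapid"))
  d$sex <- factor(d$sex, levels = c("male", "female"))
  d
}
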