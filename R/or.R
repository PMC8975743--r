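#' Crude odds ratio from a 2x2 table
#'
#' Computes the cross-product odds ratio `(a * d) / (b * c)` with a Woolf
#' (log-scale Wald) 95% confidence interval. The four counts follow the
#' exposed-vs-reference layout: `a` and `b` are event and non-event counts
#' in the comparison group, `c` and `d` the same in the reference group.
#' Any zero cell triggers the Haldane-Anscombe correction (0.5 added to all
#' cells), flagged in the `corrected` column.
#'
#' @param a,b,c,d Non-negative counts (vectorised).
#' @param conf_level Confidence level for the Woolf interval.
#' @return A tibble with `or`, `conf.low`, `conf.high`, `log_or`, `se`,
#'   `p.value` (two-sided Wald) and `corrected`.
#' @export
#' @examples
#' crude_or(32, 63, 775, 917) # discontinuation, poor vs normal metabolisers
crude_or <- function(a, b, c, d, conf_level = 0.95) {
  counts <- vctrs_recycle(a, b, c, d)
  if (any(unlist(counts) < 0, na.rm = TRUE)) {
    abort("all counts must be non-negative.")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  purrr::pmap(counts, function(a, b, c, d) {
    corrected <- any(c(a, b, c, d) == 0)
    if (corrected) {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
    or <- (a * d) / (b * c)
    log_or <- log(or)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    tibble(
      or = or,
      conf.low = exp(log_or - z * se),
      conf.high = exp(log_or + z * se),
      log_or = log_or, se = se,
      p.value = 2 * pnorm(-abs(log_or / se)),
      corrected = corrected
    )
  }) |>
    purrr::list_rbind()
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests in the family (positive integer).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 4) # 0.0125
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    abort("`alpha` must lie in (0, 1).")
  }
  if (!is.numeric(n_tests) || any(n_tests < 1) ||
      any(n_tests != round(n_tests))) {
    abort("`n_tests` must be a positive integer.")
  }
  alpha / n_tests
}
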