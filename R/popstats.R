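#' Carrier count of a call set
#'
#' Each call contributes `AC - hom_count` carriers: heterozygotes plus
#' homozygotes counted once. Assumes no individual carries two distinct
#' qualifying variants (a documented approximation; the overcount bias is below
#' k^2/2n at the allele frequencies involved).
#' @param calls call frame with `AC` and `hom_count`.
#' @return integer carrier count.
#' @export
carriers_from_calls <- function(calls) {
  if (!nrow(calls)) return(0L)
  if (any(calls$AC < 2L * calls$hom_count)) {
    fail("call with AC < 2*hom_count", "carrier_invariant_error")
  }
  as.integer(sum(calls$AC - calls$hom_count))
}

#' Carrier prevalence point estimate
#' @param k carrier count.
#' @param n cohort size (> 0).
#' @return prevalence in percent, `100 * k / n` (unrounded).
#' @export
prevalence <- function(k, n) {
  if (any(n <= 0)) fail("cohort size must be positive", "prevalence_error")
  if (any(k < 0 | k > n)) fail("carrier count outside [0, n]", "prevalence_error")
  100 * k / n
}

#' Binomial confidence interval for a prevalence
#'
#' Wilson score interval (default) or Clopper-Pearson exact interval, returned
#' in percent.
#' @param k successes (carriers).
#' @param n trials (cohort size).
#' @param method `"wilson"` or `"clopper_pearson"`.
#' @param level confidence level in (0, 1).
#' @return named vector `c(ci_low, ci_high)` in percent.
#' @export
binomial_ci <- function(k, n, method = c("wilson", "clopper_pearson"),
                        level = 0.95) {
  method <- match.arg(method)
  if (level <= 0 || level >= 1) fail("confidence level must be in (0,1)",
                                     "ci_level_error")
  if (k < 0 || k > n) fail("k outside [0, n]", "ci_input_error")
  alpha <- 1 - level
  if (method == "wilson") {
    z <- stats::qnorm(1 - alpha / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- max(0, centre - half); hi <- min(1, centre + half)
  } else {
    lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  }
  c(ci_low = 100 * lo, ci_high = 100 * hi)
}

#' Full prevalence estimate with interval
#' @param k carriers; @param n cohort size.
#' @param method,level see [binomial_ci()].
#' @return list with `k`, `n`, `prevalence` (percent), `ci_low`, `ci_high`,
#'   `ci_method`, `level`.
#' @export
prevalence_estimate <- function(k, n, method = "wilson", level = 0.95) {
  ci <- binomial_ci(k, n, method, level)
  list(k = k, n = n, prevalence = prevalence(k, n),
       ci_low = unname(ci["ci_low"]), ci_high = unname(ci["ci_high"]),
       ci_method = method, level = level)
}

#' "One in N" form of a prevalence
#'
#' @param prevalence_percent prevalence in percent (> 0).
#' @return `round(100 / prevalence_percent)`, the unrounded-to-display carrier
#'   denominator. Use [format_one_in()] for display rounding.
#' @export
one_in_n <- function(prevalence_percent) {
  if (any(prevalence_percent <= 0)) fail("prevalence must be positive",
                                         "one_in_n_error")
  round(100 / prevalence_percent)
}

#' Display-round a "one in N" figure
#' @param n integer from [one_in_n()].
#' @param nearest rounding grain (e.g. 50 or 100). Display only; never applied
#'   to stored values.
#' @return string like `"1 in 500"`.
#' @export
format_one_in <- function(n, nearest = 50) {
  sprintf("1 in %d", as.integer(round(n / nearest) * nearest))
}

#' Chi-square homogeneity test of carrier prevalence across groups
#'
#' @param groups named list or data.frame mapping group label to
#'   `c(carriers, size)` (list) or columns `carriers`, `size`.
#' @return list(statistic, df, p_value, warning) — `warning` is set when an
#'   expected cell drops below 1.
#' @export
group_chi_square <- function(groups) {
  if (is.data.frame(groups)) {
    k <- groups$carriers; n <- groups$size
  } else {
    k <- vapply(groups, `[[`, numeric(1), 1)
    n <- vapply(groups, `[[`, numeric(1), 2)
  }
  if (length(k) < 2) fail("need at least two groups", "group_test_error")
  if (any(n <= 0)) fail("group sizes must be positive", "group_test_error")
  m <- cbind(carriers = k, noncarriers = n - k)
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  warn <- if (any(ht$expected < 1)) "expected cell count below 1" else NA_character_
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, warning = warn)
}

#' Two-group carrier-proportion test
#'
#' Two-sided Fisher's exact test on the 2x2 carriers table (chi-square without
#' continuity correction available as an option).
#' @param k1,n1,k2,n2 carriers and sizes of the two groups.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return p-value.
#' @export
pairwise_prop_test <- function(k1, n1, k2, n2, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (method == "fisher") {
    stats::fisher.test(m, alternative = "two.sided")$p.value
  } else {
    suppressWarnings(stats::chisq.test(m, correct = FALSE))$p.value
  }
}

#' Hardy-Weinberg heterozygote-to-homozygote ratio
#'
#' At allele frequency q, the expected number of heterozygous individuals per
#' homozygous individual is `2pq / q^2 = 2(1-q)/q`.
#' @param q alternate allele frequency in (0, 1).
#' @return expected het individuals per hom individual.
#' @export
hwe_het_hom_ratio <- function(q) {
  if (any(q <= 0 | q >= 1)) fail("allele frequency must be in (0,1)",
                                 "hwe_input_error")
  2 * (1 - q) / q
}

#' Allele frequency implied by an observed homozygote count
#'
#' Under Hardy-Weinberg, h homozygotes among n individuals imply
#' `q = sqrt(h/n)`.
#' @param h homozygote count; @param n cohort size.
#' @return allele frequency estimate.
#' @export
hwe_q_from_hom <- function(h, n) {
  if (h <= 0 || n <= 0 || h > n) fail("need 0 < h <= n", "hwe_input_error")
  sqrt(h / n)
}

#' Fraction of positions covered at a depth threshold
#' @param coverage coverage frame ([read_coverage()]).
#' @param positions data.frame with `chrom`, `pos` (e.g. a call frame), or NULL
#'   for all coverage rows.
#' @param depth_threshold mean-depth threshold.
#' @return list(fraction, n, missing = positions absent from the coverage
#'   table).
#' @export
coverage_fraction <- function(coverage, positions = NULL, depth_threshold = 50) {
  if (is.null(positions)) {
    depth <- coverage$mean_depth
    missing <- character(0)
  } else {
    i <- match(paste(positions$chrom, positions$pos),
               paste(coverage$chrom, coverage$pos))
    depth <- coverage$mean_depth[i]
    missing <- paste0(positions$chrom, ":", positions$pos)[is.na(i)]
    depth <- depth[!is.na(depth)]
  }
  list(fraction = if (length(depth)) mean(depth >= depth_threshold) else NA_real_,
       n = length(depth), missing = missing)
}
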