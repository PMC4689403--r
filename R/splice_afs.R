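#' Default allele-frequency-spectrum thresholds
#'
#' Private = dataset-wide singleton (AC equal to `private_max_AC`, default 1);
#' low-frequency = not private and AF below `low_freq_max_AF` (default 0.5%);
#' common otherwise.
#' @return list(private_max_AC, low_freq_max_AF).
#' @export
afs_config <- function(private_max_AC = 1L, low_freq_max_AF = 0.005) {
  list(private_max_AC = as.integer(private_max_AC),
       low_freq_max_AF = low_freq_max_AF)
}

#' Allele-frequency class of a variant
#' @param AC alternate allele count (> 0).
#' @param AN total allele number.
#' @param config thresholds from [afs_config()].
#' @return character vector over `private` / `low_frequency` / `common`
#'   (vectorized over AC/AN).
#' @export
afs_class <- function(AC, AN, config = afs_config()) {
  if (any(AC == 0)) fail("AC = 0: unobserved allele has no frequency class",
                         "afs_zero_error")
  if (any(AC > AN)) fail("AC > AN", "afs_invariant_error")
  af <- AC / AN
  ifelse(AC <= config$private_max_AC, "private",
         ifelse(af < config$low_freq_max_AF, "low_frequency", "common"))
}

SPLICE_BINS <- c("1-2", "3-4", "5-6")

#' Bin splice calls by intron distance and allele-frequency class
#'
#' Distance bins |d| in 1-2 (essential), 3-4, 5-6; calls beyond 6 bp are
#' excluded.
#' @param calls annotated call frame with `splice_distance`, `AC`, `AN`.
#' @param config thresholds from [afs_config()].
#' @return data.frame `bin`, `n`, `private`, `low_frequency`, `common` (one row
#'   per bin, always all three bins).
#' @export
splice_bin_table <- function(calls, config = afs_config()) {
  d <- abs(calls$splice_distance)
  keep <- !is.na(d) & d >= 1 & d <= 6
  sub <- calls[keep, , drop = FALSE]
  bin <- SPLICE_BINS[(abs(sub$splice_distance) - 1) %/% 2 + 1]
  cls <- if (nrow(sub)) afs_class(sub$AC, sub$AN, config) else character(0)
  out <- data.frame(bin = SPLICE_BINS, n = 0L, private = 0L,
                    low_frequency = 0L, common = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(SPLICE_BINS)) {
    b <- SPLICE_BINS[i]
    out$n[i] <- sum(bin == b)
    out$private[i] <- sum(bin == b & cls == "private")
    out$low_frequency[i] <- sum(bin == b & cls == "low_frequency")
    out$common[i] <- sum(bin == b & cls == "common")
  }
  out
}

bin_counts <- function(table, bin) {
  if (bin == "3-6") {
    i <- table$bin %in% c("3-4", "5-6")
    c(n = sum(table$n[i]), private = sum(table$private[i]),
      low_frequency = sum(table$low_frequency[i]), common = sum(table$common[i]))
  } else {
    i <- table$bin == bin
    if (!any(i)) fail(sprintf("unknown bin '%s'", bin), "bin_error")
    c(n = table$n[i], private = table$private[i],
      low_frequency = table$low_frequency[i], common = table$common[i])
  }
}

#' Compare the frequency-class composition of two distance bins
#'
#' Two-sided Fisher's exact test on the 2x2 table (class vs not-class) x
#' (bin_a vs bin_b). `"3-6"` pools the two non-essential bins, so the pooled
#' essential-vs-non-essential comparison is `afs_composition_test(t, "1-2",
#' "3-6", "private")`.
#' @param table output of [splice_bin_table()].
#' @param bin_a,bin_b bin labels (`"1-2"`, `"3-4"`, `"5-6"`, `"3-6"`).
#' @param class_label `"private"`, `"low_frequency"` or `"common"`.
#' @return p-value.
#' @export
afs_composition_test <- function(table, bin_a, bin_b, class_label = "private") {
  a <- bin_counts(table, bin_a); b <- bin_counts(table, bin_b)
  if (a["n"] == 0 || b["n"] == 0) fail("empty bin in composition test",
                                       "empty_bin_error")
  m <- matrix(c(a[class_label], a["n"] - a[class_label],
                b[class_label], b["n"] - b[class_label]),
              nrow = 2, byrow = TRUE)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Splice allele-frequency-spectrum report
#' @param calls annotated call frame.
#' @param config thresholds from [afs_config()].
#' @return data.frame per bin: n, class fractions, and the Fisher p-value of
#'   each non-essential bin against the essential bin (private composition).
#' @export
splice_afs_report <- function(calls, config = afs_config()) {
  tab <- splice_bin_table(calls, config)
  out <- data.frame(
    bin = tab$bin, n = tab$n,
    private_frac = ifelse(tab$n > 0, tab$private / tab$n, NA_real_),
    low_freq_frac = ifelse(tab$n > 0, tab$low_frequency / tab$n, NA_real_),
    common_frac = ifelse(tab$n > 0, tab$common / tab$n, NA_real_),
    p_vs_essential = NA_real_, stringsAsFactors = FALSE)
  for (b in c("3-4", "5-6")) {
    i <- out$bin == b
    if (tab$n[tab$bin == "1-2"] > 0 && tab$n[i] > 0) {
      out$p_vs_essential[i] <- afs_composition_test(tab, "1-2", b, "private")
    }
  }
  out
}
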