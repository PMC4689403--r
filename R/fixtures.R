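# Deterministic margin-matched fixtures. These reproduce the printed aggregate
# margins of the reference-population analysis (counts per dataset, band and
# mutation type; carrier totals; splice and nonsense-spectrum ratios) for
# worked-example tests and reports. They are synthetic: the individual variants
# are placeholders engineered so that the summary operations recover the
# printed margins, not the actual population variants.

fixture_calls <- function(dataset, band, class, n, AN, pos_start,
                          exon_class = "all_transcripts", affects_all = TRUE,
                          mean_depth = 60, extra_ac = 0L, keys = NULL) {
  if (n == 0) return(NULL)
  pos <- if (is.na(pos_start)) rep(0L, n) else seq.int(pos_start, length.out = n)
  ref <- if (class == "frameshift") "CA" else "C"
  alt <- if (class == "frameshift") "C" else "T"
  df <- data.frame(
    chrom = "chr2", pos = pos, id = ".", ref = ref, alt = alt,
    qual = 1000, filter_status = "PASS",
    AC = c(1L + as.integer(extra_ac), rep(1L, n - 1)),
    AN = AN, hom_count = 0L, dataset = dataset,
    consequence_class = class, band = band, exon_id = "EX",
    exon_class = exon_class, affects_all = affects_all,
    mean_depth = mean_depth,
    splice_distance = if (class == "essential_splice") 2L else NA_integer_,
    stringsAsFactors = FALSE)
  if (!is.null(keys)) {
    df$pos <- keys$pos; df$ref <- keys$ref; df$alt <- keys$alt
  }
  df$key <- variant_key(df)
  df
}

#' Margin-matched reference-population fixture
#'
#' A deterministic three-dataset cohort (superset "EXAC" role, subset "KG" and
#' "ESP" roles) whose aggregate margins equal the published analysis:
#' per-dataset truncating totals 470 / 33 / 66 entering the transcript filter,
#' filtered totals 173 / 9 / 16, carrier totals 219 / 10 / 19, the ExAC-role
#' filtered band split 19/39/90/25, 247 of 470 ExAC-role calls in exons not
#' affecting all transcripts, and exactly three splice variants shared between
#' the two subset call sets. Cell-level carrier counts are back-computed from
#' the printed prevalences. Also carries the ethnicity group counts.
#'
#' @return list: `calls_by_dataset` (annotated truncating call frames, the
#'   pipeline's stage-4 input), `cohort_sizes`, `groups` (data.frame `label`,
#'   `size`, `carriers`), `config` (filter configuration to use).
#' @export
make_table1_fixture <- function() {
  sizes <- c(EXAC = 60706L, KG = 2504L, ESP = 6504L)
  ANs <- 2L * sizes
  fs <- "frameshift"; ns <- "nonsense"; sp <- "essential_splice"
  ## ---- ExAC role: 470 = 173 retained + 247 transcript + 50 coverage
  # retained cells: band, class, variants, carriers (from printed prevalences)
  exac_ret <- list(
    list("Z", fs, 8L, 8L),  list("Z", ns, 4L, 4L),  list("Z", sp, 7L, 11L),
    list("I", fs, 10L, 10L), list("I", ns, 19L, 21L), list("I", sp, 10L, 13L),
    list("A", fs, 35L, 35L), list("A", ns, 37L, 55L), list("A", sp, 18L, 29L),
    list("M", fs, 10L, 16L), list("M", ns, 12L, 14L), list("M", sp, 3L, 3L))
  # removed at the transcript stage (isoform-specific / low-PSI exons)
  exac_tr <- list(
    list("Z", fs, 2L), list("Z", ns, 4L), list("Z", sp, 3L),
    list("I", fs, 69L), list("I", ns, 69L), list("I", sp, 62L),
    list("A", fs, 15L), list("A", ns, 12L), list("A", sp, 5L),
    list("M", ns, 5L), list("M", sp, 1L))
  # removed at the coverage stage (well-annotated exons, low depth)
  exac_cov <- list(list("I", fs, 30L), list("I", ns, 15L), list("I", sp, 5L))
  pos <- 200000L
  exac <- list()
  ret_pool <- list()  # retained keys per band:class, for subset reuse
  for (cell in exac_ret) {
    d <- fixture_calls("EXAC", cell[[1]], cell[[2]], cell[[3]], ANs[["EXAC"]],
                       pos, extra_ac = cell[[4]] - cell[[3]])
    ret_pool[[paste(cell[[1]], cell[[2]])]] <- d[c("pos", "ref", "alt")]
    exac[[length(exac) + 1]] <- d
    pos <- pos + cell[[3]]
  }
  first_tr <- TRUE
  for (cell in exac_tr) {
    d <- fixture_calls("EXAC", cell[[1]], cell[[2]], cell[[3]], ANs[["EXAC"]],
                       pos, exon_class = "isoform_specific", affects_all = FALSE,
                       extra_ac = if (first_tr) 297L else 0L)
    # alternate the removal reason between isoform-specific and low-PSI exons
    d$exon_class <- rep(c("isoform_specific", "low_psi"), length.out = nrow(d))
    exac[[length(exac) + 1]] <- d
    pos <- pos + cell[[3]]
    first_tr <- FALSE
  }
  for (cell in exac_cov) {
    exac[[length(exac) + 1]] <- fixture_calls(
      "EXAC", cell[[1]], cell[[2]], cell[[3]], ANs[["EXAC"]], pos,
      mean_depth = 8)
    pos <- pos + cell[[3]]
  }
  exac <- do.call(rbind, exac)
  ## ---- shared subset-only splice keys (the three 1KG/ESP shared variants)
  shared_sp <- data.frame(pos = seq.int(350000L, length.out = 3L),
                          ref = "C", alt = "T", stringsAsFactors = FALSE)
  ## ---- 1KG role: 33 = 9 retained + 17 transcript + 4 concordance + 3 shared
  ##      (shared-with-ESP splice calls survive concordance, fail coverage)
  take <- function(cell, k, from = 1) ret_pool[[cell]][from:(from + k - 1), ]
  kg <- rbind(
    fixture_calls("KG", "I", ns, 1L, ANs[["KG"]], NA, keys = take("I nonsense", 1)),
    fixture_calls("KG", "A", fs, 1L, ANs[["KG"]], NA, keys = take("A frameshift", 1)),
    fixture_calls("KG", "A", ns, 6L, ANs[["KG"]], NA, extra_ac = 1L,
                  keys = take("A nonsense", 6)),
    fixture_calls("KG", "M", sp, 1L, ANs[["KG"]], NA, keys = take("M essential_splice", 1)),
    # transcript-stage removals: novex-specific / low-PSI exon calls
    fixture_calls("KG", "I", ns, 8L, ANs[["KG"]], 300000L,
                  exon_class = "isoform_specific", affects_all = FALSE,
                  extra_ac = 12L),
    fixture_calls("KG", "I", sp, 9L, ANs[["KG"]], 300100L,
                  exon_class = "low_psi", affects_all = FALSE),
    # concordance-stage removals: unique to this subset call set
    fixture_calls("KG", "I", ns, 4L, ANs[["KG"]], 300200L),
    # shared with ESP, absent from the superset: retained by concordance,
    # removed by the coverage filter
    fixture_calls("KG", "I", sp, 3L, ANs[["KG"]], NA, mean_depth = 8,
                  keys = shared_sp))
  ## ---- ESP role: 66 = 16 retained + 36 transcript + 11 concordance + 3 shared
  esp <- rbind(
    fixture_calls("ESP", "Z", ns, 1L, ANs[["ESP"]], NA, keys = take("Z nonsense", 1)),
    fixture_calls("ESP", "I", ns, 5L, ANs[["ESP"]], NA, extra_ac = 3L,
                  keys = take("I nonsense", 5, from = 2)),
    fixture_calls("ESP", "I", sp, 2L, ANs[["ESP"]], NA, keys = take("I essential_splice", 2)),
    fixture_calls("ESP", "A", fs, 1L, ANs[["ESP"]], NA, keys = take("A frameshift", 1, from = 2)),
    fixture_calls("ESP", "A", ns, 3L, ANs[["ESP"]], NA, keys = take("A nonsense", 3, from = 7)),
    fixture_calls("ESP", "M", fs, 2L, ANs[["ESP"]], NA, keys = take("M frameshift", 2)),
    fixture_calls("ESP", "M", ns, 2L, ANs[["ESP"]], NA, keys = take("M nonsense", 2)),
    fixture_calls("ESP", "I", fs, 16L, ANs[["ESP"]], 400000L,
                  exon_class = "isoform_specific", affects_all = FALSE,
                  extra_ac = 543L),
    fixture_calls("ESP", "I", ns, 12L, ANs[["ESP"]], 400100L,
                  exon_class = "isoform_specific", affects_all = FALSE),
    fixture_calls("ESP", "I", sp, 8L, ANs[["ESP"]], 400200L,
                  exon_class = "low_psi", affects_all = FALSE),
    fixture_calls("ESP", "I", fs, 6L, ANs[["ESP"]], 400300L),
    fixture_calls("ESP", "I", ns, 5L, ANs[["ESP"]], 400400L),
    fixture_calls("ESP", "I", sp, 3L, ANs[["ESP"]], NA, mean_depth = 8,
                  keys = shared_sp))
  rownames(exac) <- rownames(kg) <- rownames(esp) <- NULL
  # ethnicity groups (superset cohort): carriers back-computed from the
  # printed per-population prevalences
  groups <- data.frame(
    label = c("AFR", "AMR", "EAS", "SAS", "FIN", "NFE"),
    size = c(5203L, 5789L, 4327L, 8256L, 3307L, 33370L),
    carriers = c(24L, 29L, 16L, 51L, 4L, 93L),
    stringsAsFactors = FALSE)
  list(
    calls_by_dataset = list(EXAC = exac, KG = kg, ESP = esp),
    cohort_sizes = sizes,
    groups = groups,
    config = list(psi_threshold = 0.15, min_mean_depth = 15,
                  superset_dataset = "EXAC", flag_only = FALSE,
                  coverage = NULL))
}

#' Margin-matched nonsense-spectrum fixture
#'
#' Annotated nonsense calls whose tallies reproduce the published spectrum
#' ratios: 21 of 23 A-band arginine stop-gains are the CpG-hotspot Cga/Tga
#' change, and 21 of 34 CpG-hotspot stop-gains lie in the A band; calls at
#' second/third codon positions round out the position spectrum.
#' @return annotated call frame for [spectrum_summary()].
#' @export
make_spectrum_fixture <- function() {
  row <- function(n, ref_codon, alt_codon, codon_pos, band, cpg) {
    data.frame(consequence_class = "nonsense", ref_codon = ref_codon,
               alt_codon = alt_codon, codon_pos = codon_pos, band = band,
               cpg = cpg, AC = 1L, AN = 121412L, hom_count = 0L,
               stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
  }
  out <- rbind(
    row(21, "CGA", "TGA", 1L, "A", TRUE),   # Cga/Tga CpG hotspot, A band
    row(2, "AGA", "TGA", 1L, "A", FALSE),   # other R/* in the A band
    row(13, "CGA", "TGA", 1L, "I", TRUE),   # CpG hotspot stop-gains elsewhere
    row(4, "TGG", "TGA", 3L, "I", FALSE),
    row(2, "TAC", "TAA", 3L, "M", FALSE))
  rownames(out) <- NULL
  out
}

#' Margin-matched splice allele-frequency-spectrum fixture
#'
#' Splice site/region calls reproducing the published composition: 373 calls of
#' which 324 (86.9%) are non-essential (3-6 bp); 41 of 49 essential calls
#' (83.7%) are private singletons; 197 calls sit next to A-band exons, 175 of
#' them (88.8%) non-essential.
#' @return annotated call frame with `consequence_class`, `splice_distance`,
#'   `band`, `AC`, `AN`.
#' @export
make_splice_fixture <- function() {
  AN <- 121412L
  mk <- function(n, dist, band, AC) {
    if (n == 0) return(NULL)
    data.frame(
      consequence_class = ifelse(abs(dist) <= 2, "essential_splice",
                                 "splice_region"),
      splice_distance = dist, band = band, AC = AC, AN = AN, hom_count = 0L,
      stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
  }
  ess_band <- c(rep("A", 22), rep("I", 27))
  ess_ac <- c(rep(1L, 41), rep(30L, 6), rep(1000L, 2))
  ess <- do.call(rbind, lapply(seq_len(49), function(i) {
    mk(1, c(1L, -1L, 2L, -2L)[(i - 1) %% 4 + 1], ess_band[i], ess_ac[i])
  }))
  ne_bin <- function(n_total, dists, n_a, ac_profile) {
    band <- c(rep("A", n_a), rep("I", n_total - n_a))
    do.call(rbind, lapply(seq_len(n_total), function(i) {
      mk(1, dists[(i - 1) %% length(dists) + 1], band[i], ac_profile[i])
    }))
  }
  ac34 <- c(rep(1L, 91), rep(30L, 65), rep(1000L, 6))
  ac56 <- c(rep(1L, 90), rep(30L, 65), rep(1000L, 7))
  out <- rbind(ess,
               ne_bin(162, c(3L, -3L, 4L, -4L), 88, ac34),
               ne_bin(162, c(5L, -5L, 6L, -6L), 87, ac56))
  rownames(out) <- NULL
  out
}

#' Call-set evolution fixture
#'
#' Nested call-set versions mirroring the published attrition of truncating
#' calls across reference-database releases: an initial set of 22 (4 nonsense,
#' 1 splice region, 17 frameshift), a cleaned set of 16, a set of 4 after
#' removing the remaining indel false positives, and a final expanded set of 33
#' (19 nonsense, 13 splice, 1 frameshift).
#' @return list(callsets = named list of call frames in release order,
#'   cohort_sizes = named sizes).
#' @export
make_evolution_fixture <- function() {
  mk <- function(keys, class) {
    data.frame(chrom = "chr2", pos = keys, ref = "C", alt = "T",
               consequence_class = class, AC = 1L, hom_count = 0L,
               stringsAsFactors = FALSE)
  }
  ns_keys <- 500001:500004
  sr_key <- 500101
  fs_keys <- 500201:500217
  v1 <- rbind(mk(ns_keys, "nonsense"), mk(sr_key, "splice_region"),
              mk(fs_keys, "frameshift"))
  v2 <- rbind(mk(ns_keys, "nonsense"), mk(sr_key, "splice_region"),
              mk(fs_keys[1:11], "frameshift"))
  v3 <- mk(ns_keys, "nonsense")
  p3 <- rbind(mk(c(ns_keys, 510001:510015), "nonsense"),
              mk(520001:520013, "essential_splice"),
              mk(530001, "frameshift"))
  list(callsets = list(P1V1 = v1, P1V2 = v2, P1V3 = v3, P3V5 = p3),
       cohort_sizes = c(P1V1 = 1092L, P1V2 = 1092L, P1V3 = 1092L, P3V5 = 2504L))
}
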