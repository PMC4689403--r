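#' Enumerate every single-substitution path from a sense codon to a stop codon
#'
#' Exhaustive over the standard genetic code: 23 patterns in total, of which 9
#' mutate the first codon position, 7 the second and 7 the third. The label
#' writes the ref and alt codons in lower case with the mutated base upper
#' case, e.g. `"Cga/Tga"`.
#' @return data.frame with columns `ref_codon`, `codon_pos`, `alt_codon`,
#'   `ref_aa`, `label`, ordered by (codon_pos, ref_codon, alt_codon).
#' @export
enumerate_stop_gain_patterns <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- names(Biostrings::GENETIC_CODE)
  # the genetic code table uses T-alphabet codons already
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  out <- list()
  for (ref in sense) {
    for (p in 1:3) {
      for (b in setdiff(bases, substr(ref, p, p))) {
        alt <- ref
        substr(alt, p, p) <- b
        if (alt %in% STOP_CODONS) {
          out[[length(out) + 1L]] <- data.frame(
            ref_codon = ref, codon_pos = p, alt_codon = alt,
            ref_aa = unname(Biostrings::GENETIC_CODE[ref]),
            label = pattern_label(ref, alt, p), stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$codon_pos, df$ref_codon, df$alt_codon), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Format a codon-change label
#'
#' Ref and alt codons in lower case, mutated base in upper case: CGA->TGA at
#' position 1 becomes `"Cga/Tga"`.
#' @param ref_codon,alt_codon 3-mers.
#' @param codon_pos mutated position 1-3.
#' @return label string.
#' @export
pattern_label <- function(ref_codon, alt_codon, codon_pos) {
  style <- function(codon) {
    x <- tolower(codon)
    substr(x, codon_pos, codon_pos) <- toupper(substr(codon, codon_pos, codon_pos))
    x
  }
  paste0(style(ref_codon), "/", style(alt_codon))
}

#' Is a substitution a CpG deamination transition?
#'
#' True for C>T with a G immediately 3', or G>A with a C immediately 5' (the
#' opposite-strand deamination), on the strand of the supplied context.
#' @param context 3-mer centred on the variant base.
#' @param ref_base,alt_base single bases; `ref_base` must equal the context
#'   centre.
#' @return logical flag.
#' @export
is_cpg_transition <- function(context, ref_base, alt_base) {
  if (substr(context, 2, 2) != ref_base) {
    fail(sprintf("context '%s' centre does not match ref base '%s'",
                 context, ref_base), "context_mismatch_error")
  }
  (ref_base == "C" && alt_base == "T" && substr(context, 3, 3) == "G") ||
    (ref_base == "G" && alt_base == "A" && substr(context, 1, 1) == "C")
}

#' Stop-gain pattern and CpG flag of one nonsense call
#'
#' The CpG context is evaluated on the spliced coding sequence by default, so a
#' codon's neighbour across an exon junction is its spliced neighbour;
#' `cpg_context = "genomic"` uses the genomic neighbours instead.
#' @param call one-row annotated call frame with `consequence_class`
#'   `"nonsense"` plus `ref_codon`, `alt_codon`, `codon_pos`, `cds_pos`,
#'   `transcript_id`, `pos`.
#' @param model a `gene_model`.
#' @param cpg_context `"spliced"` (default) or `"genomic"`.
#' @return list(pattern = one-row pattern frame, cpg = flag).
#' @export
nonsense_pattern <- function(call, model, cpg_context = c("spliced", "genomic")) {
  cpg_context <- match.arg(cpg_context)
  if (call$consequence_class != "nonsense") {
    fail("nonsense_pattern requires a nonsense call", "not_nonsense_error")
  }
  p <- call$codon_pos
  pat <- data.frame(
    ref_codon = call$ref_codon, codon_pos = p, alt_codon = call$alt_codon,
    ref_aa = translate_codon(call$ref_codon),
    label = pattern_label(call$ref_codon, call$alt_codon, p),
    stringsAsFactors = FALSE)
  ref_b <- substr(call$ref_codon, p, p)
  alt_b <- substr(call$alt_codon, p, p)
  if (cpg_context == "spliced") {
    cseq <- cds_sequence(model, call$transcript_id)
    i <- call$cds_pos
    prev <- if (i > 1) substr(cseq, i - 1, i - 1) else "N"
    nxt <- if (i < nchar(cseq)) substr(cseq, i + 1, i + 1) else "N"
  } else {
    g <- as.integer(call$pos)
    prev_g <- seq_at(model$sequence, model$locus_offset, g - 1L)
    nxt_g <- seq_at(model$sequence, model$locus_offset, g + 1L)
    if (model$strand == "-") {
      tmp <- comp_base(nxt_g); nxt_g <- comp_base(prev_g); prev_g <- tmp
    }
    prev <- prev_g; nxt <- nxt_g
  }
  cpg <- (ref_b == "C" && alt_b == "T" && nxt == "G") ||
    (ref_b == "G" && alt_b == "A" && prev == "C")
  list(pattern = pat, cpg = cpg)
}

#' Summarize the nonsense-mutation spectrum of a call set
#'
#' Tallies stop-gain patterns by label, codon position, CpG-transition status,
#' arginine-to-stop (`R/*`) status and band. If the calls already carry a `cpg`
#' column it is used as-is; otherwise `model` is required and the flag is
#' computed per call via [nonsense_pattern()].
#' @param calls annotated call frame; non-nonsense rows are ignored.
#' @param model a `gene_model`, required when `calls` has no `cpg` column.
#' @param band_filter optional band label restricting the summary.
#' @return object of class `spectrum_summary`: list with `calls` (per-call
#'   pattern table), `counts` (per-label tallies), `by_position` (length-3
#'   count vector), `cpg_transition_count`, `r_star_count`, `n`.
#' @export
spectrum_summary <- function(calls, model = NULL, band_filter = NULL) {
  ns <- calls[calls$consequence_class == "nonsense", , drop = FALSE]
  if (!is.null(band_filter)) ns <- ns[!is.na(ns$band) & ns$band == band_filter, ,
                                      drop = FALSE]
  if (nrow(ns) && !"cpg" %in% names(ns)) {
    if (is.null(model)) fail("spectrum_summary needs a model or a cpg column",
                             "spectrum_config_error")
    np <- lapply(seq_len(nrow(ns)), function(i) nonsense_pattern(ns[i, ], model))
    ns$cpg <- vapply(np, `[[`, logical(1), "cpg")
    ns$label <- vapply(np, function(x) x$pattern$label, character(1))
    ns$ref_aa <- vapply(np, function(x) x$pattern$ref_aa, character(1))
  }
  if (nrow(ns) && !"label" %in% names(ns)) {
    ns$label <- mapply(pattern_label, ns$ref_codon, ns$alt_codon, ns$codon_pos)
  }
  if (nrow(ns) && !"ref_aa" %in% names(ns)) {
    ns$ref_aa <- translate_codon(ns$ref_codon)
  }
  by_position <- vapply(1:3, function(p) sum(ns$codon_pos == p), numeric(1))
  names(by_position) <- c("pos1", "pos2", "pos3")
  counts <- if (nrow(ns)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(ns))),
                            by = list(label = ns$label,
                                      codon_pos = ns$codon_pos,
                                      ref_aa = ns$ref_aa), FUN = sum)
    agg[order(agg$codon_pos, agg$label), , drop = FALSE]
  } else {
    data.frame(label = character(0), codon_pos = integer(0),
               ref_aa = character(0), count = integer(0))
  }
  structure(list(
    calls = ns, counts = counts, by_position = by_position,
    cpg_transition_count = sum(ns$cpg %in% TRUE),
    r_star_count = sum(ns$ref_aa == "R"),
    n = nrow(ns)
  ), class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary> %d nonsense calls; by position %s; CpG %d; R/* %d\n",
              x$n, paste(x$by_position, collapse = "/"),
              x$cpg_transition_count, x$r_star_count))
  invisible(x)
}

#' Fraction of arginine-to-stop calls that are Cga/Tga
#'
#' @param summary a `spectrum_summary` built from all bands.
#' @param band optional band restriction (e.g. `"A"`).
#' @return list(k, n, fraction) where n counts `R/*` calls and k those with
#'   label `"Cga/Tga"`.
#' @export
cga_tga_over_r_star <- function(summary, band = NULL) {
  ns <- summary$calls
  if (!is.null(band)) ns <- ns[!is.na(ns$band) & ns$band == band, , drop = FALSE]
  rs <- ns[ns$ref_aa == "R", , drop = FALSE]
  k <- sum(rs$label == "Cga/Tga")
  list(k = k, n = nrow(rs),
       fraction = if (nrow(rs)) k / nrow(rs) else NA_real_)
}

#' Fraction of CpG-hotspot nonsense calls located in the A band
#' @param summary a `spectrum_summary` built from all bands.
#' @return list(k, n, fraction) where n counts CpG-transition nonsense calls
#'   and k those in band `"A"`.
#' @export
a_band_over_all_cpg <- function(summary) {
  cp <- summary$calls[summary$calls$cpg %in% TRUE, , drop = FALSE]
  k <- sum(!is.na(cp$band) & cp$band == "A")
  list(k = k, n = nrow(cp),
       fraction = if (nrow(cp)) k / nrow(cp) else NA_real_)
}

#' Chi-square test of codon-position bias among nonsense calls
#'
#' Goodness-of-fit of the position-1/2/3 counts against a uniform null
#' (1/3 each) or an opportunity-weighted null (9/23, 7/23, 7/23 from the
#' stop-gain enumeration).
#' @param summary a `spectrum_summary`.
#' @param null_model `"uniform"` or `"opportunity"`.
#' @return list(statistic, df, p_value, expected).
#' @export
codon_position_bias_test <- function(summary,
                                     null_model = c("uniform", "opportunity")) {
  null_model <- match.arg(null_model)
  counts <- summary$by_position
  if (sum(counts) == 0) fail("no nonsense calls to test", "empty_summary_error")
  p <- if (null_model == "uniform") rep(1 / 3, 3) else c(9, 7, 7) / 23
  if (any(p * sum(counts) == 0)) fail("zero expected cell", "expected_zero_error")
  ht <- stats::chisq.test(counts, p = p)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = unname(ht$expected))
}

#' Spectrum report table
#' @param summary a `spectrum_summary`.
#' @return data.frame: one row per pattern label with counts, CpG counts and
#'   per-band counts.
#' @export
spectrum_report <- function(summary) {
  ns <- summary$calls
  if (!nrow(ns)) {
    return(data.frame(label = character(0), ref_aa = character(0),
                      codon_pos = integer(0), count = integer(0),
                      cpg_count = integer(0)))
  }
  labs <- unique(ns$label[order(ns$codon_pos, ns$label)])
  rows <- lapply(labs, function(l) {
    sub <- ns[ns$label == l, , drop = FALSE]
    r <- data.frame(label = l, ref_aa = sub$ref_aa[1],
                    codon_pos = sub$codon_pos[1], count = nrow(sub),
                    cpg_count = sum(sub$cpg %in% TRUE), stringsAsFactors = FALSE)
    for (b in c("Z", "I", "A", "M")) {
      r[[paste0("band_", b)]] <- sum(!is.na(sub$band) & sub$band == b)
    }
    r
  })
  do.call(rbind, rows)
}
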