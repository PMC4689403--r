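#' Simulation configuration
#'
#' Study conditions for the synthetic gene and cohorts. Defaults emulate the
#' structure of a titin-like locus and ExAC-style population call sets at desk
#' scale: 40 shared exons plus one novex-like terminal exon, three transcripts,
#' Z/I/A/M band fractions weighted toward the A band, a singleton-heavy allele
#' frequency spectrum, five population groups of 5000 individuals, and mean
#' site coverage of 65x with ~10% of sites below the depth filter.
#'
#' @param seed integer seed driving every random draw.
#' @param n_exons number of shared exons (the novex-like exon is extra).
#' @param exon_len_range exon lengths in codons (uniform draw; lengths are
#'   multiples of 3 so every transcript CDS is too).
#' @param intron_len_range intron lengths in bp.
#' @param n_transcripts total transcripts: the full transcript, the novex-like
#'   transcript, and `n_transcripts - 2` alternative transcripts each skipping
#'   exons.
#' @param novex_after the novex-like unique terminal exon is placed after this
#'   many shared exons.
#' @param n_skipped shared exons absent from the alternative transcript(s).
#' @param n_low_psi shared exons given PSI below threshold.
#' @param band_fracs named fractions of the reference CDS assigned to Z/I/A/M.
#' @param psi_constitutive,psi_low PSI draw ranges.
#' @param psi_threshold PSI cut-off the low-PSI exons sit below.
#' @param strand `"+"` or `"-"`.
#' @param class_counts named counts of variants to plant per consequence class.
#' @param frac_not_all fraction of exonic variants placed in exons that do not
#'   affect all transcripts (novex-specific, skipped, low-PSI), emulating the
#'   52-54% seen in reference call sets.
#' @param singleton_fraction fraction of variants planted as singletons
#'   (AC = 1).
#' @param low_freq_af_range allele-frequency range for non-singletons
#'   (log-uniform draw).
#' @param populations data.frame `label`, `size`, `multiplier` (carrier-rate
#'   multiplier; allele counts are split multinomially with weight
#'   size x multiplier).
#' @param pass_fraction fraction of variants with FILTER `PASS`.
#' @param coverage list `mean`, `sd`, `low_frac`: site mean depth is normal
#'   (truncated at the depth threshold) except a `low_frac` share of sites
#'   drawn below the threshold.
#' @param min_mean_depth depth threshold the low-coverage sites sit under.
#' @param superset,subsets dataset roles: the superset call set contains every
#'   planted variant; each subset samples them at `subset_inclusion` and gains
#'   `n_false_positives` variants of its own (the planted concordance-filter
#'   targets).
#' @param subset_inclusion,n_false_positives see above.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_exons = 40L,
                       exon_len_range = c(25L, 90L),
                       intron_len_range = c(60L, 240L),
                       n_transcripts = 3L,
                       novex_after = 8L,
                       n_skipped = 2L,
                       n_low_psi = 3L,
                       band_fracs = c(Z = 0.09, I = 0.35, A = 0.45, M = 0.11),
                       psi_constitutive = c(0.90, 1.00),
                       psi_low = c(0.02, 0.10),
                       psi_threshold = 0.15,
                       strand = "+",
                       class_counts = c(nonsense = 40L, frameshift = 25L,
                                        essential_splice = 12L,
                                        splice_region = 30L, missense = 50L,
                                        synonymous = 50L),
                       frac_not_all = 0.5,
                       singleton_fraction = 0.7,
                       low_freq_af_range = c(5e-5, 5e-3),
                       populations = data.frame(
                         label = c("AFR", "AMR", "EAS", "SAS", "NFE"),
                         size = 5000L, multiplier = 1,
                         stringsAsFactors = FALSE),
                       pass_fraction = 0.95,
                       coverage = list(mean = 65, sd = 15, low_frac = 0.10),
                       min_mean_depth = 15,
                       superset = "EXAC",
                       subsets = c("KG", "ESP"),
                       subset_inclusion = 0.35,
                       n_false_positives = 8L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_transcripts >= 2, all(cfg$band_fracs >= 0),
            abs(sum(cfg$band_fracs) - 1) < 1e-9,
            all(cfg$class_counts >= 0),
            all(cfg$populations$size > 0),
            cfg$pass_fraction >= 0 && cfg$pass_fraction <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a gene model
#'
#' Deterministic for a given config (including seed): exon grid, transcripts
#' (full, novex-like with a unique terminal exon, and exon-skipping
#' alternatives), band intervals partitioning the reference CDS span, PSI
#' values, and a random locus sequence.
#' @param config a [sim_config()].
#' @return a `gene_model`.
#' @export
simulate_gene_model <- function(config) {
  set.seed(config$seed)
  n <- config$n_exons
  if (config$novex_after >= n - 1 || config$novex_after < 2) {
    fail("novex_after must leave shared exons on both sides", "sim_config_error")
  }
  n_total <- n + 1L  # shared exons + the novex-like unique exon
  lens <- 3L * sample(seq(config$exon_len_range[1], config$exon_len_range[2]),
                      n_total, replace = TRUE)
  gaps <- sample(seq(config$intron_len_range[1], config$intron_len_range[2]),
                 n_total - 1L, replace = TRUE)
  locus_offset <- 1000001L
  starts <- integer(n_total)
  starts[1] <- locus_offset + 300L
  for (i in 2:n_total) starts[i] <- starts[i - 1] + lens[i - 1] + gaps[i - 1]
  ends <- starts + lens - 1L
  novex_idx <- config$novex_after + 1L  # genomic slot of the unique exon
  shared_idx <- setdiff(seq_len(n_total), novex_idx)
  ids <- character(n_total)
  ids[shared_idx] <- sprintf("E%02d", seq_len(n))
  ids[novex_idx] <- "EN1"
  exons <- data.frame(exon_id = ids, start = starts, end = ends,
                      stringsAsFactors = FALSE)
  # skipped exons come from the region shared with the novex-like transcript,
  # so they stay present in two transcripts (only the novex exon is uniquely
  # held); low-PSI exons sit past the novex terminus
  before_novex <- shared_idx[shared_idx >= 3 & shared_idx <= novex_idx - 2]
  if (length(before_novex) < config$n_skipped) {
    fail("not enough shared exons before the novex terminus to skip",
         "sim_config_error")
  }
  skipped <- sort(sample(before_novex, config$n_skipped))
  interior <- shared_idx[shared_idx > novex_idx + 2 & shared_idx < n_total - 1]
  low_psi <- sort(sample(interior, config$n_low_psi))
  tx_full <- list(transcript_id = "tx_full", name = "full",
                  exon_ids = ids[shared_idx],
                  cds_start = min(starts[shared_idx]),
                  cds_end = max(ends[shared_idx]))
  novex_exons <- c(ids[shared_idx[shared_idx < novex_idx]], "EN1")
  tx_novex <- list(transcript_id = "tx_novex", name = "novex3-like",
                   exon_ids = novex_exons,
                   cds_start = starts[1], cds_end = ends[novex_idx])
  txs <- list(tx_full, tx_novex)
  if (config$n_transcripts >= 3) {
    for (j in seq_len(config$n_transcripts - 2)) {
      skip_j <- skipped[((seq_along(skipped) - 1) %% (config$n_transcripts - 2)) + 1 == j]
      keep <- setdiff(shared_idx, skip_j)
      txs[[length(txs) + 1]] <- list(
        transcript_id = sprintf("tx_alt%d", j), name = sprintf("alt%d", j),
        exon_ids = ids[keep], cds_start = min(starts[keep]),
        cds_end = max(ends[keep]))
    }
  }
  psi <- stats::setNames(
    round(stats::runif(n_total, config$psi_constitutive[1],
                       config$psi_constitutive[2]), 3), ids)
  psi[ids[low_psi]] <- round(stats::runif(length(low_psi), config$psi_low[1],
                                          config$psi_low[2]), 3)
  psi[ids[skipped]] <- 0.60
  psi["EN1"] <- 0.30  # novex-like exon: expressed but isoform-specific
  locus_len <- max(ends) - locus_offset + 1L + 300L
  sequence <- paste(sample(c("A", "C", "G", "T"), locus_len, replace = TRUE),
                    collapse = "")
  # bands: contiguous genomic intervals cutting the reference CDS at the
  # configured base fractions
  model0 <- gene_model("SIMGENE", "chrS", config$strand, locus_offset, sequence,
                       exons, txs, data.frame(band = character(0),
                                              start = integer(0),
                                              end = integer(0)), psi)
  cg <- coding_gpos(model0, "tx_full", translation_order = FALSE)
  fr <- config$band_fracs
  if (config$strand == "-") fr <- rev(fr)  # keep Z at the transcription start
  cuts <- round(cumsum(fr) * length(cg))
  cuts[length(cuts)] <- length(cg)
  if (any(diff(c(0, cuts)) <= 0)) fail("band fractions give an empty band",
                                       "sim_config_error")
  uppers <- cg[cuts]
  lowers <- c(min(cg), utils::head(uppers, -1) + 1L)
  bands <- data.frame(band = names(fr), start = lowers, end = uppers,
                      stringsAsFactors = FALSE)
  gene_model("SIMGENE", "chrS", config$strand, locus_offset, sequence,
             exons, txs, bands, psi)
}

# All single-nucleotide substitution effects on one transcript: one row per
# (coding position, alt base) with the resulting consequence class.
snv_effect_table <- function(model, transcript_id) {
  idx <- model_index(model, transcript_id)
  cseq <- idx$cds_seq
  L <- nchar(cseq)
  cds_pos <- seq_len(L)
  ci <- (cds_pos - 1L) %/% 3L + 1L
  cp <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- substring(cseq, 3L * ci - 2L, 3L * ci)
  ref_base <- substring(cseq, cds_pos, cds_pos)
  gpos <- idx$coding_gpos
  ex <- idx$exons
  exon_by_gpos <- ex$exon_id[
    vapply(gpos, function(p) which(ex$start <= p & p <= ex$end)[1], integer(1))]
  rows <- list()
  for (b in c("A", "C", "G", "T")) {
    keep <- ref_base != b
    alt_codon <- ref_codon[keep]
    pos_in <- cp[keep]
    for (p in 1:3) {
      sel <- pos_in == p
      if (any(sel)) substr(alt_codon[sel], p, p) <- b
    }
    ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon[keep]])
    alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
    cls <- ifelse(ref_aa != "*" & alt_aa == "*", "nonsense",
                  ifelse(ref_aa == alt_aa, "synonymous", "missense"))
    rows[[b]] <- data.frame(
      gpos = gpos[keep], cds_pos = cds_pos[keep], codon_index = ci[keep],
      codon_pos = cp[keep], ref_codon = ref_codon[keep],
      alt_coding = b, alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
      class = cls, exon_id = exon_by_gpos[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$cds_pos, out$alt_coding), , drop = FALSE]
}

# intronic positions within 1-6 bp of the reference transcript's intron
# boundaries, with their signed distance and adjacent exon
splice_candidates <- function(model, transcript_id) {
  ex <- model_index(model, transcript_id)$exons
  out <- list()
  for (i in seq_len(nrow(ex) - 1)) {
    gap_lo <- ex$end[i] + 1L
    gap_hi <- ex$start[i + 1] - 1L
    if (gap_hi - gap_lo + 1L < 13L) next
    for (d in 1:6) {
      p_lo <- ex$end[i] + d       # just past the genomically-lower exon
      p_hi <- ex$start[i + 1] - d # just before the genomically-higher exon
      if (model$strand == "+") {
        out[[length(out) + 1]] <- data.frame(
          gpos = c(p_lo, p_hi), distance = c(d, -d),
          exon_id = c(ex$exon_id[i], ex$exon_id[i + 1]),
          stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1]] <- data.frame(
          gpos = c(p_lo, p_hi), distance = c(-d, d),
          exon_id = c(ex$exon_id[i], ex$exon_id[i + 1]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate a variant cohort over a gene model
#'
#' Plants exactly the configured number of variants of each consequence class
#' at positions that guarantee the class (stop-gain codons for nonsense, 1-2 bp
#' mid-exon indels for frameshift, exact intron distances for splice classes),
#' with allele counts from the configured frequency spectrum, multinomial
#' per-population counts, a PASS fraction, dataset roles (superset plus subset
#' call sets with planted subset-unique false positives), and per-site
#' coverage. Every draw is seeded; the truth table records each variant's
#' class, band, exon class, frequency class, false-positive flag and dataset
#' membership.
#' @param config a [sim_config()].
#' @param model the model from [simulate_gene_model()] with the same config.
#' @return list: `records_by_dataset` (named list of variant frames),
#'   `coverage`, `truth`, `config`.
#' @export
simulate_variants <- function(config, model) {
  set.seed(config$seed + 1000003L)
  ref_tx <- reference_transcript(model)
  novex_tx <- "tx_novex"
  pops <- config$populations
  AN <- 2L * sum(pops$size)
  eff_full <- snv_effect_table(model, ref_tx)
  eff_novex <- snv_effect_table(model, novex_tx)
  eff_novex <- eff_novex[eff_novex$exon_id == "EN1", , drop = FALSE]
  exon_ctx <- vapply(model$exons$exon_id, exon_class, character(1),
                     model = model, psi_threshold = config$psi_threshold)
  skipped_ids <- model$exons$exon_id[
    exon_ctx == "isoform_specific" & model$exons$exon_id != "EN1"]
  low_psi_ids <- model$exons$exon_id[exon_ctx == "low_psi"]
  const_ids <- model$exons$exon_id[
    exon_ctx == "all_transcripts" &
      model$exons$exon_id %in% model$transcripts[[ref_tx]]$exon_ids]
  used <- integer(0)   # genomic positions already touched
  variants <- list()
  add_variant <- function(pos, ref, alt, class, exon_id, truth_extra = list()) {
    rec <- c(list(pos = as.integer(pos), ref = ref, alt = alt, class = class,
                  exon_id = exon_id), truth_extra)
    variants[[length(variants) + 1L]] <<- rec
    used <<- c(used, seq.int(pos, pos + nchar(ref) + 1L))
  }
  # how many of an exonic class go to each context
  context_split <- function(count) {
    n_not <- round(config$frac_not_all * count)
    ctxs <- rep(c("novex", "skipped", "low_psi"), length.out = n_not)
    c(rep("constitutive", count - n_not), ctxs)
  }
  ctx_exons <- list(constitutive = const_ids, skipped = skipped_ids,
                    low_psi = low_psi_ids, novex = "EN1")
  plant_snv <- function(class, ctx) {
    # fall back through neighbouring contexts when a small exon runs out of
    # eligible codons; the truth label always reflects the exon actually used
    try_ctx <- unique(c(ctx, "skipped", "low_psi", "novex", "constitutive"))
    cand <- NULL
    for (ctx_i in try_ctx) {
      eff <- if (ctx_i == "novex") eff_novex else eff_full
      cand <- eff[eff$class == class & eff$exon_id %in% ctx_exons[[ctx_i]] &
                    !(eff$gpos %in% used), , drop = FALSE]
      if (nrow(cand)) break
    }
    if (!nrow(cand)) fail(sprintf(
      "not enough eligible positions for class %s in context %s", class, ctx),
      "sim_plant_error")
    row <- cand[sample.int(nrow(cand), 1), ]
    ref <- seq_at(model$sequence, model$locus_offset, row$gpos)
    alt <- if (model$strand == "-") comp_base(row$alt_coding) else row$alt_coding
    add_variant(row$gpos, ref, alt, class, row$exon_id)
  }
  plant_frameshift <- function(ctx) {
    # same fallback chain as plant_snv: a small exon can run out of free
    # indel windows, in which case neighbouring contexts absorb the variant
    try_ctx <- unique(c(ctx, "skipped", "low_psi", "novex", "constitutive"))
    for (ctx_i in try_ctx) {
      ex_ids <- ctx_exons[[ctx_i]]
      for (attempt in seq_len(120L)) {
        eid <- if (length(ex_ids) == 1) ex_ids else sample(ex_ids, 1)
        i <- match(eid, model$exons$exon_id)
        lo <- model$exons$start[i] + 8L
        hi <- model$exons$end[i] - 10L
        if (hi <= lo) next
        p <- sample(seq.int(lo, hi), 1)
        len <- sample(1:2, 1)
        if (stats::runif(1) < 0.5) {  # deletion
          ref <- seq_at(model$sequence, model$locus_offset, p, len + 1L)
          alt <- substr(ref, 1, 1)
        } else {                      # insertion
          ref <- seq_at(model$sequence, model$locus_offset, p)
          alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), len,
                                          replace = TRUE), collapse = ""))
        }
        rec <- normalize_variant(list(pos = p, ref = ref, alt = alt),
                                 model$sequence, model$locus_offset)
        # geometric guarantee of the class, independent of the classifier:
        # all changed bases strictly inside the exon body after left-alignment
        w_lo <- rec$pos; w_hi <- rec$pos + nchar(rec$ref) - 1L
        if (w_lo <= model$exons$start[i] || w_hi >= model$exons$end[i]) next
        if (any(seq.int(w_lo, w_hi + 1L) %in% used)) next
        add_variant(rec$pos, rec$ref, rec$alt, "frameshift", eid)
        return(invisible(NULL))
      }
    }
    fail(sprintf("not enough eligible indel windows for frameshift in context %s",
                 ctx), "sim_plant_error")
  }
  spl <- splice_candidates(model, ref_tx)
  spl <- spl[spl$exon_id %in% const_ids, , drop = FALSE]
  plant_splice <- function(class) {
    dmax <- if (class == "essential_splice") 2L else 6L
    dmin <- if (class == "essential_splice") 1L else 3L
    cand <- spl[abs(spl$distance) >= dmin & abs(spl$distance) <= dmax &
                  !(spl$gpos %in% used), , drop = FALSE]
    if (!nrow(cand)) fail(sprintf("not enough eligible positions for class %s",
                                  class), "sim_plant_error")
    row <- cand[sample.int(nrow(cand), 1), ]
    ref <- seq_at(model$sequence, model$locus_offset, row$gpos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    add_variant(row$gpos, ref, alt, class, row$exon_id,
                list(distance = row$distance))
  }
  cc <- config$class_counts
  for (class in names(cc)) {
    k <- cc[[class]]
    if (k == 0) next
    if (class %in% c("nonsense", "missense", "synonymous")) {
      for (ctx in context_split(k)) plant_snv(class, ctx)
    } else if (class == "frameshift") {
      for (ctx in context_split(k)) plant_frameshift(ctx)
    } else if (class %in% c("essential_splice", "splice_region")) {
      for (j in seq_len(k)) plant_splice(class)
    } else {
      fail(sprintf("unknown class in class_counts: %s", class),
           "sim_config_error")
    }
  }
  n_real <- length(variants)
  # planted subset-unique false positives (concordance-filter targets)
  fp_dataset <- character(0)
  for (ds in config$subsets) {
    for (j in seq_len(config$n_false_positives)) {
      cls <- if (j %% 2 == 0) "nonsense" else "frameshift"
      if (cls == "nonsense") plant_snv(cls, "constitutive")
      else plant_frameshift("constitutive")
      fp_dataset <- c(fp_dataset, ds)
    }
  }
  n_all <- length(variants)
  is_fp <- c(rep(FALSE, n_real), rep(TRUE, n_all - n_real))
  # allele counts from the AFS spec
  ac <- integer(n_all)
  for (i in seq_len(n_all)) {
    if (stats::runif(1) < config$singleton_fraction) {
      ac[i] <- 1L
    } else {
      af <- exp(stats::runif(1, log(config$low_freq_af_range[1]),
                             log(config$low_freq_af_range[2])))
      ac[i] <- max(2L, as.integer(round(af * AN)))
    }
  }
  w <- pops$size * pops$multiplier
  pop_ac <- vapply(seq_len(n_all), function(i) {
    stats::rmultinom(1, ac[i], w)[, 1]
  }, numeric(nrow(pops)))
  pass <- stats::runif(n_all) < config$pass_fraction
  qual <- round(stats::runif(n_all, 100, 3000))
  in_subset <- matrix(FALSE, n_all, length(config$subsets),
                      dimnames = list(NULL, config$subsets))
  for (s in config$subsets) {
    in_subset[seq_len(n_real), s] <- stats::runif(n_real) < config$subset_inclusion
  }
  for (i in which(is_fp)) in_subset[i, fp_dataset[i - n_real]] <- TRUE
  # coverage truth
  pos_all <- vapply(variants, function(v) v$pos, integer(1))
  upos <- sort(unique(pos_all))
  low_cov <- stats::runif(length(upos)) < config$coverage$low_frac
  depth <- ifelse(low_cov,
                  stats::runif(length(upos), 2, config$min_mean_depth - 1),
                  pmax(config$min_mean_depth,
                       stats::rnorm(length(upos), config$coverage$mean,
                                    config$coverage$sd)))
  depth <- round(depth, 1)
  coverage <- data.frame(chrom = model$chrom, pos = upos,
                         mean_depth = depth, stringsAsFactors = FALSE)
  for (t in c(10, 50)) {
    coverage[[paste0("ge_", t)]] <- round(
      1 - stats::pnorm(t, coverage$mean_depth, 15), 4)
  }
  # assemble records
  base <- data.frame(
    chrom = model$chrom, pos = pos_all, id = ".",
    ref = vapply(variants, function(v) v$ref, character(1)),
    alt = vapply(variants, function(v) v$alt, character(1)),
    qual = qual, filter_status = ifelse(pass, "PASS", "LowQual"),
    AC = ac, AN = AN, hom_count = 0L, stringsAsFactors = FALSE)
  for (p in seq_len(nrow(pops))) {
    base[[paste0("AC_", pops$label[p])]] <- as.integer(pop_ac[p, ])
    base[[paste0("AN_", pops$label[p])]] <- 2L * pops$size[p]
  }
  order_pos <- order(base$pos)
  records_by_dataset <- list()
  sup_rows <- which(!is_fp)
  records_by_dataset[[config$superset]] <- cbind(
    base[intersect(order_pos, sup_rows), , drop = FALSE],
    dataset = config$superset, stringsAsFactors = FALSE)
  for (s in config$subsets) {
    rows <- which(in_subset[, s])
    records_by_dataset[[s]] <- cbind(
      base[intersect(order_pos, rows), , drop = FALSE],
      dataset = s, stringsAsFactors = FALSE)
  }
  records_by_dataset <- lapply(records_by_dataset, function(d) {
    rownames(d) <- NULL
    d[c(setdiff(names(d), grep("^A[CN]_", names(d), value = TRUE)),
        grep("^A[CN]_", names(d), value = TRUE))]
  })
  ctx_label <- c(all_transcripts = "all_transcripts",
                 isoform_specific = "isoform_specific", low_psi = "low_psi")
  truth <- data.frame(
    key = paste(model$chrom, base$pos, base$ref, base$alt, sep = ":"),
    pos = base$pos,
    class = vapply(variants, function(v) v$class, character(1)),
    band = band_of(model, base$pos),
    exon_id = vapply(variants, function(v) v$exon_id, character(1)),
    exon_class = ctx_label[exon_ctx[vapply(variants, function(v) v$exon_id,
                                           character(1))]],
    splice_distance = vapply(variants, function(v) {
      if (is.null(v$distance)) NA_integer_ else as.integer(v$distance)
    }, integer(1)),
    AC = ac, AN = AN,
    afs_class = afs_class(ac, AN),
    fp = is_fp, pass = pass,
    depth_low = low_cov[match(base$pos, upos)],
    datasets = vapply(seq_len(n_all), function(i) {
      ds <- c(if (!is_fp[i]) config$superset,
              config$subsets[in_subset[i, ]])
      paste(ds, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(records_by_dataset = records_by_dataset, coverage = coverage,
       truth = truth, config = config)
}

#' Simulate a full bundle (model + cohorts) in one call
#' @param config a [sim_config()].
#' @return list with `model` plus everything [simulate_variants()] returns.
#' @export
simulate_cohort <- function(config = sim_config()) {
  model <- simulate_gene_model(config)
  c(list(model = model), simulate_variants(config, model))
}

#' Write a simulation bundle to disk
#'
#' Layout: `model.json` + `model.fa`, one `cohort_<dataset>.vcf` per call set,
#' `coverage.tsv`, `truth.tsv`, `simconfig.yaml` (the config echoed back).
#' Identical config (including seed) produces byte-identical files.
#' @param sim output of [simulate_cohort()] (or [simulate_variants()] plus a
#'   `model` element).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_model(sim$model, dir, "model")
  for (ds in names(sim$records_by_dataset)) {
    write_vcf(sim$records_by_dataset[[ds]],
              file.path(dir, sprintf("cohort_%s.vcf", ds)))
  }
  write_coverage(sim$coverage, file.path(dir, "coverage.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  cfg$populations <- as.list(stats::setNames(
    paste(sim$config$populations$size, sim$config$populations$multiplier,
          sep = "x"), sim$config$populations$label))
  yaml::write_yaml(cfg, file.path(dir, "simconfig.yaml"))
  invisible(dir)
}
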