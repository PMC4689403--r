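# In-code fixtures: tiny deterministic models and small random models for
# brute-force oracles. Nothing here touches disk except via tempdir().

# single-transcript, single-exon model whose CDS is exactly `cds` (plus-strand)
# or its reverse complement placed so the translated CDS is still `cds`
# (minus-strand). The exon sits at genomic 101..(100 + nchar(cds)).
tiny_model <- function(cds = "ATGCGATAA", strand = "+") {
  stopifnot(nchar(cds) %% 3 == 0)
  pad5 <- strrep("A", 100)
  pad3 <- strrep("A", 50)
  body <- if (strand == "+") cds else revcomp(cds)
  seqn <- paste0(pad5, body, pad3)
  ex <- data.frame(exon_id = "E01", start = 101L,
                   end = 100L + nchar(cds), stringsAsFactors = FALSE)
  gene_model(
    gene = "TOY", chrom = "chrT", strand = strand, locus_offset = 1L,
    sequence = seqn, exons = ex,
    transcripts = list(list(transcript_id = "tx1", name = "only",
                            exon_ids = "E01", cds_start = 101L,
                            cds_end = 100L + nchar(cds))),
    bands = data.frame(band = "A", start = 101L, end = 100L + nchar(cds),
                       stringsAsFactors = FALSE),
    psi = c(E01 = 1.0))
}

# random two-exon single-transcript model for coordinate-mapping oracles
random_two_exon_model <- function(seed, strand = "+") {
  set.seed(seed)
  len1 <- 3L * sample(4:12, 1)
  len2 <- 3L * sample(4:12, 1)
  gap <- sample(20:60, 1)
  start1 <- 51L
  end1 <- start1 + len1 - 1L
  start2 <- end1 + gap + 1L
  end2 <- start2 + len2 - 1L
  seqn <- paste(sample(c("A", "C", "G", "T"), end2 + 40L, replace = TRUE),
                collapse = "")
  gene_model(
    gene = "RND", chrom = "chrR", strand = strand, locus_offset = 1L,
    sequence = seqn,
    exons = data.frame(exon_id = c("E1", "E2"), start = c(start1, start2),
                       end = c(end1, end2), stringsAsFactors = FALSE),
    transcripts = list(list(transcript_id = "tx1", name = "only",
                            exon_ids = c("E1", "E2"), cds_start = start1,
                            cds_end = end2)),
    bands = data.frame(band = c("I", "A"), start = c(start1, start2 - 5L),
                       end = c(start2 - 6L, end2), stringsAsFactors = FALSE),
    psi = c(E1 = 1.0, E2 = 1.0))
}

# brute-force genomic->CDS map: walk every exon base in genomic order and
# number them in translation order
brute_force_cds_map <- function(model, transcript_id) {
  tx <- model$transcripts[[transcript_id]]
  ex <- model$exons[match(tx$exon_ids, model$exons$exon_id), ]
  gpos <- integer(0)
  for (i in seq_len(nrow(ex))) {
    for (p in ex$start[i]:ex$end[i]) {
      if (p >= tx$cds_start && p <= tx$cds_end) gpos <- c(gpos, p)
    }
  }
  gpos <- sort(gpos)
  if (model$strand == "-") gpos <- rev(gpos)
  stats::setNames(seq_along(gpos), gpos)
}

# mirror a whole model bundle: reverse-complement the sequence and flip all
# coordinates, so plus-strand models become equivalent minus-strand models
flip_model <- function(model) {
  L <- nchar(model$sequence)
  lo <- model$locus_offset
  hi <- lo + L - 1L
  mirror <- function(p) lo + (hi - p)
  ex <- model$exons
  ex2 <- data.frame(exon_id = ex$exon_id, start = mirror(ex$end),
                    end = mirror(ex$start), stringsAsFactors = FALSE)
  ex2 <- ex2[order(ex2$start), ]
  rownames(ex2) <- NULL
  txs <- lapply(model$transcripts, function(tx) {
    sub <- ex2[match(tx$exon_ids, ex2$exon_id), ]
    list(transcript_id = tx$transcript_id, name = tx$name,
         exon_ids = sub$exon_id[order(sub$start)],
         cds_start = mirror(tx$cds_end), cds_end = mirror(tx$cds_start))
  })
  bd <- model$bands
  bd2 <- data.frame(band = bd$band, start = mirror(bd$end),
                    end = mirror(bd$start), stringsAsFactors = FALSE)
  gene_model(model$gene, model$chrom,
             if (model$strand == "+") "-" else "+",
             lo, revcomp(model$sequence), ex2, unname(txs), bd2, model$psi)
}

mirror_pos <- function(model, p) {
  model$locus_offset + (model$locus_offset + nchar(model$sequence) - 1L - p)
}

# apply a ref->alt edit to a sequence string (1-based genomic coordinates)
apply_edit <- function(sequence, locus_offset, pos, ref, alt) {
  i <- pos - locus_offset + 1L
  stopifnot(substr(sequence, i, i + nchar(ref) - 1L) == ref)
  paste0(substr(sequence, 1, i - 1L), alt,
         substr(sequence, i + nchar(ref), nchar(sequence)))
}

# small fast config for simulation-driven tests
test_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             class_counts = c(nonsense = 12L, frameshift = 8L,
                              essential_splice = 4L, splice_region = 8L,
                              missense = 12L, synonymous = 12L),
             n_false_positives = 3L, ...)
}
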