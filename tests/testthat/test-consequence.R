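snv_rec <- function(pos, ref, alt, dataset = "T") {
  data.frame(chrom = "chrT", pos = as.integer(pos), id = ".", ref = ref,
             alt = alt, qual = 100, filter_status = "PASS", AC = 1L,
             AN = 1000L, hom_count = 0L, dataset = dataset,
             stringsAsFactors = FALSE)
}

test_that("CGA to TGA is called nonsense R/* with the right codon fields", {
  m <- tiny_model("ATGCGATAA")
  call <- classify_variant(m, snv_rec(104L, "C", "T"))
  expect_identical(call$consequence_class, "nonsense")
  expect_identical(call$aa_change, "R/*")
  expect_identical(call$ref_codon, "CGA")
  expect_identical(call$alt_codon, "TGA")
  expect_identical(call$codon_pos, 1L)
  expect_identical(call$band, "A")
  expect_true(is_ttntv(call))
  # same change on the mirrored minus-strand model
  mm <- tiny_model("ATGCGATAA", strand = "-")
  pos_m <- 101L + (109L - 104L)  # mirrored coordinate within the exon
  call_m <- classify_variant(mm, snv_rec(pos_m, "G", "A"))
  expect_identical(call_m$consequence_class, "nonsense")
  expect_identical(call_m$aa_change, "R/*")
  expect_identical(call_m$alt_codon, "TGA")
})

test_that("synonymous, missense and stop-loss fall into the right buckets", {
  m <- tiny_model("ATGCGATAA")
  # CGA -> CGG: both arginine
  expect_identical(classify_variant(m, snv_rec(106L, "A", "G"))$consequence_class,
                   "synonymous")
  # CGA -> CAA: R -> Q
  expect_identical(classify_variant(m, snv_rec(105L, "G", "A"))$consequence_class,
                   "missense")
  # TAA -> CAA: stop-loss maps to the missense bucket
  expect_identical(classify_variant(m, snv_rec(107L, "T", "C"))$consequence_class,
                   "missense")
})

test_that("indels are split into frameshift and in-frame by length", {
  m <- tiny_model(strrep("ATGCGACTGGAATCC", 3L))  # 45 bp CDS
  seqn <- m$sequence
  del1 <- snv_rec(110L, seq_at(seqn, 1L, 110L, 2L), seq_at(seqn, 1L, 110L, 1L))
  expect_identical(classify_variant(m, del1)$consequence_class, "frameshift")
  del3 <- snv_rec(110L, seq_at(seqn, 1L, 110L, 4L), seq_at(seqn, 1L, 110L, 1L))
  expect_identical(classify_variant(m, del3)$consequence_class, "inframe_indel")
  ins2 <- snv_rec(110L, seq_at(seqn, 1L, 110L, 1L),
                  paste0(seq_at(seqn, 1L, 110L, 1L), "AT"))
  expect_identical(classify_variant(m, ins2)$consequence_class, "frameshift")
})

test_that("splice distances are signed, strand-aware and windowed to 6 bp", {
  m <- random_two_exon_model(3, "+")
  e1_end <- m$exons$end[1]
  e2_start <- m$exons$start[2]
  expect_identical(splice_distance(m, e1_end + 1L, "tx1"), 1L)   # donor +1
  expect_identical(splice_distance(m, e2_start - 3L, "tx1"), -3L) # acceptor -3
  expect_true(is.na(splice_distance(m, e1_end + 7L, "tx1")))
  expect_true(is.na(splice_distance(m, e1_end, "tx1")))  # exonic
  expect_error(splice_distance(m, e1_end + 1L, "nope"),
               class = "unknown_transcript_error")
  # strand-reversal oracle: mirror the model and re-run the plus-strand rule
  mf <- flip_model(m)
  for (g in c(e1_end + 1L, e1_end + 2L, e2_start - 1L, e2_start - 4L)) {
    expect_identical(splice_distance(mf, mirror_pos(m, g), "tx1"),
                     splice_distance(m, g, "tx1"))
  }
})

test_that("splice consequence classes follow the distance windows", {
  m <- random_two_exon_model(5, "+")
  seqn <- m$sequence
  mk <- function(p) {
    ref <- seq_at(seqn, 1L, p)
    snv_rec(p, ref, setdiff(c("A", "C", "G", "T"), ref)[1])
  }
  e1_end <- m$exons$end[1]
  expect_identical(classify_variant(m, mk(e1_end + 2L))$consequence_class,
                   "essential_splice")
  expect_identical(classify_variant(m, mk(e1_end + 5L))$consequence_class,
                   "splice_region")
  expect_identical(classify_variant(m, mk(e1_end + 12L))$consequence_class,
                   "intronic")
  expect_true(is_ttntv("essential_splice"))
  expect_false(is_ttntv("splice_region"))
  expect_false(is_ttntv("missense"))
})

test_that("classifier agrees with simulator truth on clean cohorts", {
  for (strand in c("+", "-")) {
    sim <- simulate_cohort(test_sim_config(seed = 31, strand = strand))
    recs <- normalize_variants(sim$records_by_dataset$EXAC, sim$model)
    ann <- classify_variants(sim$model, recs)
    tr <- sim$truth[match(ann$key, sim$truth$key), ]
    expect_identical(ann$consequence_class, tr$class)
    expect_identical(ann$exon_class[!is.na(ann$exon_class)],
                     tr$exon_class[!is.na(ann$exon_class)])
    sp <- !is.na(tr$splice_distance)
    expect_identical(ann$splice_distance[sp], tr$splice_distance[sp])
    # surviving annotation invariants: band defined for all exonic calls
    expect_false(anyNA(ann$band[ann$consequence_class == "nonsense"]))
  }
})

test_that("SNV classes match an edit-and-translate oracle", {
  sim <- simulate_cohort(test_sim_config(seed = 33))
  m <- sim$model
  ref_tx <- reference_transcript(m)
  map <- genomic_to_cds(m, ref_tx, seq(m$locus_offset,
                                       m$locus_offset + nchar(m$sequence) - 1L))
  recs <- sim$records_by_dataset$EXAC
  snvs <- recs[nchar(recs$ref) == 1 & nchar(recs$alt) == 1, ]
  cseq <- cds_sequence(m, ref_tx)
  ref_prot <- as.character(Biostrings::translate(Biostrings::DNAString(cseq),
                                                 no.init.codon = TRUE))
  for (i in seq_len(nrow(snvs))) {
    cds_pos <- genomic_to_cds(m, ref_tx, snvs$pos[i])
    if (is.na(cds_pos)) next
    alt_c <- if (m$strand == "-") comp_base(snvs$alt[i]) else snvs$alt[i]
    mut <- cseq
    substr(mut, cds_pos, cds_pos) <- alt_c
    mut_prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(mut), no.init.codon = TRUE, if.fuzzy.codon = "X"))
    ci <- (cds_pos - 1) %/% 3 + 1
    call <- classify_variant(m, snvs[i, ])
    gained_stop <- substr(mut_prot, ci, ci) == "*" &&
      substr(ref_prot, ci, ci) != "*"
    expect_identical(call$consequence_class == "nonsense", gained_stop,
                     info = snvs$pos[i])
  }
})

test_that("classification is invariant under a whole-model strand flip", {
  sim <- simulate_cohort(test_sim_config(seed = 35))
  m <- sim$model
  mf <- flip_model(m)
  recs <- sim$records_by_dataset$EXAC
  snvs <- recs[nchar(recs$ref) == 1 & nchar(recs$alt) == 1, ]
  snvs <- snvs[sample.int(nrow(snvs), 25), ]
  for (i in seq_len(nrow(snvs))) {
    call <- classify_variant(m, snvs[i, ])
    rec_f <- snvs[i, ]
    rec_f$pos <- mirror_pos(m, snvs$pos[i])
    rec_f$ref <- comp_base(snvs$ref[i])
    rec_f$alt <- comp_base(snvs$alt[i])
    call_f <- classify_variant(mf, rec_f)
    expect_identical(call_f$consequence_class, call$consequence_class)
    expect_identical(call_f$band, call$band)
    expect_identical(call_f$affects_all, call$affects_all)
  }
})

test_that("variants in isoform-specific exons are still called by severity", {
  sim <- simulate_cohort(test_sim_config(seed = 36))
  m <- sim$model
  tr <- sim$truth
  novex <- tr[tr$exon_id == "EN1" & tr$class == "nonsense", ]
  expect_gt(nrow(novex), 0)  # the round-robin context split always plants some
  rec <- sim$records_by_dataset$EXAC
  rec <- rec[paste(rec$chrom, rec$pos, rec$ref, rec$alt, sep = ":") %in%
               novex$key, ][1, ]
  call <- classify_variant(m, rec)
  expect_identical(call$consequence_class, "nonsense")
  expect_identical(call$transcript_hits, "tx_novex")
  expect_false(call$affects_all)
  expect_identical(call$exon_class, "isoform_specific")
})
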