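write_test_vcf <- function(lines) {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", lines), p)
  p
}

test_that("multi-allelic sites decompose into per-allele records", {
  p <- write_test_vcf(
    "chr2\t100\t.\tG\tA,T\t500\tPASS\tAC=5,2;AN=1000;Hom=1,0;AC_EUR=3,1;AN_EUR=400")
  df <- read_vcf(p, dataset = "D")
  expect_identical(nrow(df), 2L)
  expect_identical(df$AC, c(5L, 2L))
  expect_identical(df$alt, c("A", "T"))
  expect_identical(df$hom_count, c(1L, 0L))
  expect_identical(df$AC_EUR, c(3L, 1L))
  expect_identical(df$AN_EUR, c(400L, 400L))
  expect_identical(unique(df$dataset), "D")
})

test_that("empty bodies, missing INFO keys and malformed records are handled", {
  p <- write_test_vcf(character(0))
  expect_identical(nrow(read_vcf(p)), 0L)
  p2 <- write_test_vcf("chr2\t100\t.\tG\tA\t500\tPASS\tAN=1000")
  expect_error(read_vcf(p2), class = "vcf_record_error")
  p3 <- write_test_vcf("chr2\t100\tbroken")
  expect_error(read_vcf(p3), class = "vcf_parse_error", regexp = "line 3")
  # absent Hom defaults to zero with a warning
  p4 <- write_test_vcf("chr2\t100\t.\tG\tA\t500\tPASS\tAC=5;AN=1000")
  expect_warning(df <- read_vcf(p4), regexp = "Hom")
  expect_identical(df$hom_count, 0L)
})

test_that("simulator VCFs round-trip through the reader", {
  sim <- simulate_cohort(test_sim_config(seed = 21))
  d <- withr::local_tempdir()
  write_sim_bundle(sim, d)
  for (ds in names(sim$records_by_dataset)) {
    orig <- sim$records_by_dataset[[ds]]
    back <- suppressWarnings(
      read_vcf(file.path(d, sprintf("cohort_%s.vcf", ds)), dataset = ds))
    expect_identical(nrow(back), nrow(orig))
    for (col in c("chrom", "pos", "ref", "alt", "filter_status", "AC", "AN",
                  "hom_count", grep("^AC_", names(orig), value = TRUE))) {
      expect_equal(back[[col]], orig[[col]], info = paste(ds, col))
    }
  }
  # region restriction subsets by position
  rng <- range(sim$records_by_dataset$EXAC$pos)
  reg <- sprintf("chrS:%d-%d", rng[1], rng[1] + 500L)
  sub <- read_vcf(file.path(d, "cohort_EXAC.vcf"), region = reg)
  expect_true(all(sub$pos <= rng[1] + 500L))
  expect_identical(nrow(sub),
                   sum(sim$records_by_dataset$EXAC$pos <= rng[1] + 500L))
})

test_that("SNVs are already minimal and degenerate alleles error", {
  seqn <- paste0(strrep("T", 20), "GCACACAT", strrep("T", 20))
  rec <- normalize_variant(list(pos = 24L, ref = "C", alt = "T"), seqn, 1L)
  expect_identical(rec$pos, 24L)
  expect_identical(rec$ref, "C")
  expect_error(
    normalize_variant(list(pos = 22L, ref = "CA", alt = "CA"), seqn, 1L),
    class = "normalization_error")
  expect_error(
    normalize_variant(list(pos = 22L, ref = "G", alt = "T"), seqn, 1L),
    class = "reference_mismatch_error")
})

test_that("deletions left-align to the leftmost equivalent representation", {
  # ...GCACACAT...: a CACA>CA deletion slides to the leftmost AC repeat
  seqn <- paste0(strrep("T", 20), "GCACACAT", strrep("T", 20))
  rec <- normalize_variant(list(pos = 22L, ref = "CACA", alt = "CA"), seqn, 1L)
  # enumeration oracle: leftmost 2-base deletion giving the same haplotype
  hap <- apply_edit(seqn, 1L, 22L, "CACA", "CA")
  found <- NULL
  for (p in 2:(nchar(seqn) - 2)) {
    cand_ref <- substr(seqn, p, p + 2)
    cand_alt <- substr(seqn, p, p)
    if (identical(apply_edit(seqn, 1L, p, cand_ref, cand_alt), hap)) {
      found <- list(pos = p, ref = cand_ref, alt = cand_alt)
      break
    }
  }
  expect_identical(rec[c("pos", "ref", "alt")],
                   list(pos = found$pos, ref = found$ref, alt = found$alt))
  # idempotent
  again <- normalize_variant(rec, seqn, 1L)
  expect_identical(again, rec)
})

test_that("normalization is idempotent and haplotype-preserving on random indels", {
  set.seed(42)
  m <- simulate_gene_model(test_sim_config(seed = 22))
  seqn <- m$sequence
  off <- m$locus_offset
  for (i in 1:150) {
    p <- sample(seq(off + 50L, off + nchar(seqn) - 60L), 1)
    L <- sample(1:4, 1)
    if (runif(1) < 0.5) {
      ref <- seq_at(seqn, off, p, L + 1L)
      alt <- substr(ref, 1, 1)
    } else {
      ref <- seq_at(seqn, off, p)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                               collapse = ""))
    }
    # pad with shared flanking bases to make the representation non-minimal
    pad <- seq_at(seqn, off, p + nchar(ref), 2L)
    rec0 <- list(pos = p, ref = paste0(ref, pad), alt = paste0(alt, pad))
    rec1 <- normalize_variant(rec0, seqn, off)
    rec2 <- normalize_variant(rec1, seqn, off)
    expect_identical(rec2, rec1)
    hap0 <- apply_edit(seqn, off, rec0$pos, rec0$ref, rec0$alt)
    hap1 <- apply_edit(seqn, off, rec1$pos, rec1$ref, rec1$alt)
    expect_identical(hap1, hap0)
    # minimality: no shared flanks left unless protecting an empty allele
    if (nchar(rec1$ref) > 1 && nchar(rec1$alt) > 1) {
      expect_false(substr(rec1$ref, nchar(rec1$ref), nchar(rec1$ref)) ==
                     substr(rec1$alt, nchar(rec1$alt), nchar(rec1$alt)))
    }
  }
})

test_that("variant keys identify normalized alleles across datasets", {
  a <- data.frame(chrom = "chr2", pos = 10L, ref = "C", alt = "T",
                  dataset = "X", stringsAsFactors = FALSE)
  b <- a; b$dataset <- "Y"
  expect_identical(variant_key(a), variant_key(b))
  ins <- a; ins$ref <- "C"; ins$alt <- "CT"
  expect_false(variant_key(a) == variant_key(ins))
})

test_that("coverage tables round-trip and monotonicity is enforced", {
  df <- data.frame(chrom = "chr2", pos = c(100L, 101L),
                   mean_depth = c(62.1, 8.0),
                   ge_10 = c(1.0, 0.4), ge_50 = c(0.93, 0.01))
  p <- tempfile(fileext = ".tsv")
  write_coverage(df, p)
  back <- read_coverage(p)
  expect_equal(back, df)
  bad <- df; bad$ge_50[1] <- 1.5  # above ge_10: impossible
  write_coverage(bad, p)
  expect_error(read_coverage(p), class = "coverage_validation_error")
  # empty file with header
  write_coverage(df[0, ], p)
  expect_identical(nrow(read_coverage(p)), 0L)
})
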