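#' Read site-level variants from a VCF subset
#'
#' Reads the VCF v4.2 subset used throughout the package: site records with
#' INFO keys `AC`, `AN`, optional `Hom` and per-population `AC_<POP>` /
#' `AN_<POP>`. Multi-allelic sites are decomposed into one record per alternate
#' allele, with per-allele `AC`/`Hom`/`AC_<POP>`. No genotype columns are
#' required: summary counts drive all downstream analysis.
#'
#' @param path VCF file path (plain text).
#' @param region optional `"chrom:start-end"` restriction.
#' @param dataset dataset tag stored in the `dataset` column (default: file
#'   basename without extension).
#' @return data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`, `qual`,
#'   `filter_status`, `AC`, `AN`, `hom_count`, `dataset`, plus any per-population
#'   `AC_*` / `AN_*` columns found in the file, ordered by (chrom, pos).
#' @export
read_vcf <- function(path, region = NULL, dataset = NULL) {
  if (!file.exists(path)) fail(sprintf("VCF not found: %s", path),
                               "missing_file_error")
  if (is.null(dataset)) dataset <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  bad <- body_idx[vapply(strsplit(lines[body_idx], "\t", fixed = TRUE),
                         length, integer(1)) < 8L]
  if (length(bad)) {
    fail(sprintf("malformed VCF record at line %d (fewer than 8 fields)", bad[1]),
         "vcf_parse_error")
  }
  if (!length(body_idx)) return(empty_variant_frame(dataset))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  out <- list()
  for (i in seq_len(nrow(fix))) {
    info <- parse_info(fix[i, "INFO"])
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    if (!all(c("AC", "AN") %in% names(info))) {
      fail(sprintf("site %s:%s lacks AC/AN INFO fields",
                   fix[i, "CHROM"], fix[i, "POS"]), "vcf_record_error")
    }
    ac <- as.integer(strsplit(info[["AC"]], ",", fixed = TRUE)[[1]])
    an <- as.integer(info[["AN"]])
    hom <- if ("Hom" %in% names(info)) {
      as.integer(strsplit(info[["Hom"]], ",", fixed = TRUE)[[1]])
    } else {
      warning(sprintf("site %s:%s has no Hom field; homozygote count set to 0",
                      fix[i, "CHROM"], fix[i, "POS"]), call. = FALSE)
      rep(0L, n_alt)
    }
    pop_keys <- grep("^(AC|AN)_", names(info), value = TRUE)
    for (a in seq_len(n_alt)) {
      rec <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        id = ifelse(is.na(fix[i, "ID"]), ".", fix[i, "ID"]),
        ref = fix[i, "REF"], alt = alts[a],
        qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
        filter_status = ifelse(is.na(fix[i, "FILTER"]), ".", fix[i, "FILTER"]),
        AC = ac[a], AN = an, hom_count = hom[a],
        dataset = dataset, stringsAsFactors = FALSE
      )
      for (k in pop_keys) {
        v <- strsplit(info[[k]], ",", fixed = TRUE)[[1]]
        rec[[k]] <- as.integer(if (startsWith(k, "AC_")) v[a] else v[1])
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  df <- do.call(rbind_fill, out)
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):(\\d+)-(\\d+)$", region))[[1]]
    if (length(m) != 4) fail(sprintf("bad region '%s'", region), "region_error")
    df <- df[df$chrom == m[2] & df$pos >= as.integer(m[3]) &
               df$pos <= as.integer(m[4]), , drop = FALSE]
  }
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  validate_variant_frame(df)
  df
}

parse_info <- function(info) {
  if (is.na(info) || info == "." || !nzchar(info)) return(character())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1))
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  vals
}

empty_variant_frame <- function(dataset = character(0)) {
  data.frame(chrom = character(0), pos = integer(0), id = character(0),
             ref = character(0), alt = character(0), qual = numeric(0),
             filter_status = character(0), AC = integer(0), AN = integer(0),
             hom_count = integer(0), dataset = character(0),
             stringsAsFactors = FALSE)
}

# rbind data.frames whose column sets may differ (missing columns become NA)
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[cols]
  })
  do.call(rbind, dfs)
}

validate_variant_frame <- function(df) {
  if (!nrow(df)) return(invisible(df))
  if (any(df$AC > df$AN)) fail("variant with AC > AN", "variant_invariant_error")
  if (any(2L * df$hom_count > df$AC)) {
    fail("variant with 2*hom_count > AC", "variant_invariant_error")
  }
  if (any(df$ref == df$alt)) fail("variant with ref == alt", "variant_invariant_error")
  invisible(df)
}

#' Write site-level variants as a plain-text VCF
#'
#' Emits the same VCF v4.2 subset [read_vcf()] consumes; reading the output
#' back reproduces all fields used downstream.
#' @param df variant data.frame (see [read_vcf()] for columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(df, path) {
  pop_keys <- grep("^(AC|AN)_", names(df), value = TRUE)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total allele number\">",
    "##INFO=<ID=Hom,Number=A,Type=Integer,Description=\"Homozygous-alternate individual count\">"
  )
  for (k in pop_keys) {
    hdr <- c(hdr, sprintf(
      "##INFO=<ID=%s,Number=%s,Type=Integer,Description=\"%s for population %s\">",
      k, if (startsWith(k, "AC_")) "A" else "1",
      if (startsWith(k, "AC_")) "Allele count" else "Allele number",
      sub("^A[CN]_", "", k)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    info <- sprintf("AC=%d;AN=%d;Hom=%d", df$AC[i], df$AN[i], df$hom_count[i])
    for (k in pop_keys) info <- paste0(info, ";", k, "=", df[[k]][i])
    recs[i] <- paste(
      df$chrom[i], df$pos[i], df$id[i], df$ref[i], df$alt[i],
      ifelse(is.na(df$qual[i]), ".", format(df$qual[i], scientific = FALSE)),
      df$filter_status[i], info, sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Normalize one variant to its left-aligned minimal representation
#'
#' Trims the shared suffix, then the shared prefix, shifting indels left while
#' the flanking sequence allows (the standard left-alignment algorithm).
#' Idempotent; preserves the edited haplotype sequence.
#'
#' @param rec one-row variant data.frame or list with `pos`, `ref`, `alt`.
#' @param sequence locus sequence the variant lies on.
#' @param locus_offset genomic position of the first base of `sequence`.
#' @return `rec` with `pos`, `ref`, `alt` normalized.
#' @export
normalize_variant <- function(rec, sequence, locus_offset) {
  pos <- as.integer(rec$pos)
  ref <- rec$ref
  alt <- rec$alt
  have <- seq_at(sequence, locus_offset, pos, nchar(ref))
  if (!identical(have, ref)) {
    fail(sprintf("reference mismatch at pos %d: file says '%s', sequence has '%s'",
                 pos, ref, have), "reference_mismatch_error")
  }
  repeat {
    changed <- FALSE
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 && (nr > 1 || na > 1) &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1, nr - 1L)
      alt <- substr(alt, 1, na - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0 || nchar(alt) == 0) {
      if (pos - 1L < locus_offset) {
        fail("variant cannot be left-aligned: locus boundary reached",
             "normalization_error")
      }
      b <- seq_at(sequence, locus_offset, pos - 1L)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  while (nchar(ref) >= 2 && nchar(alt) >= 2 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) fail("ref equals alt after trimming", "normalization_error")
  rec$pos <- pos; rec$ref <- ref; rec$alt <- alt
  rec
}

#' Normalize every variant in a frame against a gene model's sequence
#' @param df variant data.frame.
#' @param model a `gene_model`.
#' @return the frame with normalized `pos`/`ref`/`alt`.
#' @export
normalize_variants <- function(df, model) {
  if (!nrow(df)) return(df)
  for (i in seq_len(nrow(df))) {
    n <- normalize_variant(df[i, ], model$sequence, model$locus_offset)
    df$pos[i] <- n$pos; df$ref[i] <- n$ref; df$alt[i] <- n$alt
  }
  df
}

#' Canonical variant key
#'
#' Equal keys identify the same normalized allele; all cross-dataset set
#' operations are keyed this way.
#' @param df variant data.frame (or any frame with `chrom`, `pos`, `ref`, `alt`).
#' @return character vector `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(df) {
  if (!nrow(df)) return(character(0))
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Read per-position coverage
#'
#' Tab-separated with columns `chrom`, `pos`, `mean_depth`, then one `ge_<t>`
#' column per depth threshold holding the fraction of samples covered at >= t;
#' fractions must be non-increasing in the threshold.
#' @param path TSV path (a leading `#` on the header line is tolerated).
#' @return data.frame, one row per position.
#' @export
read_coverage <- function(path) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "#")) {
    lines[1] <- sub("^#\\s*", "", lines[1])
  }
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  ge_cols <- grep("^ge_", names(df), value = TRUE)
  thr <- as.numeric(sub("^ge_", "", ge_cols))
  ge_cols <- ge_cols[order(thr)]
  if (length(ge_cols) > 1 && nrow(df)) {
    m <- as.matrix(df[, ge_cols, drop = FALSE])
    if (any(m[, -1, drop = FALSE] > m[, -ncol(m), drop = FALSE] + 1e-12)) {
      fail("coverage frac_ge fractions increase with depth threshold",
           "coverage_validation_error")
    }
  }
  df
}

#' Write per-position coverage
#' @param df coverage data.frame as returned by [read_coverage()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
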