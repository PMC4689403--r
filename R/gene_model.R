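#' Gene model container
#'
#' A self-contained description of one multi-isoform gene: its locus sequence,
#' exons, transcripts (fully coding between `cds_start` and `cds_end`), sarcomere
#' band intervals (Z/I/A/M, genomic spans), and per-exon proportion-spliced-in
#' (PSI) values. All coordinates are 1-based inclusive genomic positions on the
#' chromosome named by `chrom`; `locus_offset` is the genomic position of the
#' first base of `sequence`.
#'
#' @param gene gene symbol.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`; for `"-"` the coding sequence is read from the
#'   genomically last exon base backwards, complemented.
#' @param locus_offset genomic position of the first base of `sequence`.
#' @param sequence locus nucleotide sequence (single string over A/C/G/T).
#' @param exons data.frame with columns `exon_id`, `start`, `end`.
#' @param transcripts list of lists with fields `transcript_id`, `name`,
#'   `exon_ids` (ordered by genomic position), `cds_start`, `cds_end`.
#' @param bands data.frame with columns `band` (one of Z/I/A/M), `start`, `end`.
#' @param psi named numeric vector, one PSI value in \[0,1\] per exon.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene, chrom, strand, locus_offset, sequence,
                       exons, transcripts, bands, psi) {
  names(transcripts) <- vapply(transcripts, `[[`, character(1), "transcript_id")
  model <- structure(
    list(
      gene = gene, chrom = chrom, strand = strand,
      locus_offset = as.integer(locus_offset), sequence = sequence,
      exons = exons, transcripts = transcripts, bands = bands, psi = psi
    ),
    class = "gene_model"
  )
  validate_gene_model(model)
  attr(model, "index") <- build_model_index(model)
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s (%s%s)  locus %d-%d  %d exons, %d transcripts, %d bands\n",
    x$gene, x$chrom, x$strand, x$locus_offset,
    x$locus_offset + nchar(x$sequence) - 1L,
    nrow(x$exons), length(x$transcripts), nrow(x$bands)
  ))
  invisible(x)
}

#' Validate all gene-model invariants
#'
#' Stops with an error naming the violated invariant.
#' @param model a `gene_model`.
#' @return the model, invisibly.
#' @export
validate_gene_model <- function(model) {
  if (!model$strand %in% c("+", "-")) {
    fail("strand must be '+' or '-'", "model_validation_error")
  }
  if (grepl("[^ACGT]", model$sequence)) {
    fail("sequence contains characters outside {A,C,G,T}", "model_validation_error")
  }
  ex <- model$exons
  if (anyDuplicated(ex$exon_id)) {
    fail("exon_ids are not unique within the gene model", "model_validation_error")
  }
  if (any(ex$start > ex$end)) {
    fail("exon start > end", "model_validation_error")
  }
  locus_end <- model$locus_offset + nchar(model$sequence) - 1L
  if (any(ex$start < model$locus_offset) || any(ex$end > locus_end)) {
    fail("exon outside locus sequence bounds", "model_validation_error")
  }
  for (tx in model$transcripts) {
    sub <- ex[match(tx$exon_ids, ex$exon_id), , drop = FALSE]
    if (anyNA(sub$start)) {
      fail(sprintf("transcript %s references unknown exon_id", tx$transcript_id),
           "model_validation_error")
    }
    o <- order(sub$start)
    if (!identical(o, seq_len(nrow(sub)))) {
      fail(sprintf("transcript %s exons not ordered by genomic position",
                   tx$transcript_id), "model_validation_error")
    }
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      fail(sprintf("transcript %s exons overlap", tx$transcript_id),
           "model_validation_error")
    }
    in_exon <- function(p) any(sub$start <= p & p <= sub$end)
    if (!in_exon(tx$cds_start) || !in_exon(tx$cds_end)) {
      fail(sprintf("transcript %s CDS boundary outside its exon union",
                   tx$transcript_id), "model_validation_error")
    }
    len <- coding_length(sub, tx$cds_start, tx$cds_end)
    if (len %% 3L != 0L) {
      fail(sprintf("transcript %s CDS length not multiple of 3 (length %d)",
                   tx$transcript_id, len), "model_validation_error")
    }
  }
  # psi defined for every exon, in [0,1]
  if (!all(ex$exon_id %in% names(model$psi))) {
    fail("psi not defined for every exon", "model_validation_error")
  }
  psi <- model$psi[ex$exon_id]
  if (any(psi < 0 | psi > 1)) {
    fail("psi value outside [0,1]", "model_validation_error")
  }
  # bands disjoint and jointly covering the CDS span of the longest transcript
  bd <- model$bands
  if (nrow(bd)) {
    bo <- bd[order(bd$start), , drop = FALSE]
    if (nrow(bo) > 1 && any(bo$start[-1] <= bo$end[-nrow(bo)])) {
      fail("band intervals overlap", "model_validation_error")
    }
    ref <- reference_transcript(model)
    cg <- coding_gpos(model, ref, translation_order = FALSE)
    covered <- rep(FALSE, length(cg))
    for (i in seq_len(nrow(bd))) {
      covered <- covered | (cg >= bd$start[i] & cg <= bd$end[i])
    }
    if (!all(covered)) {
      fail("band intervals do not cover the CDS span of the longest transcript",
           "model_validation_error")
    }
  }
  invisible(model)
}

coding_length <- function(exon_df, cds_start, cds_end) {
  s <- pmax(exon_df$start, cds_start)
  e <- pmin(exon_df$end, cds_end)
  sum(pmax(e - s + 1L, 0L))
}

# Genomic positions of a transcript's coding bases. translation_order = TRUE
# returns them in the order they are read (descending for strand -).
coding_gpos <- function(model, transcript_id, translation_order = TRUE) {
  tx <- model$transcripts[[transcript_id]]
  if (is.null(tx)) fail(sprintf("unknown transcript_id '%s'", transcript_id),
                        "unknown_transcript_error")
  sub <- model$exons[match(tx$exon_ids, model$exons$exon_id), , drop = FALSE]
  s <- pmax(sub$start, tx$cds_start)
  e <- pmin(sub$end, tx$cds_end)
  keep <- s <= e
  pos <- unlist(Map(seq.int, s[keep], e[keep]), use.names = FALSE)
  pos <- sort(pos)
  if (translation_order && model$strand == "-") pos <- rev(pos)
  as.integer(pos)
}

build_model_index <- function(model) {
  idx <- list()
  for (tx in model$transcripts) {
    gpos <- coding_gpos(model, tx$transcript_id)
    bases <- seq_at(model$sequence, model$locus_offset, gpos)
    if (model$strand == "-") bases <- comp_base(bases)
    sub <- model$exons[match(tx$exon_ids, model$exons$exon_id), , drop = FALSE]
    idx[[tx$transcript_id]] <- list(
      coding_gpos = gpos,
      cds_seq = paste(bases, collapse = ""),
      exons = sub,
      span = c(min(sub$start), max(sub$end))
    )
  }
  idx
}

model_index <- function(model, transcript_id = NULL) {
  idx <- attr(model, "index")
  if (is.null(idx)) idx <- build_model_index(model)
  if (is.null(transcript_id)) idx else {
    one <- idx[[transcript_id]]
    if (is.null(one)) fail(sprintf("unknown transcript_id '%s'", transcript_id),
                           "unknown_transcript_error")
    one
  }
}

#' Spliced coding sequence of a transcript
#' @param model a `gene_model`.
#' @param transcript_id transcript id.
#' @return the CDS on the coding strand, 5'->3'.
#' @export
cds_sequence <- function(model, transcript_id) {
  model_index(model, transcript_id)$cds_seq
}

#' Transcript with the longest CDS
#'
#' Used as the designated reference transcript for consequence calling.
#' @param model a `gene_model`.
#' @return a transcript_id.
#' @export
reference_transcript <- function(model) {
  lens <- vapply(model$transcripts, function(tx) {
    sub <- model$exons[match(tx$exon_ids, model$exons$exon_id), , drop = FALSE]
    coding_length(sub, tx$cds_start, tx$cds_end)
  }, numeric(1))
  names(lens)[which.max(lens)]
}

#' Map genomic positions to CDS positions
#'
#' @param model a `gene_model`.
#' @param transcript_id transcript id.
#' @param gpos genomic position(s).
#' @return integer vector of 1-based positions within the spliced CDS, read in
#'   translation order (reversed for strand `-`); `NA` where `gpos` is intronic,
#'   non-coding, or outside the transcript.
#' @export
genomic_to_cds <- function(model, transcript_id, gpos) {
  match(as.integer(gpos), model_index(model, transcript_id)$coding_gpos)
}

#' Codon context at a genomic position
#'
#' @param model a `gene_model`.
#' @param transcript_id transcript id.
#' @param gpos one genomic position.
#' @return `NULL` if `gpos` is not coding in the transcript; otherwise a list
#'   with `transcript_id`, `cds_pos`, `codon_index`, `codon_pos` (1-3),
#'   `ref_codon` (coding strand) and `ref_aa`.
#' @export
codon_context <- function(model, transcript_id, gpos) {
  cds_pos <- genomic_to_cds(model, transcript_id, gpos)
  if (is.na(cds_pos)) return(NULL)
  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  codon_pos <- (cds_pos - 1L) %% 3L + 1L
  cseq <- cds_sequence(model, transcript_id)
  ref_codon <- substr(cseq, 3L * codon_index - 2L, 3L * codon_index)
  list(
    transcript_id = transcript_id, cds_pos = cds_pos,
    codon_index = codon_index, codon_pos = codon_pos,
    ref_codon = ref_codon, ref_aa = translate_codon(ref_codon)
  )
}

#' Transcripts whose exon union covers a position
#' @param model a `gene_model`.
#' @param gpos one genomic position.
#' @return character vector of transcript ids (possibly empty).
#' @export
transcripts_containing <- function(model, gpos) {
  hits <- vapply(model$transcripts, function(tx) {
    sub <- model$exons[match(tx$exon_ids, model$exons$exon_id), , drop = FALSE]
    any(sub$start <= gpos & gpos <= sub$end)
  }, logical(1))
  names(hits)[hits]
}

#' Band label at a genomic position
#'
#' Bands are genomic spans: intronic positions inside a band interval inherit
#' that band, which keeps splice-variant banding well defined.
#' @param model a `gene_model`.
#' @param gpos genomic position(s).
#' @return character vector of band labels, `NA` outside all bands.
#' @export
band_of <- function(model, gpos) {
  bd <- model$bands
  vapply(as.integer(gpos), function(p) {
    i <- which(bd$start <= p & p <= bd$end)
    if (length(i)) bd$band[i[1]] else NA_character_
  }, character(1))
}

#' Transcripts whose genomic span overlaps an interval
#'
#' A short isoform that simply terminates before an exon does not count as
#' "skipping" it; only transcripts whose span reaches the interval are relevant
#' when judging whether an exon (or position) is present in all transcripts.
#' @param model a `gene_model`.
#' @param start,end interval (1-based inclusive; a single position has
#'   `start == end`).
#' @return character vector of transcript ids.
#' @export
transcripts_spanning <- function(model, start, end = start) {
  hits <- vapply(model$transcripts, function(tx) {
    idx <- model_index(model, tx$transcript_id)
    idx$span[1] <= end && start <= idx$span[2]
  }, logical(1))
  names(hits)[hits]
}

#' Classify an exon by transcript membership and expression
#'
#' `low_psi` (PSI below threshold) takes precedence over `isoform_specific`
#' (absent from at least one transcript whose span overlaps the exon);
#' otherwise `all_transcripts`.
#' @param model a `gene_model`.
#' @param exon_id exon id.
#' @param psi_threshold PSI cut-off (default 0.15).
#' @return one of `"all_transcripts"`, `"isoform_specific"`, `"low_psi"`.
#' @export
exon_class <- function(model, exon_id, psi_threshold = 0.15) {
  i <- match(exon_id, model$exons$exon_id)
  if (is.na(i)) {
    fail(sprintf("unknown exon_id '%s'", exon_id), "unknown_exon_error")
  }
  if (model$psi[[exon_id]] < psi_threshold) return("low_psi")
  relevant <- transcripts_spanning(model, model$exons$start[i], model$exons$end[i])
  in_all <- all(vapply(model$transcripts[relevant],
                       function(tx) exon_id %in% tx$exon_ids, logical(1)))
  if (!in_all) "isoform_specific" else "all_transcripts"
}

#' Exon of a transcript containing a position
#' @param model a `gene_model`.
#' @param transcript_id transcript id.
#' @param gpos one genomic position.
#' @return exon_id or `NA` if `gpos` is not exonic in the transcript.
#' @export
exon_at <- function(model, transcript_id, gpos) {
  sub <- model_index(model, transcript_id)$exons
  i <- which(sub$start <= gpos & gpos <= sub$end)
  if (length(i)) sub$exon_id[i[1]] else NA_character_
}

#' Load a gene model from its JSON bundle
#'
#' The bundle is a JSON file with keys `gene`, `chrom`, `strand`,
#' `locus_offset`, `sequence_fasta` (sidecar FASTA file name, resolved relative
#' to the JSON file), `exons`, `transcripts`, `bands`, `psi`. All invariants are
#' validated on load.
#' @param path path to the JSON file.
#' @return a `gene_model`.
#' @export
load_gene_model <- function(path) {
  if (!file.exists(path)) fail(sprintf("gene model file not found: %s", path),
                               "missing_file_error")
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  need <- c("gene", "chrom", "strand", "locus_offset", "sequence_fasta",
            "exons", "transcripts", "bands", "psi")
  miss <- setdiff(need, names(j))
  if (length(miss)) fail(sprintf("gene model JSON missing keys: %s",
                                 paste(miss, collapse = ", ")),
                         "schema_error")
  fa_path <- file.path(dirname(path), j$sequence_fasta)
  if (!file.exists(fa_path)) fail(sprintf("sequence FASTA not found: %s", fa_path),
                                  "missing_file_error")
  seqs <- Biostrings::readDNAStringSet(fa_path)
  exons <- data.frame(exon_id = j$exons$id,
                      start = as.integer(j$exons$start),
                      end = as.integer(j$exons$end),
                      stringsAsFactors = FALSE)
  txj <- j$transcripts
  transcripts <- lapply(seq_len(nrow(txj)), function(i) {
    list(transcript_id = txj$id[i], name = txj$name[i],
         exon_ids = txj$exons[[i]],
         cds_start = as.integer(txj$cds_start[i]),
         cds_end = as.integer(txj$cds_end[i]))
  })
  bands <- data.frame(band = j$bands$band,
                      start = as.integer(j$bands$start),
                      end = as.integer(j$bands$end),
                      stringsAsFactors = FALSE)
  psi <- unlist(j$psi)
  gene_model(
    gene = j$gene, chrom = j$chrom, strand = j$strand,
    locus_offset = as.integer(j$locus_offset),
    sequence = as.character(seqs[[1]]),
    exons = exons, transcripts = transcripts, bands = bands, psi = psi
  )
}

#' Write a gene model as a JSON + FASTA bundle
#'
#' Inverse of [load_gene_model()]; writing then reloading reproduces the model
#' field-by-field.
#' @param model a `gene_model`.
#' @param dir output directory (created if needed).
#' @param name basename for the bundle files (`<name>.json`, `<name>.fa`).
#' @return the JSON path, invisibly.
#' @export
write_gene_model <- function(model, dir, name = "model") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa_name <- paste0(name, ".fa")
  obj <- list(
    gene = model$gene, chrom = model$chrom, strand = model$strand,
    locus_offset = model$locus_offset, sequence_fasta = fa_name,
    exons = data.frame(id = model$exons$exon_id, start = model$exons$start,
                       end = model$exons$end, stringsAsFactors = FALSE),
    transcripts = lapply(unname(model$transcripts), function(tx) {
      list(id = tx$transcript_id, name = tx$name, exons = tx$exon_ids,
           cds_start = tx$cds_start, cds_end = tx$cds_end)
    }),
    bands = model$bands,
    psi = as.list(model$psi[model$exons$exon_id])
  )
  json_path <- file.path(dir, paste0(name, ".json"))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             json_path)
  dna <- Biostrings::DNAStringSet(structure(model$sequence,
                                            names = sprintf("%s_locus", model$gene)))
  Biostrings::writeXStringSet(dna, file.path(dir, fa_name))
  invisible(json_path)
}
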