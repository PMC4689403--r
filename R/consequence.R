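#' Consequence classes, most severe first
#'
#' Severity precedence used when a variant is classifiable multiple ways across
#' transcripts.
#' @export
CONSEQUENCE_CLASSES <- c("nonsense", "frameshift", "essential_splice",
                         "splice_region", "inframe_indel", "missense",
                         "synonymous", "intronic", "noncoding")

# Intron position of gpos relative to one transcript, without the 1-6 window.
# Returns NULL when gpos is exonic in the transcript or outside its span, else
# list(distance = signed d in transcription order (+ donor side, - acceptor
# side), exon_id = adjacent exon).
intron_position <- function(model, transcript_id, gpos) {
  idx <- model_index(model, transcript_id)
  sub <- idx$exons
  if (gpos < idx$span[1] || gpos > idx$span[2]) return(NULL)
  if (any(sub$start <= gpos & gpos <= sub$end)) return(NULL)
  prev_i <- which(sub$end < gpos)
  next_i <- which(sub$start > gpos)
  prev_i <- prev_i[which.max(sub$end[prev_i])]
  next_i <- next_i[which.min(sub$start[next_i])]
  d_lo <- gpos - sub$end[prev_i]     # bases past the genomically-lower exon
  d_hi <- sub$start[next_i] - gpos   # bases before the genomically-higher exon
  if (model$strand == "+") {
    if (d_lo <= d_hi) {
      list(distance = d_lo, exon_id = sub$exon_id[prev_i])
    } else {
      list(distance = -d_hi, exon_id = sub$exon_id[next_i])
    }
  } else {
    # transcription runs right to left: donor side is the genomically-higher
    # exon's start, acceptor side the genomically-lower exon's end
    if (d_hi <= d_lo) {
      list(distance = d_hi, exon_id = sub$exon_id[next_i])
    } else {
      list(distance = -d_lo, exon_id = sub$exon_id[prev_i])
    }
  }
}

#' Signed splice distance of a position
#'
#' Distance from an intronic position to the nearest intron boundary of the
#' transcript, in transcription order: `+d` means d bases into the intron from
#' the donor (the exon's 3' end), `-d` means d bases from the acceptor (the
#' exon's 5' start). Only distances 1-6 are reported; everything else is `NA`.
#' @param model a `gene_model`.
#' @param gpos one genomic position.
#' @param transcript_id transcript id.
#' @return signed integer distance, or `NA`.
#' @export
splice_distance <- function(model, gpos, transcript_id) {
  ip <- intron_position(model, transcript_id, gpos)
  if (is.null(ip) || abs(ip$distance) > 6L) return(NA_integer_)
  as.integer(ip$distance)
}

# classify rec against one transcript; returns a list describing the call
classify_on_transcript <- function(model, transcript_id, rec) {
  pos <- as.integer(rec$pos)
  ref <- rec$ref; alt <- rec$alt
  nr <- nchar(ref); na <- nchar(alt)
  blank <- list(class = "noncoding", ctx = NULL, alt_codon = NA_character_,
                aa_change = NA_character_, splice_distance = NA_integer_,
                exon_id = NA_character_, anchor = pos)
  if (nr == 1L && na == 1L) {
    ctx <- codon_context(model, transcript_id, pos)
    if (!is.null(ctx)) {
      alt_coding <- if (model$strand == "-") comp_base(alt) else alt
      alt_codon <- ctx$ref_codon
      substr(alt_codon, ctx$codon_pos, ctx$codon_pos) <- alt_coding
      alt_aa <- translate_codon(alt_codon)
      cls <- if (ctx$ref_aa != "*" && alt_aa == "*") "nonsense"
      else if (alt_aa == ctx$ref_aa) "synonymous"
      else "missense"   # includes stop-loss / start-loss
      return(list(class = cls, ctx = ctx, alt_codon = alt_codon,
                  aa_change = paste0(ctx$ref_aa, "/", alt_aa),
                  splice_distance = NA_integer_,
                  exon_id = exon_at(model, transcript_id, pos), anchor = pos))
    }
    ip <- intron_position(model, transcript_id, pos)
    if (is.null(ip)) return(blank)
    d <- ip$distance
    cls <- if (abs(d) <= 2L) "essential_splice"
    else if (abs(d) <= 6L) "splice_region" else "intronic"
    return(list(class = cls, ctx = NULL, alt_codon = NA_character_,
                aa_change = NA_character_, splice_distance = as.integer(d),
                exon_id = ip$exon_id, anchor = pos))
  }
  # indel (normalized: anchor base shared). Deleted bases sit at pos+1 ..
  # pos+nr-1; an insertion lands between pos and pos+1.
  changed <- if (nr > na) seq.int(pos + 1L, pos + nr - 1L) else pos
  coding <- model_index(model, transcript_id)$coding_gpos
  exonic_overlap <- if (nr > na) {
    any(changed %in% coding)
  } else if (na > nr) {
    (pos %in% coding) && ((pos + 1L) %in% coding)
  } else {
    any(seq.int(pos, pos + nr - 1L) %in% coding)
  }
  if (exonic_overlap) {
    if (nr == na) {
      cls <- "missense"  # multi-nucleotide substitution, not analysed further
    } else if (abs(nr - na) %% 3L == 0L) {
      cls <- "inframe_indel"
    } else {
      cls <- "frameshift"
    }
    first_coding <- changed[changed %in% coding][1]
    if (is.na(first_coding)) first_coding <- pos
    return(list(class = cls, ctx = NULL, alt_codon = NA_character_,
                aa_change = NA_character_, splice_distance = NA_integer_,
                exon_id = exon_at(model, transcript_id, first_coding),
                anchor = first_coding))
  }
  left <- changed[1]
  ip <- intron_position(model, transcript_id, left)
  if (is.null(ip)) return(blank)
  d <- ip$distance
  cls <- if (abs(d) <= 2L) "essential_splice"
  else if (abs(d) <= 6L) "splice_region" else "intronic"
  list(class = cls, ctx = NULL, alt_codon = NA_character_,
       aa_change = NA_character_, splice_distance = as.integer(d),
       exon_id = ip$exon_id, anchor = left)
}

#' Classify one variant's molecular consequence on the gene model
#'
#' The variant is classified against every transcript and the most severe
#' class wins (precedence [CONSEQUENCE_CLASSES]); ties go to the designated
#' reference transcript (longest CDS by default). Transcript membership is the
#' set of transcripts whose exon union covers the variant (for splice calls,
#' the transcripts carrying the adjacent exon).
#'
#' @param model a `gene_model`.
#' @param rec one-row normalized variant data.frame.
#' @param psi_threshold PSI cut-off carried into the exon class annotation.
#' @param ref_tx reference transcript id; default [reference_transcript()].
#' @return one-row data.frame: the input columns plus `key`,
#'   `consequence_class`, `band`, `exon_id`, `exon_class`, `transcript_id`,
#'   `transcript_hits` (comma list), `affects_all`, `cds_pos`, `codon_index`,
#'   `codon_pos`, `ref_codon`, `alt_codon`, `aa_change`, `splice_distance`.
#' @export
classify_variant <- function(model, rec, psi_threshold = 0.15, ref_tx = NULL) {
  if (is.null(ref_tx)) ref_tx <- reference_transcript(model)
  pos <- as.integer(rec$pos)
  locus_end <- model$locus_offset + nchar(model$sequence) - 1L
  if (pos < model$locus_offset || pos > locus_end) {
    fail(sprintf("variant position %d outside locus bounds", pos),
         "locus_bounds_error")
  }
  have <- seq_at(model$sequence, model$locus_offset, pos, nchar(rec$ref))
  if (!identical(have, rec$ref)) {
    fail(sprintf("reference mismatch at pos %d: variant ref '%s', sequence '%s'",
                 pos, rec$ref, have), "reference_mismatch_error")
  }
  tx_ids <- names(model$transcripts)
  per_tx <- lapply(tx_ids, function(t) classify_on_transcript(model, t, rec))
  names(per_tx) <- tx_ids
  sev <- match(vapply(per_tx, `[[`, character(1), "class"), CONSEQUENCE_CLASSES)
  best <- min(sev)
  cand <- tx_ids[sev == best]
  chosen_tx <- if (ref_tx %in% cand) ref_tx else cand[1]
  call <- per_tx[[chosen_tx]]
  exonic <- call$class %in% c("nonsense", "frameshift", "inframe_indel",
                              "missense", "synonymous")
  if (exonic) {
    hits <- transcripts_containing(model, call$anchor)
    relevant <- transcripts_spanning(model, call$anchor)
  } else if (!is.na(call$exon_id)) {
    hits <- tx_ids[vapply(model$transcripts,
                          function(tx) call$exon_id %in% tx$exon_ids,
                          logical(1))]
    ei <- match(call$exon_id, model$exons$exon_id)
    relevant <- transcripts_spanning(model, model$exons$start[ei],
                                     model$exons$end[ei])
  } else {
    hits <- character(0)
    relevant <- character(0)
  }
  exon_cls <- if (!is.na(call$exon_id)) {
    exon_class(model, call$exon_id, psi_threshold)
  } else NA_character_
  ctx <- call$ctx
  ann <- data.frame(
    key = variant_key(as.data.frame(rec, stringsAsFactors = FALSE)),
    consequence_class = call$class,
    band = band_of(model, pos),
    exon_id = call$exon_id,
    exon_class = exon_cls,
    transcript_id = chosen_tx,
    transcript_hits = paste(hits, collapse = ","),
    affects_all = length(hits) > 0 && all(relevant %in% hits),
    cds_pos = if (is.null(ctx)) NA_integer_ else ctx$cds_pos,
    codon_index = if (is.null(ctx)) NA_integer_ else ctx$codon_index,
    codon_pos = if (is.null(ctx)) NA_integer_ else ctx$codon_pos,
    ref_codon = if (is.null(ctx)) NA_character_ else ctx$ref_codon,
    alt_codon = call$alt_codon,
    aa_change = call$aa_change,
    splice_distance = call$splice_distance,
    stringsAsFactors = FALSE
  )
  cbind(as.data.frame(rec, stringsAsFactors = FALSE)[
    setdiff(names(rec), names(ann))], ann)
}

#' Classify every variant in a frame
#' @param model a `gene_model`.
#' @param df normalized variant data.frame.
#' @param psi_threshold PSI cut-off.
#' @param ref_tx reference transcript id.
#' @return annotated data.frame, one row per input variant.
#' @export
classify_variants <- function(model, df, psi_threshold = 0.15, ref_tx = NULL) {
  if (!nrow(df)) {
    out <- cbind(df, data.frame(
      key = character(0), consequence_class = character(0), band = character(0),
      exon_id = character(0), exon_class = character(0),
      transcript_id = character(0), transcript_hits = character(0),
      affects_all = logical(0), cds_pos = integer(0), codon_index = integer(0),
      codon_pos = integer(0), ref_codon = character(0),
      alt_codon = character(0), aa_change = character(0),
      splice_distance = integer(0), stringsAsFactors = FALSE))
    return(out)
  }
  if (is.null(ref_tx)) ref_tx <- reference_transcript(model)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    classify_variant(model, df[i, ], psi_threshold, ref_tx)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Is a call a truncating variant?
#'
#' Truncating = nonsense, frameshift, or essential splice site. Splice-region
#' (3-6 bp) variants are deliberately excluded.
#' @param x annotated call frame, or a character vector of consequence classes.
#' @return logical vector.
#' @export
is_ttntv <- function(x) {
  cls <- if (is.data.frame(x)) x$consequence_class else x
  cls %in% c("nonsense", "frameshift", "essential_splice")
}
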