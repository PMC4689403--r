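#' @name filters
#' @title Call-set filtering pipeline
#' @description
#' The filtering workflow that turns raw call sets into the candidate set of
#' truncating variants that affect all transcripts, lie in expressed exons, and
#' are well covered: quality filter, normalize/annotate, truncating-class
#' filter, transcript-membership/PSI filter, cross-dataset concordance filter,
#' coverage filter. Every stage emits a trace recording what it removed.
NULL

make_trace <- function(stage, in_keys, out_keys, extra = list()) {
  c(list(stage = stage, n_in = length(in_keys), n_out = length(out_keys),
         removed_keys = setdiff(in_keys, out_keys)), extra)
}

#' Tabulate filter traces
#' @param traces list of traces as produced by the filter stages.
#' @return data.frame with columns `stage`, `n_in`, `n_out`, `n_removed`.
#' @export
trace_table <- function(traces) {
  data.frame(
    stage = vapply(traces, `[[`, character(1), "stage"),
    n_in = vapply(traces, `[[`, numeric(1), "n_in"),
    n_out = vapply(traces, `[[`, numeric(1), "n_out"),
    n_removed = vapply(traces, function(t) length(t$removed_keys), numeric(1)),
    stringsAsFactors = FALSE
  )
}

# trace keys: dataset-qualified so the same allele seen in two call sets stays
# distinguishable in removal lists
trace_key <- function(df) paste(df$dataset, variant_key(df), sep = "|")

#' Quality filter: retain PASS calls only
#' @param records variant data.frame.
#' @return list(records = retained frame, trace).
#' @export
quality_filter <- function(records) {
  keep <- records$filter_status == "PASS"
  out <- records[keep, , drop = FALSE]
  list(records = out,
       trace = make_trace("quality", trace_key(records), trace_key(out)))
}

#' Transcript-membership / PSI filter
#'
#' Removes calls whose exon (or, for splice calls, adjacent exon) is
#' isoform-specific or has PSI below threshold; equivalently retains calls
#' affecting all transcripts in exons with PSI at or above the threshold.
#' @param calls annotated call frame (columns `exon_class`, `affects_all`).
#' @param psi_threshold PSI cut-off (annotation must have used the same one).
#' @return list(calls, trace).
#' @export
transcript_filter <- function(calls, psi_threshold = 0.15) {
  drop <- (!is.na(calls$exon_class) &
             calls$exon_class %in% c("isoform_specific", "low_psi")) |
    !calls$affects_all
  out <- calls[!drop, , drop = FALSE]
  list(calls = out,
       trace = make_trace("transcript", trace_key(calls), trace_key(out)))
}

#' Coverage filter
#'
#' Retains calls whose position has mean depth at or above the threshold.
#' Calls at positions missing from the coverage table are removed and listed
#' under `uncovered` in the trace (never silently kept).
#' @param calls annotated call frame.
#' @param coverage coverage data.frame ([read_coverage()]), or `NULL` to use a
#'   `mean_depth` column already present on `calls`.
#' @param min_mean_depth depth threshold (default 15).
#' @return list(calls, trace).
#' @export
coverage_filter <- function(calls, coverage = NULL, min_mean_depth = 15) {
  if (!nrow(calls)) {
    return(list(calls = calls,
                trace = make_trace("coverage", character(0), character(0),
                                   list(uncovered = character(0)))))
  }
  if (is.null(coverage)) {
    if (!"mean_depth" %in% names(calls)) {
      fail("coverage_filter needs a coverage table or a mean_depth column",
           "coverage_config_error")
    }
    depth <- calls$mean_depth
  } else {
    i <- match(paste(calls$chrom, calls$pos),
               paste(coverage$chrom, coverage$pos))
    depth <- coverage$mean_depth[i]
  }
  uncovered <- is.na(depth)
  keep <- !uncovered & depth >= min_mean_depth
  out <- calls[keep, , drop = FALSE]
  list(calls = out,
       trace = make_trace("coverage", trace_key(calls), trace_key(out),
                          list(uncovered = trace_key(calls[uncovered, ,
                                                           drop = FALSE]))))
}

#' Cross-dataset concordance filter
#'
#' Variants present in a subset call set but absent from the designated
#' superset call set are treated as likely false positives and removed (or only
#' flagged with `flag_only = TRUE`). A variant shared by two or more subset
#' call sets is retained whatever the superset contains, and counted in the
#' `overlap` report. Superset calls are never removed.
#' @param calls_by_dataset named list of annotated call frames.
#' @param superset name of the superset dataset.
#' @param flag_only if TRUE, add a `concordant` column instead of removing.
#' @return list(calls_by_dataset, trace, overlap) where `overlap` counts keys
#'   shared between each pair of subset call sets.
#' @export
concordance_filter <- function(calls_by_dataset, superset, flag_only = FALSE) {
  if (is.null(superset) || !superset %in% names(calls_by_dataset)) {
    fail("no dataset designated as the concordance superset",
         "concordance_config_error")
  }
  keys <- lapply(calls_by_dataset, variant_key)
  subsets <- setdiff(names(calls_by_dataset), superset)
  overlap <- list()
  if (length(subsets) > 1) {
    pairs <- utils::combn(subsets, 2, simplify = FALSE)
    for (p in pairs) {
      overlap[[paste(p, collapse = "&")]] <- intersect(keys[[p[1]]], keys[[p[2]]])
    }
  }
  in_keys <- unlist(lapply(names(calls_by_dataset), function(d) {
    paste(d, keys[[d]], sep = "|")
  }))
  out <- calls_by_dataset
  for (d in subsets) {
    others <- unlist(keys[setdiff(subsets, d)])
    unique_fp <- !(keys[[d]] %in% keys[[superset]]) & !(keys[[d]] %in% others)
    if (flag_only) {
      out[[d]]$concordant <- !unique_fp
    } else {
      out[[d]] <- out[[d]][!unique_fp, , drop = FALSE]
    }
  }
  out_keys <- unlist(lapply(names(out), function(d) {
    paste(d, variant_key(out[[d]]), sep = "|")
  }))
  list(calls_by_dataset = out,
       trace = make_trace("concordance", in_keys, out_keys),
       overlap = overlap)
}

#' Run the full filtering pipeline
#'
#' Stage order: quality -> normalize/annotate -> truncating-class filter ->
#' transcript/PSI filter -> cross-dataset concordance -> coverage.
#' @param records_by_dataset named list of raw variant frames ([read_vcf()]).
#' @param model a `gene_model`.
#' @param config list: `psi_threshold` (0.15), `min_mean_depth` (15),
#'   `superset_dataset`, `flag_only` (FALSE), `ref_tx`, `coverage` (coverage
#'   frame or NULL).
#' @return list with `calls` (combined final frame), `by_dataset`, `traces`
#'   (six stage traces), `overlap` (subset call-set intersections).
#' @export
run_pipeline <- function(records_by_dataset, model, config = list()) {
  cfg <- utils::modifyList(list(psi_threshold = 0.15, min_mean_depth = 15,
                                superset_dataset = NULL, flag_only = FALSE,
                                ref_tx = NULL, coverage = NULL), config)
  traces <- list()
  agg <- function(stage, per_ds) {
    make_trace(stage,
               unlist(lapply(per_ds, function(x) x$in_keys), use.names = FALSE),
               unlist(lapply(per_ds, function(x) x$out_keys), use.names = FALSE))
  }
  # 1. quality
  q <- lapply(records_by_dataset, quality_filter)
  traces$quality <- agg("quality", lapply(names(q), function(d) {
    list(in_keys = trace_key(records_by_dataset[[d]]),
         out_keys = trace_key(q[[d]]$records))
  }))
  recs <- lapply(q, `[[`, "records")
  # 2. normalize + annotate (count-preserving)
  ann <- lapply(names(recs), function(d) {
    classify_variants(model, normalize_variants(recs[[d]], model),
                      psi_threshold = cfg$psi_threshold, ref_tx = cfg$ref_tx)
  })
  names(ann) <- names(recs)
  keys2 <- unlist(lapply(ann, trace_key), use.names = FALSE)
  traces$annotate <- make_trace("annotate", keys2, keys2)
  # 3. truncating classes only
  tv <- lapply(ann, function(df) df[is_ttntv(df), , drop = FALSE])
  traces$ttntv <- agg("ttntv", lapply(names(ann), function(d) {
    list(in_keys = trace_key(ann[[d]]), out_keys = trace_key(tv[[d]]))
  }))
  # 4-6. transcript / concordance / coverage on the annotated truncating set
  fs <- filter_annotated(tv, cfg)
  traces <- c(traces, fs$traces)
  list(calls = fs$calls, by_dataset = fs$by_dataset, traces = unname(traces),
       overlap = fs$overlap)
}

#' Run the annotation-independent filter stages on annotated calls
#'
#' Stages 4-6 of the pipeline (transcript/PSI, cross-dataset concordance,
#' coverage) applied to call frames that already carry annotations — as
#' produced by the pipeline's annotate stage or by a margin-matched fixture.
#' @param calls_by_dataset named list of annotated call frames.
#' @param config list: `psi_threshold`, `min_mean_depth`, `superset_dataset`,
#'   `flag_only`, `coverage`.
#' @return list(calls, by_dataset, traces = list(transcript, concordance,
#'   coverage), overlap).
#' @export
filter_annotated <- function(calls_by_dataset, config = list()) {
  cfg <- utils::modifyList(list(psi_threshold = 0.15, min_mean_depth = 15,
                                superset_dataset = NULL, flag_only = FALSE,
                                coverage = NULL), config)
  traces <- list()
  agg <- function(stage, per_ds) {
    make_trace(stage,
               unlist(lapply(per_ds, function(x) x$in_keys), use.names = FALSE),
               unlist(lapply(per_ds, function(x) x$out_keys), use.names = FALSE))
  }
  tv <- calls_by_dataset
  tf <- lapply(tv, transcript_filter, psi_threshold = cfg$psi_threshold)
  traces$transcript <- agg("transcript", lapply(names(tv), function(d) {
    list(in_keys = trace_key(tv[[d]]), out_keys = trace_key(tf[[d]]$calls))
  }))
  cur <- lapply(tf, `[[`, "calls")
  overlap <- list()
  if (length(cur) >= 2) {
    cc <- concordance_filter(cur, cfg$superset_dataset, cfg$flag_only)
    traces$concordance <- cc$trace
    overlap <- cc$overlap
    cur <- cc$calls_by_dataset
  } else {
    k <- unlist(lapply(cur, trace_key), use.names = FALSE)
    traces$concordance <- make_trace("concordance", k, k)
  }
  cv <- lapply(cur, coverage_filter, coverage = cfg$coverage,
               min_mean_depth = cfg$min_mean_depth)
  traces$coverage <- agg("coverage", lapply(names(cur), function(d) {
    list(in_keys = trace_key(cur[[d]]), out_keys = trace_key(cv[[d]]$calls))
  }))
  final <- lapply(cv, `[[`, "calls")
  combined <- do.call(rbind_fill, unname(final))
  if (is.null(combined)) combined <- empty_variant_frame()
  rownames(combined) <- NULL
  list(calls = combined, by_dataset = final, traces = traces, overlap = overlap)
}

#' Compare two call sets by variant key
#' @param a,b annotated or raw variant frames (normalized).
#' @return list(shared, only_a, only_b) of variant keys.
#' @export
compare_callsets <- function(a, b) {
  ka <- unique(variant_key(a)); kb <- unique(variant_key(b))
  list(shared = intersect(ka, kb), only_a = setdiff(ka, kb),
       only_b = setdiff(kb, ka))
}
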