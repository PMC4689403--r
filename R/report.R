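#' Burden-table report (counts and prevalence by dataset, type and band)
#'
#' Mirrors the layout of a distribution-and-burden table: rows for the total,
#' each mutation type, each band, and each band x type cell; one count column
#' and one prevalence column per dataset, with prevalence in percent to three
#' decimals, plus a `cell` column pair formatted `"count (prevalence)"`.
#' Prevalence in a cell is the carrier count of that cell's calls over the
#' cohort size, so every printed number is recomputable from the calls.
#'
#' @param calls_by_dataset named list of annotated call frames (normally the
#'   pipeline's final calls).
#' @param cohort_sizes named numeric vector, one size per dataset.
#' @return data.frame, one row per table line.
#' @export
table1_report <- function(calls_by_dataset, cohort_sizes) {
  datasets <- names(calls_by_dataset)
  types <- c(frameshift = "frameshift", nonsense = "nonsense",
             splice_site = "essential_splice")
  bands <- c("Z", "I", "A", "M")
  rows <- list(list(label = "total", sel = function(df) rep(TRUE, nrow(df))))
  for (t in names(types)) {
    cls <- types[[t]]
    rows[[length(rows) + 1]] <- list(
      label = t, sel = local({
        c0 <- cls
        function(df) df$consequence_class == c0
      }))
  }
  for (b in bands) {
    rows[[length(rows) + 1]] <- list(
      label = paste0(b, "_band"), sel = local({
        b0 <- b
        function(df) !is.na(df$band) & df$band == b0
      }))
    for (t in names(types)) {
      rows[[length(rows) + 1]] <- list(
        label = paste0(b, "_band_", t), sel = local({
          b0 <- b; c0 <- types[[t]]
          function(df) !is.na(df$band) & df$band == b0 &
            df$consequence_class == c0
        }))
    }
  }
  out <- data.frame(row = vapply(rows, `[[`, character(1), "label"),
                    stringsAsFactors = FALSE)
  for (d in datasets) {
    df <- calls_by_dataset[[d]]
    n_cohort <- cohort_sizes[[d]]
    cnt <- integer(length(rows)); prev <- numeric(length(rows))
    for (i in seq_along(rows)) {
      sub <- df[rows[[i]]$sel(df), , drop = FALSE]
      cnt[i] <- nrow(sub)
      prev[i] <- prevalence(carriers_from_calls(sub), n_cohort)
    }
    out[[paste0(d, "_count")]] <- cnt
    out[[paste0(d, "_prevalence")]] <- round(prev, 3)
    out[[paste0(d, "_cell")]] <- sprintf("%d (%.3f)", cnt, prev)
  }
  out
}

#' Write a report data.frame as TSV with commented footnotes
#' @param report data.frame.
#' @param path output path.
#' @param footnotes character vector written as trailing `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path, footnotes = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(footnotes)) writeLines(paste0("# ", footnotes), con)
  invisible(path)
}

#' Call-set evolution report
#'
#' Per release version: counts by consequence class, allele-based carrier
#' count, prevalence given the cohort size, and attrition against the previous
#' version (shared / dropped / gained variant keys).
#' @param callsets named list of call frames, in release order.
#' @param cohort_sizes named vector of cohort sizes, same names.
#' @return data.frame, one row per version.
#' @export
evolution_report <- function(callsets, cohort_sizes) {
  if (length(callsets) < 2) fail("need at least two call-set versions",
                                 "evolution_error")
  versions <- names(callsets)
  cls_cols <- c("nonsense", "frameshift", "essential_splice", "splice_region")
  rows <- lapply(seq_along(versions), function(i) {
    df <- callsets[[i]]
    r <- data.frame(version = versions[i], n = nrow(df),
                    stringsAsFactors = FALSE)
    for (cl in cls_cols) r[[cl]] <- sum(df$consequence_class == cl)
    k <- carriers_from_calls(df)
    r$carriers <- k
    r$prevalence <- round(prevalence(k, cohort_sizes[[versions[i]]]), 3)
    if (i == 1) {
      r$shared_prev <- NA_integer_; r$only_prev <- NA_integer_
      r$only_curr <- NA_integer_
    } else {
      cmp <- compare_callsets(callsets[[i - 1]], df)
      r$shared_prev <- length(cmp$shared)
      r$only_prev <- length(cmp$only_a)
      r$only_curr <- length(cmp$only_b)
    }
    r
  })
  do.call(rbind, rows)
}

#' Write a run manifest
#'
#' Records enough to re-run an analysis bit-identically given the same inputs:
#' the configuration, input file checksums, seed, package version and
#' timestamp.
#' @param path output JSON path.
#' @param config configuration list (echoed verbatim).
#' @param inputs character vector of input file paths (md5-summed).
#' @param seed integer seed used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), inputs = character(0),
                           seed = NA_integer_) {
  checks <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    stats::setNames(list(), character(0))
  }
  manifest <- list(
    tool = "ttnsift",
    version = as.character(utils::packageVersion("ttnsift")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = checks)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), path)
  invisible(path)
}
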