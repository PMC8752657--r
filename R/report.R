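#' Write a screening report to disk
#'
#' Writes the records of one zone screen (a [runZoneAnalysis()] table) as a
#' tidy CSV and as JSON, plus a plain-text summary of the selected features
#' with their band labels. Records are ordered deterministically by
#' (base_image, feature), so identical inputs produce byte-identical files.
#'
#' @param records data.frame from [runZoneAnalysis()].
#' @param prefix output path prefix; writes `<prefix>.csv`, `<prefix>.json`
#'   and `<prefix>_summary.txt`.
#' @return character vector of the three paths, invisibly.
#' @export
writeScreeningReport <- function(records, prefix) {
  if (!nrow(records)) stop("no screening records to write")
  records <- records[order(records$base_image, records$feature), ]
  rownames(records) <- NULL
  csv <- paste0(prefix, ".csv")
  jsn <- paste0(prefix, ".json")
  txt <- paste0(prefix, "_summary.txt")
  utils::write.csv(records, csv, row.names = FALSE)
  writeLines(jsonlite::toJSON(records, dataframe = "rows", na = "null",
                              auto_unbox = FALSE, digits = NA, pretty = TRUE),
             jsn)
  sel <- records[records$selected, ]
  lines <- c(sprintf("zone %s, %d gray levels, %d lesions",
                     records$zone[1], records$n_bins[1],
                     records$n_lesions[1]),
             sprintf("%d of %d (base image, feature) records selected",
                     nrow(sel), nrow(records)))
  if (nrow(sel) == 0L) {
    lines <- c(lines, "no feature selected")
  } else {
    lines <- c(lines, sprintf(
      "%s | %s: rho %.3f/%.3f, AUC %.3f/%.3f, ICC %.3f, BA SD %.1f%% [corr %s, AUC %s, ICC %s]",
      sel$base_image, sel$feature, sel$rho_first, sel$rho_second,
      sel$auc_first, sel$auc_second, sel$icc, sel$ba_sd_pct,
      sel$corr_label, sel$auc_label, sel$icc_label))
  }
  writeLines(lines, txt)
  invisible(c(csv, jsn, txt))
}

#' Write a full study bundle
#'
#' Writes the QC table (CSV + JSON lines + exclusion summary) and every zone
#' screening report of a [runFullStudy()] bundle into a directory.
#'
#' @param bundle a `StudyBundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudyBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$qc, file.path(dir, "qc.csv"), row.names = FALSE)
  writeQcJson(bundle$qc, file.path(dir, "qc.jsonl"))
  s <- attr(bundle$qc, "summary")
  writeLines(jsonlite::toJSON(s, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "qc_summary.json"))
  for (nm in names(bundle$reports))
    writeScreeningReport(bundle$reports[[nm]], file.path(dir, nm))
  invisible(dir)
}
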