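#' Write one lesion examination as a voxel CSV
#'
#' Serialises a [LesionAcquisition-class] in the package's normative voxel
#' CSV dialect: header `row,col,in_roi,b0,b100,b1000,b1500`, one line per
#' voxel of the mask bounding box, 0-based row/col indices, `in_roi` in
#' `{0,1}`, signals printed at full double precision so the file round-trips
#' losslessly. Lesion metadata (id, zone, grade group, exam) travel in the
#' cohort manifest (see [writeCohortCsv()]), not in the CSV itself.
#'
#' @param acq a [LesionAcquisition-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVoxelCsv <- function(acq, path) {
  stopifnot(is(acq, "LesionAcquisition"))
  validObject(acq)
  bb <- .maskBoundingBox(acq@mask)
  rows <- bb$rows[1]:bb$rows[2]
  cols <- bb$cols[1]:bb$cols[2]
  # row-major order over the bounding box, 0-based coordinates
  grid <- expand.grid(col = cols, row = rows)[, c("row", "col")]
  ij <- cbind(grid$row, grid$col)
  num <- function(v) sprintf("%.17g", v)
  df <- data.frame(
    row = grid$row - bb$rows[1],
    col = grid$col - bb$cols[1],
    in_roi = as.integer(acq@mask[ij]),
    b0 = num(acq@signals[["0"]][ij]),
    b100 = num(acq@signals[["100"]][ij]),
    b1000 = num(acq@signals[["1000"]][ij]),
    b1500 = num(acq@signals[["1500"]][ij]),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a voxel CSV into a lesion acquisition
#'
#' Parses the dialect written by [writeVoxelCsv()]. Unknown extra columns
#' are ignored with a warning; a missing required column or a non-rectangular
#' `(row, col)` index set is a format error. Metadata not stored in the CSV
#' can be supplied through the arguments (a cohort manifest does this for
#' you, see [readCohortCsv()]).
#'
#' @param path path to a voxel CSV file.
#' @param lesionId,zone,gradeGroup,examIndex,voxelSize metadata to attach.
#' @return a [LesionAcquisition-class].
#' @export
readVoxelCsv <- function(path, lesionId = basename(path), zone = "PZ",
                         gradeGroup = NA_integer_, examIndex = 1L,
                         voxelSize = 1.0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("row", "col", "in_roi", "b0", "b100", "b1000", "b1500")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("voxel CSV format error: missing column ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  if (nrow(df) == 0L)
    stop("voxel CSV format error: no voxels (header-only file)")
  nr <- max(df$row) + 1L
  nc <- max(df$col) + 1L
  if (nrow(df) != nr * nc ||
      anyDuplicated(df[c("row", "col")]) ||
      min(df$row) != 0L || min(df$col) != 0L)
    stop("voxel CSV format error: (row, col) indices do not form a full ",
         "rectangular grid")
  ij <- cbind(df$row + 1L, df$col + 1L)
  toGrid <- function(v) {
    g <- matrix(NA_real_, nr, nc)
    g[ij] <- as.numeric(v)
    g
  }
  mask <- matrix(FALSE, nr, nc)
  mask[ij] <- df$in_roi != 0L
  signals <- list("0" = toGrid(df$b0), "100" = toGrid(df$b100),
                  "1000" = toGrid(df$b1000), "1500" = toGrid(df$b1500))
  new("LesionAcquisition", lesionId = lesionId, zone = zone,
      gradeGroup = as.integer(gradeGroup), examIndex = as.integer(examIndex),
      signals = signals, mask = mask, voxelSize = voxelSize)
}

#' Lesion-level quality control
#'
#' Applies the lesion exclusion rules to a paired (test-retest) acquisition:
#' `ROI_TOO_SMALL` when either examination's ROI holds fewer than
#' `minVoxels` voxels (default 50), `NEGATIVE_ADC` when any in-ROI voxel of
#' any of the four two-b-value ADC maps of either examination is negative,
#' `EXTENT_LT_4` when a ROI bounding box spans fewer than 4 voxels in either
#' direction (too small for neighbourhood texture), and `MISSING_B` when a
#' b-value grid is absent. A lesion passes iff no reason fires.
#'
#' @param exam1,exam2 the two [LesionAcquisition-class] examinations of one
#'   lesion (matching `lesionId`).
#' @param adcMaps1,adcMaps2 optional lists of the four [AdcMap-class] per
#'   exam (computed internally when omitted).
#' @param minVoxels ROI voxel-count floor (default 50).
#' @return an object of class `QcReport`: a list with `lesion_id`, `passed`,
#'   `reasons` (character vector), `voxel_count` (first exam),
#'   `voxel_count_second` and `invalid_voxels` (in-ROI voxels with
#'   non-positive signal across all ADC maps).
#' @export
qcLesion <- function(exam1, exam2, adcMaps1 = NULL, adcMaps2 = NULL,
                     minVoxels = 50L) {
  stopifnot(is(exam1, "LesionAcquisition"), is(exam2, "LesionAcquisition"))
  if (!identical(exam1@lesionId, exam2@lesionId))
    stop("mismatched lesion ids between exams: ", exam1@lesionId, " vs ",
         exam2@lesionId)
  reasons <- character()
  haveB <- function(a) all(as.character(.B_VALUES) %in% names(a@signals))
  if (!haveB(exam1) || !haveB(exam2)) reasons <- c(reasons, "MISSING_B")
  n1 <- sum(exam1@mask); n2 <- sum(exam2@mask)
  if (n1 < minVoxels || n2 < minVoxels) reasons <- c(reasons, "ROI_TOO_SMALL")
  invalid <- 0L
  if (!"MISSING_B" %in% reasons) {
    if (is.null(adcMaps1)) adcMaps1 <- .allAdcMaps(exam1)
    if (is.null(adcMaps2)) adcMaps2 <- .allAdcMaps(exam2)
    neg <- FALSE
    for (m in c(adcMaps1, adcMaps2)) {
      v <- maskedValues(m)
      invalid <- invalid + sum(is.na(v))
      if (any(v < 0, na.rm = TRUE)) neg <- TRUE
    }
    if (neg) reasons <- c(reasons, "NEGATIVE_ADC")
  }
  if (any(.maskExtent(exam1@mask) < 4L) || any(.maskExtent(exam2@mask) < 4L))
    reasons <- c(reasons, "EXTENT_LT_4")
  structure(list(lesion_id = exam1@lesionId, passed = length(reasons) == 0L,
                 reasons = reasons, voxel_count = n1,
                 voxel_count_second = n2, invalid_voxels = invalid),
            class = "QcReport")
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QcReport %s: %s (ROI %d/%d voxels%s)\n", x$lesion_id,
              if (x$passed) "PASS" else paste("FAIL:", paste(x$reasons, collapse = ", ")),
              x$voxel_count, x$voxel_count_second,
              if (x$invalid_voxels > 0)
                sprintf(", %d invalid", x$invalid_voxels) else ""))
  invisible(x)
}

#' Quality control over a whole cohort
#'
#' Runs [qcLesion()] on every lesion of a cohort (as returned by
#' [generateCohort()] or [readCohortCsv()]) and tabulates the outcome.
#'
#' @param cohort list of lesions, each with components `exam1` and `exam2`.
#' @param minVoxels ROI voxel-count floor.
#' @return a data.frame with one row per lesion: `lesion_id`, `zone`,
#'   `grade_group`, `passed`, `reasons` (`;`-separated), `voxel_count`,
#'   `voxel_count_second`, `invalid_voxels`.
#' @export
qcCohort <- function(cohort, minVoxels = 50L) {
  rows <- lapply(cohort, function(les) {
    r <- qcLesion(les$exam1, les$exam2, minVoxels = minVoxels)
    data.frame(lesion_id = r$lesion_id, zone = les$exam1@zone,
               grade_group = les$exam1@gradeGroup, passed = r$passed,
               reasons = paste(r$reasons, collapse = ";"),
               voxel_count = r$voxel_count,
               voxel_count_second = r$voxel_count_second,
               invalid_voxels = r$invalid_voxels,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise cohort QC as a flowchart-style exclusion count
#'
#' @param qc data.frame from [qcCohort()].
#' @return list with `n_lesions`, `n_passed`, `n_excluded` and `exclusions`,
#'   a named list counting each exclusion reason (a lesion failing for
#'   several reasons is counted under each).
#' @export
qcSummary <- function(qc) {
  reasonTab <- table(unlist(strsplit(qc$reasons[!qc$passed], ";")))
  list(n_lesions = nrow(qc), n_passed = sum(qc$passed),
       n_excluded = sum(!qc$passed), exclusions = as.list(reasonTab))
}

#' Write a QC report as JSON lines
#'
#' One JSON object per lesion, mirroring the rows of [qcCohort()].
#'
#' @param qc data.frame from [qcCohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeQcJson <- function(qc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(qc))) {
    rec <- as.list(qc[i, ])
    rec$reasons <- if (nzchar(rec$reasons))
      strsplit(rec$reasons, ";")[[1]] else character()
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write a cohort as voxel CSVs plus a JSON manifest
#'
#' Writes one voxel CSV per lesion-examination (via [writeVoxelCsv()]) and a
#' `manifest.json` recording, per file: lesion id, zone, grade group,
#' examination index and relative path, plus the generating seed when the
#' cohort came from [generateCohort()].
#'
#' @param cohort list of lesions (`exam1`/`exam2` components).
#' @param dir output directory (created if needed).
#' @param seed optional integer recorded in the manifest.
#' @return the manifest path, invisibly.
#' @export
writeCohortCsv <- function(cohort, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (les in cohort) {
    for (ex in c("exam1", "exam2")) {
      acq <- les[[ex]]
      fn <- sprintf("%s_exam%d.csv", acq@lesionId, acq@examIndex)
      writeVoxelCsv(acq, file.path(dir, fn))
      entries[[length(entries) + 1L]] <- list(
        lesion_id = acq@lesionId, zone = acq@zone,
        grade_group = acq@gradeGroup, exam = acq@examIndex, file = fn)
    }
  }
  manifest <- list(seed = seed, n_lesions = length(cohort), files = entries)
  path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' Read a cohort written by [writeCohortCsv()]
#'
#' @param dir directory holding `manifest.json` and the voxel CSVs.
#' @return a cohort list (per lesion: `exam1`, `exam2`).
#' @export
readCohortCsv <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  byLesion <- list()
  for (e in manifest$files) {
    acq <- readVoxelCsv(file.path(dir, e$file), lesionId = e$lesion_id,
                        zone = e$zone, gradeGroup = e$grade_group,
                        examIndex = e$exam)
    key <- e$lesion_id
    if (is.null(byLesion[[key]])) byLesion[[key]] <- list()
    byLesion[[key]][[sprintf("exam%d", e$exam)]] <- acq
  }
  unname(byLesion)
}
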