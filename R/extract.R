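# Feature extraction over lesions and cohorts: every configured base image
# (the four two-b-value ADC maps and the four single-b DWI grids) of both
# examinations yields one 46-feature vector; results are returned as a tidy
# table ready for the screening cascade.

# Named list of base images (values + mask) for one acquisition.
.baseImages <- function(acq, bPairs = .B_PAIRS, dwiBs = .B_VALUES) {
  out <- list()
  for (p in bPairs) {
    m <- computeAdc(acq, p)
    out[[sprintf("ADC(%g,%g)", p[1], p[2])]] <-
      list(values = m@values, mask = m@mask)
  }
  for (b in dwiBs) {
    out[[sprintf("DWI %g", b)]] <-
      list(values = signalGrid(acq, b), mask = acq@mask)
  }
  out
}

#' Extract all texture features of one lesion (both examinations)
#'
#' For every configured base image -- by default the four two-b-value ADC
#' maps (0,1000), (0,1500), (100,1000), (100,1500) and the four single-b DWI
#' grids -- computes the 46-feature vector of [textureFeatureVector()] on
#' each examination. With all defaults this yields 8 base images x 2 exams
#' = 16 feature vectors.
#'
#' @param exam1,exam2 the two [LesionAcquisition-class] examinations.
#' @param nBins gray levels for discretization.
#' @param bPairs list of b-value pairs to map to ADC base images.
#' @param dwiBs b-values used directly as base images.
#' @return tidy data.frame: `lesion_id`, `zone`, `grade_group`, `exam`,
#'   `base_image`, `n_bins`, `feature`, `value`.
#' @export
extractLesionFeatures <- function(exam1, exam2, nBins = 32L,
                                  bPairs = .B_PAIRS, dwiBs = .B_VALUES) {
  stopifnot(identical(exam1@lesionId, exam2@lesionId))
  rows <- list()
  for (acq in list(exam1, exam2)) {
    imgs <- .baseImages(acq, bPairs, dwiBs)
    for (nm in names(imgs)) {
      fv <- textureFeatureVector(imgs[[nm]]$values, imgs[[nm]]$mask, nBins)
      rows[[length(rows) + 1L]] <- data.frame(
        lesion_id = acq@lesionId, zone = acq@zone,
        grade_group = acq@gradeGroup, exam = acq@examIndex,
        base_image = nm, n_bins = as.integer(nBins),
        feature = names(fv), value = unname(fv), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Extract features for a whole cohort
#'
#' Runs [extractLesionFeatures()] over every lesion of a cohort, optionally
#' restricted to QC-passing lesions.
#'
#' @param cohort list of lesions (`exam1`/`exam2` components).
#' @param nBins gray levels for discretization.
#' @param bPairs,dwiBs base-image configuration (see
#'   [extractLesionFeatures()]).
#' @param qc optional data.frame from [qcCohort()]; when given, only lesions
#'   with `passed == TRUE` are extracted.
#' @return tidy feature data.frame (one row per lesion-exam-image-feature).
#' @export
extractCohortFeatures <- function(cohort, nBins = 32L, bPairs = .B_PAIRS,
                                  dwiBs = .B_VALUES, qc = NULL) {
  if (!is.null(qc)) {
    keep <- qc$lesion_id[qc$passed]
    cohort <- Filter(function(l) l$exam1@lesionId %in% keep, cohort)
  }
  if (!length(cohort)) stop("no lesions to extract features from")
  do.call(rbind, lapply(cohort, function(l)
    extractLesionFeatures(l$exam1, l$exam2, nBins, bPairs, dwiBs)))
}
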