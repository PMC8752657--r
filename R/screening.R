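#' Screening pipeline configuration
#'
#' Options of the staged feature-screening cascade.
#'
#' @param alpha significance level of the dual-examination Spearman gate.
#' @param nBins gray levels for feature extraction (may be a vector, e.g.
#'   `c(8, 16, 32)`, for a bin-sensitivity run of [runFullStudy()]).
#' @param baSdExclusionPct Bland-Altman SD (%) above which a feature is
#'   excluded as non-repeatable.
#' @param bPairs list of b-value pairs for ADC base images.
#' @param dwiBs b-values used directly as base images.
#' @param gateMode `"label"` (default): selection requires the dual Spearman
#'   gate and the Bland-Altman rule only, with AUC/ICC bands attached as
#'   descriptive labels; `"strict"`: additionally requires AUC >= 0.7 at both
#'   examinations and ICC >= 0.5 as hard gates.
#' @param exact use exact permutation p-values for the Spearman gate when
#'   n <= 8.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(alpha = 0.05, nBins = 32L, baSdExclusionPct = 300,
                           bPairs = .B_PAIRS, dwiBs = .B_VALUES,
                           gateMode = c("label", "strict"), exact = FALSE) {
  stopifnot(alpha > 0, alpha < 1, baSdExclusionPct > 0)
  structure(list(alpha = alpha, nBins = as.integer(nBins),
                 baSdExclusionPct = baSdExclusionPct, bPairs = bPairs,
                 dwiBs = dwiBs, gateMode = match.arg(gateMode),
                 exact = exact),
            class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat(sprintf("PipelineConfig: alpha %.3g, bins {%s}, BA SD exclusion > %g%%, %d ADC pairs + %d DWI b-values, gate mode '%s'\n",
              x$alpha, paste(x$nBins, collapse = ", "), x$baSdExclusionPct,
              length(x$bPairs), length(x$dwiBs), x$gateMode))
  invisible(x)
}

#' Classification bands for correlation, discrimination and repeatability
#'
#' Band labels with half-open intervals `[low, high)` and the top band
#' closed at 1 (shared endpoints are assigned to the upper band):
#' correlation strength by `|rho|` -- moderate `[0.4, 0.7)`, strong
#' `[0.7, 0.9)`, very strong `[0.9, 1]`; discrimination by AUC -- acceptable
#' `[0.7, 0.8)`, excellent `[0.8, 0.9)`, outstanding `[0.9, 1]`;
#' repeatability by ICC -- moderate `[0.5, 0.75)`, good `[0.75, 0.9)`,
#' excellent `[0.9, 1]`. Values below the lowest band map to `"none"`.
#'
#' @param rho,auc,icc numeric values (vectorized; NA passes through).
#' @return character vector of labels.
#' @examples
#' classifyStrength(-0.45)   # "moderate"
#' classifyAuc(0.85)         # "excellent"
#' classifyIcc(0.75)         # "good"
#' @name classification
NULL

.classifyBands <- function(x, cuts, labels) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- labels[findInterval(x[ok], cuts) + 1L]
  out
}

#' @rdname classification
#' @export
classifyStrength <- function(rho)
  .classifyBands(abs(rho), c(0.4, 0.7, 0.9),
                 c("none", "moderate", "strong", "very strong"))

#' @rdname classification
#' @export
classifyAuc <- function(auc)
  .classifyBands(auc, c(0.7, 0.8, 0.9),
                 c("none", "acceptable", "excellent", "outstanding"))

#' @rdname classification
#' @export
classifyIcc <- function(icc)
  .classifyBands(icc, c(0.5, 0.75, 0.9),
                 c("none", "moderate", "good", "excellent"))

#' Run the feature-screening cascade for one zone
#'
#' The staged screen applied per (base image, feature), over QC-passing
#' lesions of the zone:
#' \enumerate{
#'   \item Spearman correlation with grade group, separately on the
#'     first-examination and second-examination values;
#'   \item only features significant at \emph{both} examinations
#'     (p < alpha twice) advance: ROC AUC for grade group 1-2 vs 3-5 at each
#'     examination (oriented by the sign of the pooled rho), test-retest
#'     ICC(A,1) and Bland-Altman percentage analysis;
#'   \item features whose Bland-Altman SD exceeds
#'     `cfg$baSdExclusionPct` (default 300\%) are excluded as
#'     non-repeatable;
#'   \item classification bands are attached (the correlation and AUC labels
#'     conservatively use the weaker of the two examinations).
#' }
#' A feature is `selected` when it passed every stage (under
#' `gateMode = "strict"`, additionally AUC >= 0.7 at both examinations and
#' ICC >= 0.5).
#'
#' @param cohort list of lesions (`exam1`/`exam2` components).
#' @param zone `"PZ"` or `"TZ"`.
#' @param cfg a [pipelineConfig()].
#' @param nBins gray-level count for this run (a scalar; defaults to the
#'   first entry of `cfg$nBins`).
#' @param features optional pre-computed tidy feature table for this zone
#'   (from [extractCohortFeatures()]); extracted internally when omitted.
#' @param qc optional [qcCohort()] table; computed internally when omitted.
#' @return data.frame with one row per (base_image, feature): Spearman
#'   results per exam, AUC per exam with orientation, ICC with CI,
#'   Bland-Altman statistics, band labels, and the flags `advanced`,
#'   `excluded_by_ba`, `selected`.
#' @export
runZoneAnalysis <- function(cohort, zone, cfg = pipelineConfig(),
                            nBins = cfg$nBins[1], features = NULL, qc = NULL) {
  sub <- Filter(function(l) l$exam1@zone == zone, cohort)
  if (is.null(qc)) qc <- qcCohort(sub) else qc <- qc[qc$zone == zone, ]
  passed <- qc$lesion_id[qc$passed]
  sub <- Filter(function(l) l$exam1@lesionId %in% passed, sub)
  if (length(sub) < 5L)
    stop("zone ", zone, " has fewer than 5 QC-passing lesions")
  gg <- vapply(sub, function(l) l$exam1@gradeGroup, 1L)
  if (length(unique(gg)) < 2L)
    stop("zone ", zone, " analysis aborted: a single grade group is present")
  if (is.null(features))
    features <- extractCohortFeatures(sub, nBins, cfg$bPairs, cfg$dwiBs)
  ids <- vapply(sub, function(l) l$exam1@lesionId, "")

  combos <- unique(features[c("base_image", "feature")])
  combos <- combos[order(combos$base_image, combos$feature), ]
  rows <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    bi <- combos$base_image[k]; ft <- combos$feature[k]
    slab <- features[features$base_image == bi & features$feature == ft, ]
    x1 <- slab$value[match(paste(ids, 1), paste(slab$lesion_id, slab$exam))]
    x2 <- slab$value[match(paste(ids, 2), paste(slab$lesion_id, slab$exam))]
    sp1 <- spearmanVsGG(x1, gg, exact = cfg$exact && length(gg) <= 8)
    sp2 <- spearmanVsGG(x2, gg, exact = cfg$exact && length(gg) <= 8)
    advanced <- isTRUE(sp1$computable) && isTRUE(sp2$computable) &&
      sp1$p_value < cfg$alpha && sp2$p_value < cfg$alpha
    rec <- data.frame(
      zone = zone, base_image = bi, feature = ft, n_bins = as.integer(nBins),
      n_lesions = length(gg),
      rho_first = sp1$rho, p_first = sp1$p_value,
      rho_ci_low_first = sp1$ci_low, rho_ci_high_first = sp1$ci_high,
      rho_second = sp2$rho, p_second = sp2$p_value,
      rho_ci_low_second = sp2$ci_low, rho_ci_high_second = sp2$ci_high,
      advanced = advanced, orientation = NA_real_,
      auc_first = NA_real_, auc_second = NA_real_,
      icc = NA_real_, icc_ci_low = NA_real_, icc_ci_high = NA_real_,
      ba_bias_pct = NA_real_, ba_sd_pct = NA_real_,
      ba_loa_low_pct = NA_real_, ba_loa_high_pct = NA_real_,
      corr_label = NA_character_, auc_label = NA_character_,
      icc_label = NA_character_,
      excluded_by_ba = FALSE, selected = FALSE, stringsAsFactors = FALSE)
    if (advanced) {
      orient <- sign(sp1$rho + sp2$rho)
      if (orient == 0) orient <- 1
      a1 <- rocAucGG(x1, gg, orient)
      a2 <- rocAucGG(x2, gg, orient)
      icc <- iccTestRetest(x1, x2)
      ba <- blandAltmanPct(x1, x2)
      rec$orientation <- orient
      rec$auc_first <- a1$auc; rec$auc_second <- a2$auc
      rec$icc <- icc$icc; rec$icc_ci_low <- icc$ci_low
      rec$icc_ci_high <- icc$ci_high
      rec$ba_bias_pct <- ba$bias_pct; rec$ba_sd_pct <- ba$sd_pct
      rec$ba_loa_low_pct <- ba$loa_low_pct; rec$ba_loa_high_pct <- ba$loa_high_pct
      rec$excluded_by_ba <- isTRUE(ba$sd_pct > cfg$baSdExclusionPct)
      rec$corr_label <- classifyStrength(min(abs(sp1$rho), abs(sp2$rho)))
      rec$auc_label <- classifyAuc(min(a1$auc, a2$auc))
      rec$icc_label <- classifyIcc(icc$icc)
      rec$selected <- !rec$excluded_by_ba &&
        (cfg$gateMode == "label" ||
           (min(a1$auc, a2$auc) >= 0.7 && isTRUE(icc$icc >= 0.5)))
    }
    rows[[k]] <- rec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full study: QC, per-zone cascades, bin sensitivity
#'
#' Applies cohort QC, then runs [runZoneAnalysis()] separately for PZ and TZ
#' at every gray-level setting in `cfg$nBins` (default 32; pass
#' `nBins = c(8, 16, 32)` to [pipelineConfig()] for a bin-sensitivity run).
#'
#' @param cohort list of lesions (`exam1`/`exam2` components).
#' @param cfg a [pipelineConfig()].
#' @return a list of class `StudyBundle`: `qc` (QC table with exclusion
#'   summary as attribute `"summary"`), and `reports`, a list indexed
#'   `"<zone>_bins<k>"` of screening tables.
#' @export
runFullStudy <- function(cohort, cfg = pipelineConfig()) {
  qc <- qcCohort(cohort)
  zones <- intersect(c("PZ", "TZ"),
                     unique(vapply(cohort, function(l) l$exam1@zone, "")))
  reports <- list()
  for (nb in cfg$nBins) {
    for (z in zones) {
      reports[[sprintf("%s_bins%d", z, nb)]] <-
        runZoneAnalysis(cohort, z, cfg, nBins = nb, qc = qc)
    }
  }
  attr(qc, "summary") <- qcSummary(qc)
  structure(list(qc = qc, reports = reports), class = "StudyBundle")
}

#' @export
print.StudyBundle <- function(x, ...) {
  s <- attr(x$qc, "summary")
  cat(sprintf("StudyBundle: %d lesions (%d passed QC, %d excluded)\n",
              s$n_lesions, s$n_passed, s$n_excluded))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %s: %d records, %d advanced, %d selected\n", nm, nrow(r),
                sum(r$advanced), sum(r$selected)))
  }
  invisible(x)
}
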