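#' @import methods
NULL

#' The four diffusion-weighting b-values (s/mm^2) every acquisition carries
#' @keywords internal
.B_VALUES <- c(0, 100, 1000, 1500)

#' The four allowed (b_low, b_high) pairs for two-point ADC mapping
#' @keywords internal
.B_PAIRS <- list(c(0, 1000), c(0, 1500), c(100, 1000), c(100, 1500))

#' Configuration of the synthetic paired-DWI cohort generator
#'
#' Holds every knob of the synthetic test-retest DWI cohort: cohort
#' composition (lesions per prostate zone, grade-group distribution), lesion
#' geometry (grid size, ROI area range), the programmed grade-group effects
#' (peripheral-zone ADC level trend; transition-zone heterogeneity trend), the
#' IVIM-style signal model (perfusion fraction, pseudo-diffusion coefficient,
#' baseline signal) and the acquisition noise (Rician sigma, test-retest mask
#' jitter).
#'
#' All diffusion coefficients are expressed in units of 1e-3 mm^2/s.
#'
#' @slot nLesionsPZ,nLesionsTZ integer; lesions simulated per zone.
#' @slot ggDistributionPZ,ggDistributionTZ numeric(5); probability of grade
#'   groups 1..5 per zone (each sums to 1).
#' @slot gridSize integer; voxels per side of the square simulation grid.
#' @slot lesionAreaRange numeric(2); min/max ROI voxel count.
#' @slot adcMeanInterceptPZ,adcSlopePZ numeric; PZ lesion-mean true diffusion
#'   is intercept + slope * grade group (slope negative: higher grade,
#'   lower diffusivity).
#' @slot adcMeanTZ numeric; TZ lesion-mean true diffusion (no level trend).
#' @slot heterogeneityBase,heterogeneitySlopeTZ numeric; area fraction of the
#'   bright-cluster (baseline-signal) process in TZ lesions is
#'   base + slope * (grade group - 1).
#' @slot s0ClusterContrast,s0ClusterContrastSlope numeric; relative S0
#'   elevation of cluster voxels, contrast + contrastSlope * (grade group -
#'   1). S0 structure shows on every b-value's DWI grid but cancels exactly
#'   in two-point ADC maps.
#' @slot clusterScale,clusterScaleSlope numeric; correlation length of the
#'   cluster process is clusterScale / (1 + clusterScaleSlope * (grade group
#'   - 1)) voxels, so higher grades carry more, smaller clusters.
#' @slot adcFieldSd numeric; standard deviation of the spatially correlated
#'   diffusion field within a lesion.
#' @slot adcBetweenLesionSd numeric; between-lesion standard deviation of the
#'   lesion-mean diffusion level.
#' @slot fieldCorrelationLength numeric; Gaussian smoothing length (voxels) of
#'   the within-lesion random field.
#' @slot perfusionFractionF numeric in [0,1); IVIM perfusion fraction.
#' @slot pseudoDiffusionDstar numeric; IVIM pseudo-diffusion coefficient.
#' @slot s0Mean numeric; mean b=0 signal (arbitrary units).
#' @slot ricianSigma numeric >= 0; Rician noise sigma (signal units).
#' @slot retestMaskJitter integer >= 0; rounds of one-voxel morphological
#'   boundary jitter applied to the second-exam ROI (0 = identical masks).
#' @slot seed integer; master seed, makes cohort generation a pure function
#'   of the configuration.
#' @export
setClass("SyntheticCohortConfig",
  representation(
    nLesionsPZ = "integer", nLesionsTZ = "integer",
    ggDistributionPZ = "numeric", ggDistributionTZ = "numeric",
    gridSize = "integer", lesionAreaRange = "numeric",
    adcMeanInterceptPZ = "numeric", adcSlopePZ = "numeric",
    adcMeanTZ = "numeric",
    heterogeneityBase = "numeric", heterogeneitySlopeTZ = "numeric",
    s0ClusterContrast = "numeric", s0ClusterContrastSlope = "numeric",
    clusterScale = "numeric", clusterScaleSlope = "numeric",
    adcFieldSd = "numeric", adcBetweenLesionSd = "numeric",
    fieldCorrelationLength = "numeric",
    perfusionFractionF = "numeric", pseudoDiffusionDstar = "numeric",
    s0Mean = "numeric", ricianSigma = "numeric",
    retestMaskJitter = "integer", seed = "integer"
  )
)

setValidity("SyntheticCohortConfig", function(object) {
  msg <- character()
  for (gg in list(PZ = object@ggDistributionPZ, TZ = object@ggDistributionTZ)) {
    if (length(gg) != 5L || any(gg < 0) || abs(sum(gg) - 1) > 1e-8)
      msg <- c(msg, "each grade-group distribution must be 5 non-negative probabilities summing to 1")
  }
  if (length(object@lesionAreaRange) != 2L ||
      object@lesionAreaRange[1] > object@lesionAreaRange[2])
    msg <- c(msg, "lesionAreaRange must be an increasing pair")
  if (object@lesionAreaRange[1] < 50)
    msg <- c(msg, "lesionAreaRange minimum must be >= 50 voxels (QC floor)")
  # the largest ROI must be rasterizable on the grid
  if (object@lesionAreaRange[2] > 0.8 * object@gridSize^2)
    msg <- c(msg, sprintf(
      "impossible geometry: max ROI area %g does not fit a %d-voxel grid",
      object@lesionAreaRange[2], object@gridSize))
  if (object@perfusionFractionF < 0 || object@perfusionFractionF >= 1)
    msg <- c(msg, "perfusionFractionF must lie in [0, 1)")
  if (object@pseudoDiffusionDstar <= object@adcMeanInterceptPZ)
    msg <- c(msg, "pseudoDiffusionDstar must exceed adcMeanInterceptPZ")
  if (object@ricianSigma < 0)
    msg <- c(msg, "ricianSigma must be >= 0")
  if (object@retestMaskJitter < 0)
    msg <- c(msg, "retestMaskJitter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth of one synthetic lesion
#'
#' The noise-free state of a simulated lesion: true diffusion field (1e-3
#' mm^2/s), baseline-signal field and ROI mask, plus identifying metadata.
#' Both examinations of a lesion share one `LesionTruth`; only the noise (and
#' optionally the mask, via jitter) differs between them.
#'
#' @slot lesionId character scalar.
#' @slot zone `"PZ"` or `"TZ"`.
#' @slot gradeGroup integer 1..5.
#' @slot diffusionField numeric matrix of true D (1e-3 mm^2/s), positive
#'   inside the mask.
#' @slot s0Field numeric matrix of b=0 signal.
#' @slot mask logical matrix; 8-connected, bounding box >= 4 voxels in each
#'   direction.
#' @export
setClass("LesionTruth",
  representation(
    lesionId = "character", zone = "character", gradeGroup = "integer",
    diffusionField = "matrix", s0Field = "matrix", mask = "matrix"
  )
)

setValidity("LesionTruth", function(object) {
  msg <- character()
  if (!object@zone %in% c("PZ", "TZ")) msg <- c(msg, "zone must be PZ or TZ")
  if (is.na(object@gradeGroup) || object@gradeGroup < 1L || object@gradeGroup > 5L)
    msg <- c(msg, "gradeGroup must be an integer in 1..5")
  dims <- list(dim(object@diffusionField), dim(object@s0Field), dim(object@mask))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    msg <- c(msg, "diffusionField, s0Field and mask must share one shape")
  m <- object@mask
  if (!is.logical(m)) msg <- c(msg, "mask must be logical")
  else if (!any(m)) msg <- c(msg, "mask must contain at least one voxel")
  else {
    if (any(object@diffusionField[m] <= 0))
      msg <- c(msg, "diffusionField must be positive inside the mask")
    ext <- .maskExtent(m)
    if (any(ext < 4L))
      msg <- c(msg, "mask bounding box must span >= 4 voxels in each direction")
    if (.countComponents(m) != 1L)
      msg <- c(msg, "mask must be 8-connected")
  }
  if (length(msg)) msg else TRUE
})

#' One examination of one lesion
#'
#' Four co-registered signal grids (b = 0, 100, 1000, 1500 s/mm^2) with the
#' ROI mask and lesion metadata. This is the unit the voxel-CSV dialect
#' serialises and the unit ADC mapping and feature extraction consume.
#'
#' @slot lesionId character scalar.
#' @slot zone `"PZ"` or `"TZ"`.
#' @slot gradeGroup integer 1..5, or NA when unknown (e.g. a bare CSV read
#'   without its manifest).
#' @slot examIndex integer, 1 or 2.
#' @slot signals named list of numeric matrices, names `"0"`, `"100"`,
#'   `"1000"`, `"1500"`.
#' @slot mask logical matrix, same shape as the signal grids.
#' @slot voxelSize numeric; in-plane voxel size in mm (metadata only).
#' @export
setClass("LesionAcquisition",
  representation(
    lesionId = "character", zone = "character", gradeGroup = "integer",
    examIndex = "integer", signals = "list", mask = "matrix",
    voxelSize = "numeric"
  )
)

setValidity("LesionAcquisition", function(object) {
  msg <- character()
  if (!object@zone %in% c("PZ", "TZ")) msg <- c(msg, "zone must be PZ or TZ")
  if (!is.na(object@gradeGroup) &&
      (object@gradeGroup < 1L || object@gradeGroup > 5L))
    msg <- c(msg, "gradeGroup must be in 1..5 or NA")
  if (!object@examIndex %in% c(1L, 2L)) msg <- c(msg, "examIndex must be 1 or 2")
  if (!identical(sort(as.numeric(names(object@signals))), .B_VALUES))
    msg <- c(msg, "signals must carry exactly b = 0, 100, 1000, 1500 s/mm^2")
  shp <- vapply(object@signals, function(g) paste(dim(g), collapse = "x"), "")
  if (length(unique(c(shp, paste(dim(object@mask), collapse = "x")))) != 1L)
    msg <- c(msg, "all signal grids and the mask must share one shape")
  if (!is.logical(object@mask) || !any(object@mask))
    msg <- c(msg, "mask must be logical with at least one TRUE voxel")
  if (length(msg)) msg else TRUE
})

#' A per-voxel ADC map for one b-value pair
#'
#' Apparent diffusion coefficient (mm^2/s) computed voxel-wise from two
#' b-values by the exact two-point monoexponential fit. Negative values are
#' preserved (downstream QC decides exclusion); voxels whose signal is
#' non-positive at either b-value are set to NA and counted in
#' `invalidCount`.
#'
#' @slot bLow,bHigh numeric b-values (s/mm^2), `bHigh > bLow`.
#' @slot values numeric matrix of ADC in mm^2/s.
#' @slot mask logical matrix.
#' @slot examIndex integer 1 or 2.
#' @slot invalidCount integer; in-ROI voxels with non-positive signal.
#' @export
setClass("AdcMap",
  representation(
    bLow = "numeric", bHigh = "numeric", values = "matrix",
    mask = "matrix", examIndex = "integer", invalidCount = "integer"
  )
)

setValidity("AdcMap", function(object) {
  msg <- character()
  if (object@bHigh <= object@bLow) msg <- c(msg, "bHigh must exceed bLow")
  if (!any(vapply(.B_PAIRS, function(p)
    isTRUE(all.equal(p, c(object@bLow, object@bHigh))), NA)))
    msg <- c(msg, "b-pair must be one of (0,1000), (0,1500), (100,1000), (100,1500)")
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must share one shape")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticCohortConfig", function(object) {
  cat("SyntheticCohortConfig\n")
  cat(sprintf("  cohort: %d PZ + %d TZ lesions, grid %dx%d, ROI area [%g, %g]\n",
              object@nLesionsPZ, object@nLesionsTZ, object@gridSize,
              object@gridSize, object@lesionAreaRange[1], object@lesionAreaRange[2]))
  cat(sprintf("  GG distribution PZ: %s\n", paste(signif(object@ggDistributionPZ, 3), collapse = " ")))
  cat(sprintf("  GG distribution TZ: %s\n", paste(signif(object@ggDistributionTZ, 3), collapse = " ")))
  cat(sprintf("  PZ level trend: D = %.3f %+.3f * GG (1e-3 mm^2/s)\n",
              object@adcMeanInterceptPZ, object@adcSlopePZ))
  cat(sprintf("  TZ: mean D = %.3f, S0 cluster fraction %.2f + %.2f * (GG-1), contrast %.2f + %.2f * (GG-1), scale %.1f / (1 + %.2f * (GG-1)) vx\n",
              object@adcMeanTZ, object@heterogeneityBase,
              object@heterogeneitySlopeTZ, object@s0ClusterContrast,
              object@s0ClusterContrastSlope, object@clusterScale,
              object@clusterScaleSlope))
  cat(sprintf("  field: sd %.3f, correlation length %.1f vx; between-lesion sd %.3f\n",
              object@adcFieldSd, object@fieldCorrelationLength, object@adcBetweenLesionSd))
  cat(sprintf("  signal: S0 %.0f, IVIM f = %.2f, D* = %.1f; Rician sigma %.2f\n",
              object@s0Mean, object@perfusionFractionF,
              object@pseudoDiffusionDstar, object@ricianSigma))
  cat(sprintf("  retest mask jitter: %d, seed: %d\n",
              object@retestMaskJitter, object@seed))
})

setMethod("show", "LesionTruth", function(object) {
  cat(sprintf("LesionTruth %s [%s, GG %d]: %d-voxel ROI on %dx%d grid, mean D %.3f (1e-3 mm^2/s)\n",
              object@lesionId, object@zone, object@gradeGroup,
              sum(object@mask), nrow(object@mask), ncol(object@mask),
              mean(object@diffusionField[object@mask])))
})

setMethod("show", "LesionAcquisition", function(object) {
  cat(sprintf("LesionAcquisition %s [%s, GG %s, exam %d]: %d-voxel ROI, grids %dx%d, b = {0, 100, 1000, 1500}\n",
              object@lesionId, object@zone,
              ifelse(is.na(object@gradeGroup), "?", object@gradeGroup),
              object@examIndex, sum(object@mask), nrow(object@mask), ncol(object@mask)))
})

setMethod("show", "AdcMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("AdcMap (%g, %g) exam %d: %d ROI voxels, median %.3f x1e-3 mm^2/s, %d invalid\n",
              object@bLow, object@bHigh, object@examIndex, sum(object@mask),
              stats::median(v, na.rm = TRUE) * 1e3, object@invalidCount))
})
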