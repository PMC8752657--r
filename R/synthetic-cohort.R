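#' Construct a synthetic-cohort configuration
#'
#' Builds a validated [SyntheticCohortConfig-class]. Defaults emulate the
#' study conditions of a paired test-retest prostate DWI cohort: 30
#' peripheral-zone (PZ) and 19 transition-zone (TZ) lesions with ROI areas of
#' 58-271 voxels on a 24x24 grid, a grade-group distribution concentrated on
#' GG 2-3, a negative PZ diffusivity trend of -0.08e-3 mm^2/s per grade-group
#' step, and a TZ heterogeneity (low-diffusion cluster) trend with no level
#' trend. Signals follow a bi-exponential IVIM-style decay with Rician
#' magnitude noise.
#'
#' @param nLesionsPZ,nLesionsTZ lesions per zone.
#' @param ggDistributionPZ,ggDistributionTZ probabilities of grade groups
#'   1..5 per zone; each must sum to 1.
#' @param gridSize voxels per side of the simulation grid.
#' @param lesionAreaRange min/max ROI voxel count; the minimum must be >= 50
#'   so that default cohorts pass the ROI-size QC floor.
#' @param adcMeanInterceptPZ,adcSlopePZ PZ lesion-mean true diffusivity model
#'   `intercept + slope * GG` (1e-3 mm^2/s; slope negative).
#' @param adcMeanTZ TZ lesion-mean true diffusivity (1e-3 mm^2/s), flat in GG.
#' @param heterogeneityBase,heterogeneitySlopeTZ TZ bright-cluster area
#'   fraction `base + slope * (GG - 1)` (dimensionless).
#' @param s0ClusterContrast,s0ClusterContrastSlope relative baseline-signal
#'   elevation of TZ cluster voxels, `contrast + slope * (GG - 1)`.
#' @param clusterScale,clusterScaleSlope correlation length of the TZ
#'   cluster process, `scale / (1 + slope * (GG - 1))` voxels (higher grade:
#'   more, smaller clusters).
#' @param adcFieldSd within-lesion field standard deviation (1e-3 mm^2/s).
#' @param adcBetweenLesionSd between-lesion SD of the mean level
#'   (1e-3 mm^2/s).
#' @param fieldCorrelationLength spatial correlation length (voxels).
#' @param perfusionFractionF IVIM perfusion fraction, in `[0, 1)`.
#' @param pseudoDiffusionDstar IVIM pseudo-diffusion coefficient
#'   (1e-3 mm^2/s); must exceed `adcMeanInterceptPZ`.
#' @param s0Mean mean b=0 signal (arbitrary units).
#' @param ricianSigma Rician noise sigma (signal units).
#' @param retestMaskJitter rounds of one-voxel morphological boundary jitter
#'   for the second-exam ROI (0 = identical masks).
#' @param seed master seed; the generated cohort is a pure function of the
#'   configuration, seed included.
#' @return a [SyntheticCohortConfig-class] object.
#' @examples
#' cfg <- syntheticCohortConfig(nLesionsPZ = 4, nLesionsTZ = 2, seed = 7)
#' cfg
#' @export
syntheticCohortConfig <- function(nLesionsPZ = 30L, nLesionsTZ = 19L,
                                  ggDistributionPZ = c(1, 27, 16, 3, 2) / 49,
                                  ggDistributionTZ = c(1, 27, 16, 3, 2) / 49,
                                  gridSize = 24L,
                                  lesionAreaRange = c(58, 271),
                                  adcMeanInterceptPZ = 1.10,
                                  adcSlopePZ = -0.08,
                                  adcMeanTZ = 0.90,
                                  heterogeneityBase = 0.05,
                                  heterogeneitySlopeTZ = 0.05,
                                  s0ClusterContrast = 0.20,
                                  s0ClusterContrastSlope = 0.07,
                                  clusterScale = 1.8,
                                  clusterScaleSlope = 0.40,
                                  adcFieldSd = 0.12,
                                  adcBetweenLesionSd = 0.05,
                                  fieldCorrelationLength = 2,
                                  perfusionFractionF = 0.10,
                                  pseudoDiffusionDstar = 10,
                                  s0Mean = 100,
                                  ricianSigma = 2,
                                  retestMaskJitter = 1L,
                                  seed = 1L) {
  new("SyntheticCohortConfig",
      nLesionsPZ = as.integer(nLesionsPZ), nLesionsTZ = as.integer(nLesionsTZ),
      ggDistributionPZ = as.numeric(ggDistributionPZ),
      ggDistributionTZ = as.numeric(ggDistributionTZ),
      gridSize = as.integer(gridSize),
      lesionAreaRange = as.numeric(lesionAreaRange),
      adcMeanInterceptPZ = adcMeanInterceptPZ, adcSlopePZ = adcSlopePZ,
      adcMeanTZ = adcMeanTZ,
      heterogeneityBase = heterogeneityBase,
      heterogeneitySlopeTZ = heterogeneitySlopeTZ,
      s0ClusterContrast = s0ClusterContrast,
      s0ClusterContrastSlope = s0ClusterContrastSlope,
      clusterScale = clusterScale, clusterScaleSlope = clusterScaleSlope,
      adcFieldSd = adcFieldSd, adcBetweenLesionSd = adcBetweenLesionSd,
      fieldCorrelationLength = fieldCorrelationLength,
      perfusionFractionF = perfusionFractionF,
      pseudoDiffusionDstar = pseudoDiffusionDstar,
      s0Mean = s0Mean, ricianSigma = ricianSigma,
      retestMaskJitter = as.integer(retestMaskJitter),
      seed = as.integer(seed))
}

#' Read a synthetic-cohort configuration from YAML
#'
#' Reads a flat YAML file whose keys are the argument names of
#' [syntheticCohortConfig()]; unspecified keys take the defaults.
#'
#' @param path path to a YAML file.
#' @return a [SyntheticCohortConfig-class] object.
#' @export
cohortConfigFromYaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(syntheticCohortConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(syntheticCohortConfig, vals)
}

# Rasterize a randomly perturbed, randomly oriented ellipse whose scale is
# binary-searched so the voxel count lands inside [areaMin, areaMax].
# Consumes the current RNG.
.randomBlobMask <- function(gridSize, areaMin, areaMax) {
  n <- gridSize
  cx <- (n + 1) / 2 + stats::runif(1, -1, 1)
  cy <- (n + 1) / 2 + stats::runif(1, -1, 1)
  ecc <- stats::runif(1, 1, 1.5)            # axis ratio
  th0 <- stats::runif(1, 0, pi)             # orientation
  amp <- stats::rnorm(3, 0, 0.06)           # boundary harmonics 2..4
  phs <- stats::runif(3, 0, 2 * pi)
  target <- stats::runif(1, areaMin, areaMax)

  xy <- expand.grid(r = seq_len(n), c = seq_len(n))
  dx <- xy$r - cx; dy <- xy$c - cy
  u <- dx * cos(th0) + dy * sin(th0)
  v <- -dx * sin(th0) + dy * cos(th0)
  rho <- sqrt((u / ecc)^2 + (v * ecc)^2)
  ang <- atan2(v, u)
  mod <- 1 + amp[1] * cos(2 * ang + phs[1]) + amp[2] * cos(3 * ang + phs[2]) +
    amp[3] * cos(4 * ang + phs[3])
  mod <- pmax(mod, 0.5)
  score <- rho / mod                        # mask = score <= s, monotone in s

  lo <- 0; hi <- n
  for (it in 1:40) {
    s <- (lo + hi) / 2
    a <- sum(score <= s)
    if (a < target) lo <- s else hi <- s
    if (a >= areaMin && a <= areaMax && abs(a - target) <= 2) break
  }
  mask <- matrix(score <= (lo + hi) / 2, n, n)
  mask <- .largestComponent(mask)
  area <- sum(mask)
  if (area < areaMin || area > areaMax || any(.maskExtent(mask) < 4L))
    return(NULL)
  mask
}

#' Generate the ground truth of one synthetic lesion
#'
#' Draws a random ROI (perturbed ellipse with area in
#' `cfg@lesionAreaRange`), a spatially correlated true-diffusivity field and
#' a baseline-signal field. In the PZ the lesion-mean diffusivity follows the
#' programmed level trend `adcMeanInterceptPZ + adcSlopePZ * gradeGroup`; the
#' diffusivity field is clipped positive. In the TZ the diffusivity mean is
#' flat at `adcMeanTZ` and grade-dependent *heterogeneity* is programmed into
#' the baseline-signal field instead: a bright-cluster process (interspersed
#' glandular/stromal tissue) whose area fraction, relative contrast and
#' fragmentation all grow with grade group. Baseline-signal structure is
#' visible on every b-value's DWI grid but cancels exactly in two-point ADC
#' maps, so ADC level percentiles carry no grade trend in the TZ.
#'
#' @param cfg a [SyntheticCohortConfig-class].
#' @param zone `"PZ"` or `"TZ"`.
#' @param gradeGroup integer 1..5.
#' @param seed integer seed; the result is a pure function of the arguments.
#' @param lesionId identifier stored in the result.
#' @return a [LesionTruth-class] object.
#' @examples
#' cfg <- syntheticCohortConfig()
#' tr <- generateLesionTruth(cfg, "PZ", 3L, seed = 11)
#' tr
#' @export
generateLesionTruth <- function(cfg, zone, gradeGroup, seed,
                                lesionId = sprintf("%s-%03d", zone, seed %% 1000L)) {
  stopifnot(is(cfg, "SyntheticCohortConfig"))
  validObject(cfg)
  gradeGroup <- as.integer(gradeGroup)
  if (gradeGroup < 1L || gradeGroup > 5L) stop("gradeGroup must be in 1..5")
  .withSeed(seed, {
    mask <- NULL
    for (try in 1:50) {
      mask <- .randomBlobMask(cfg@gridSize, cfg@lesionAreaRange[1],
                              cfg@lesionAreaRange[2])
      if (!is.null(mask)) break
    }
    if (is.null(mask))
      stop("impossible geometry: could not place an ROI of area [",
           cfg@lesionAreaRange[1], ", ", cfg@lesionAreaRange[2],
           "] on a ", cfg@gridSize, "-voxel grid")

    mu <- if (zone == "PZ") {
      cfg@adcMeanInterceptPZ + cfg@adcSlopePZ * gradeGroup
    } else cfg@adcMeanTZ
    mu <- mu + stats::rnorm(1, 0, cfg@adcBetweenLesionSd)

    field <- pmax(mu + cfg@adcFieldSd *
      .gaussianField(cfg@gridSize, cfg@gridSize, cfg@fieldCorrelationLength),
      0.05)

    s0 <- cfg@s0Mean * pmax(1 + 0.05 *
      .gaussianField(cfg@gridSize, cfg@gridSize, cfg@fieldCorrelationLength), 0.2)

    if (zone == "TZ") {
      frac <- min(max(cfg@heterogeneityBase +
                        cfg@heterogeneitySlopeTZ * (gradeGroup - 1), 0), 0.6)
      contrast <- cfg@s0ClusterContrast +
        cfg@s0ClusterContrastSlope * (gradeGroup - 1)
      if (frac > 0 && contrast > 0) {
        lam <- cfg@clusterScale / (1 + cfg@clusterScaleSlope * (gradeGroup - 1))
        clusterField <- .gaussianField(cfg@gridSize, cfg@gridSize, lam)
        thr <- stats::quantile(clusterField[mask], 1 - frac, names = FALSE)
        s0[clusterField > thr] <- s0[clusterField > thr] * (1 + contrast)
      }
    }

    new("LesionTruth", lesionId = lesionId, zone = zone,
        gradeGroup = gradeGroup, diffusionField = field, s0Field = s0,
        mask = mask)
  })
}

# One round of morphological boundary jitter: each dilation-ring voxel is
# added and each erosion-ring voxel removed with probability 0.25; the mask
# is then restored to its largest 8-connected component. Reverts if the
# result would fall below the QC floor.
.jitterMaskOnce <- function(mask) {
  nb <- matrix(0L, nrow(mask), ncol(mask))
  for (d in .NEIGH8) nb <- nb + .shiftGrid(mask, d[1], d[2], FALSE)
  ring_out <- !mask & nb > 0L
  ring_in <- mask & nb < 8L
  out <- mask
  out[ring_out] <- stats::runif(sum(ring_out)) < 0.25
  drop <- ring_in & matrix(stats::runif(length(mask)) < 0.25,
                           nrow(mask), ncol(mask))
  out[drop] <- FALSE
  out <- .largestComponent(out)
  if (sum(out) < 52L || any(.maskExtent(out) < 4L)) mask else out
}

#' Simulate one DWI examination of a lesion
#'
#' Evaluates the bi-exponential IVIM-style signal decay
#' \deqn{S(b) = S_0 [ f e^{-b D^*} + (1 - f) e^{-b D} ]}
#' at b = 0, 100, 1000, 1500 s/mm^2 on the lesion's true fields and adds
#' Rician magnitude noise (the magnitude of complex Gaussian noise around the
#' noiseless signal), drawn independently per voxel, b-value and examination.
#' Exam 2 reuses the shared truth field; when `cfg@retestMaskJitter > 0` its
#' ROI is a morphologically jittered copy of the exam-1 ROI.
#'
#' @param truth a [LesionTruth-class].
#' @param cfg a [SyntheticCohortConfig-class].
#' @param examIndex 1 or 2.
#' @param seed integer seed; identical arguments give identical grids.
#' @return a [LesionAcquisition-class].
#' @examples
#' cfg <- syntheticCohortConfig(ricianSigma = 0)
#' tr <- generateLesionTruth(cfg, "PZ", 2L, seed = 3)
#' acq <- simulateAcquisition(tr, cfg, examIndex = 1L, seed = 3)
#' acq
#' @export
simulateAcquisition <- function(truth, cfg, examIndex, seed) {
  stopifnot(is(truth, "LesionTruth"), is(cfg, "SyntheticCohortConfig"))
  validObject(cfg)
  examIndex <- as.integer(examIndex)
  if (!examIndex %in% c(1L, 2L)) stop("examIndex must be 1 or 2")
  .withSeed(.deriveSeed(seed, examIndex), {
    mask <- truth@mask
    if (examIndex == 2L && cfg@retestMaskJitter > 0L)
      for (k in seq_len(cfg@retestMaskJitter)) mask <- .jitterMaskOnce(mask)

    f <- cfg@perfusionFractionF
    dstar <- cfg@pseudoDiffusionDstar * 1e-3   # mm^2/s
    d <- truth@diffusionField * 1e-3
    signals <- lapply(.B_VALUES, function(b) {
      s <- truth@s0Field * (f * exp(-b * dstar) + (1 - f) * exp(-b * d))
      if (cfg@ricianSigma > 0) {
        n1 <- matrix(stats::rnorm(length(s), 0, cfg@ricianSigma), nrow(s))
        n2 <- matrix(stats::rnorm(length(s), 0, cfg@ricianSigma), nrow(s))
        s <- sqrt((s + n1)^2 + n2^2)
      }
      s
    })
    names(signals) <- as.character(.B_VALUES)
    new("LesionAcquisition", lesionId = truth@lesionId, zone = truth@zone,
        gradeGroup = truth@gradeGroup, examIndex = examIndex,
        signals = signals, mask = mask, voxelSize = 1.0)
  })
}

#' Generate a paired test-retest DWI cohort
#'
#' Draws grade groups from the per-zone distributions and, for every lesion,
#' generates one shared [LesionTruth-class] and two [LesionAcquisition-class]
#' examinations with independent noise. Fully reproducible from `cfg@seed`.
#'
#' @param cfg a [SyntheticCohortConfig-class].
#' @return a list with one element per lesion, each a list with components
#'   `truth`, `exam1`, `exam2`.
#' @examples
#' cfg <- syntheticCohortConfig(nLesionsPZ = 2L, nLesionsTZ = 1L, seed = 5)
#' coh <- generateCohort(cfg)
#' length(coh)
#' @export
generateCohort <- function(cfg) {
  stopifnot(is(cfg, "SyntheticCohortConfig"))
  validObject(cfg)
  zones <- c(rep("PZ", cfg@nLesionsPZ), rep("TZ", cfg@nLesionsTZ))
  ggs <- .withSeed(.deriveSeed(cfg@seed, 0L), {
    c(sample(1:5, cfg@nLesionsPZ, replace = TRUE, prob = cfg@ggDistributionPZ),
      sample(1:5, cfg@nLesionsTZ, replace = TRUE, prob = cfg@ggDistributionTZ))
  })
  lapply(seq_along(zones), function(i) {
    id <- sprintf("%s-%03d", zones[i], i)
    truth <- generateLesionTruth(cfg, zones[i], ggs[i],
                                 seed = .deriveSeed(cfg@seed, i, 1L),
                                 lesionId = id)
    list(truth = truth,
         exam1 = simulateAcquisition(truth, cfg, 1L, .deriveSeed(cfg@seed, i, 2L)),
         exam2 = simulateAcquisition(truth, cfg, 2L, .deriveSeed(cfg@seed, i, 3L)))
  })
}
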