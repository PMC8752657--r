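#' Compute a per-voxel ADC map from one b-value pair
#'
#' Two-point monoexponential fit: with signals \eqn{S(b_{low})} and
#' \eqn{S(b_{high})}, the apparent diffusion coefficient of a voxel is
#' \deqn{ADC = \frac{\ln(S(b_{low}) / S(b_{high}))}{b_{high} - b_{low}}}
#' in mm^2/s. With two observations the monoexponential fit is exact, so no
#' least-squares machinery is involved. The map covers the full grid;
#' downstream consumers read the masked voxels. Negative ADC values are
#' preserved (lesion QC decides exclusion). Voxels with a non-positive signal
#' at either b-value get NA and are counted in the `invalidCount` slot.
#'
#' @param acq a [LesionAcquisition-class].
#' @param bPair numeric pair `(b_low, b_high)`, one of (0,1000), (0,1500),
#'   (100,1000), (100,1500).
#' @return an [AdcMap-class]; values in mm^2/s.
#' @examples
#' cfg <- syntheticCohortConfig(ricianSigma = 0, perfusionFractionF = 0)
#' tr <- generateLesionTruth(cfg, "PZ", 2L, seed = 1)
#' acq <- simulateAcquisition(tr, cfg, 1L, seed = 1)
#' m <- computeAdc(acq, c(0, 1000))
#' m
#' @export
computeAdc <- function(acq, bPair) {
  stopifnot(is(acq, "LesionAcquisition"))
  bPair <- as.numeric(bPair)
  ok <- any(vapply(.B_PAIRS, function(p) isTRUE(all.equal(p, bPair)), NA))
  if (!ok)
    stop("bPair must be one of: ",
         paste(vapply(.B_PAIRS, function(p)
           sprintf("(%g, %g)", p[1], p[2]), ""), collapse = ", "))
  sLow <- signalGrid(acq, bPair[1])
  sHigh <- signalGrid(acq, bPair[2])
  values <- matrix(NA_real_, nrow(sLow), ncol(sLow))
  valid <- sLow > 0 & sHigh > 0
  values[valid] <- log(sLow[valid] / sHigh[valid]) / (bPair[2] - bPair[1])
  new("AdcMap", bLow = bPair[1], bHigh = bPair[2], values = values,
      mask = acq@mask, examIndex = acq@examIndex,
      invalidCount = sum(!valid & acq@mask))
}

#' Rescale ADC values to the reporting unit
#'
#' ADC maps are stored in mm^2/s; summaries are conventionally reported in
#' units of 1e-3 mm^2/s. `adcSummaryScale()` converts between the two
#' (`inverse = TRUE` maps reported values back to storage units).
#'
#' @param x an [AdcMap-class] or numeric values in mm^2/s (or, with
#'   `inverse = TRUE`, in 1e-3 mm^2/s).
#' @param inverse convert reporting units back to mm^2/s.
#' @return numeric values (matrix or vector, as supplied).
#' @examples
#' adcSummaryScale(0.0008)                 # 0.8 x 1e-3 mm^2/s
#' adcSummaryScale(adcSummaryScale(0.0008), inverse = TRUE)
#' @export
adcSummaryScale <- function(x, inverse = FALSE) {
  v <- if (is(x, "AdcMap")) adcValues(x) else x
  if (inverse) v / 1e3 else v * 1e3
}

# All four ADC maps of one acquisition.
.allAdcMaps <- function(acq) {
  maps <- lapply(.B_PAIRS, function(p) computeAdc(acq, p))
  names(maps) <- vapply(.B_PAIRS, function(p)
    sprintf("ADC(%g,%g)", p[1], p[2]), "")
  maps
}
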