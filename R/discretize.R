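#' Discretize in-ROI values onto a fixed number of gray levels
#'
#' Fixed-bin-number, in-ROI min-max discretization:
#' \deqn{level(x) = 1 + \lfloor n_{bins} (x - min) / (max - min) \rfloor}
#' clamped to `nBins` (so the maximum maps to level `nBins`). A constant ROI
#' maps every voxel to level 1. Voxels outside the mask (or NA inside it,
#' e.g. invalid ADC voxels) get level 0 and are excluded from all texture
#' matrices.
#'
#' @param values numeric matrix (e.g. an ADC map or one b-value's signal
#'   grid), or an [AdcMap-class].
#' @param mask logical matrix; defaults to the map's own mask when `values`
#'   is an [AdcMap-class].
#' @param nBins number of gray levels (>= 2; 8, 16 or 32 in practice).
#' @return an object of class `DiscretizedRoi`: list with `bins` (integer
#'   matrix, 0 outside the ROI), `mask` (the effective mask: supplied mask
#'   minus NA voxels), `nBins`, `sourceMin`, `sourceMax`.
#' @examples
#' v <- matrix(c(0, 0.5, 1, 0.2), 2, 2)
#' discretizeRoi(v, matrix(TRUE, 2, 2), nBins = 2)$bins
#' @export
discretizeRoi <- function(values, mask = NULL, nBins = 32L) {
  if (is(values, "AdcMap")) {
    if (is.null(mask)) mask <- values@mask
    values <- values@values
  }
  if (is.null(mask)) stop("mask is required")
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be >= 2")
  mask <- mask & !is.na(values)
  if (!any(mask)) stop("no usable in-ROI voxels to discretize")
  x <- values[mask]
  lo <- min(x); hi <- max(x)
  bins <- matrix(0L, nrow(values), ncol(values))
  if (hi > lo) {
    lev <- 1L + as.integer(floor(nBins * (values[mask] - lo) / (hi - lo)))
    bins[mask] <- pmin(lev, nBins)
  } else {
    bins[mask] <- 1L
  }
  structure(list(bins = bins, mask = mask, nBins = nBins,
                 sourceMin = lo, sourceMax = hi),
            class = "DiscretizedRoi")
}

#' @export
print.DiscretizedRoi <- function(x, ...) {
  cat(sprintf("DiscretizedRoi: %d voxels on %d levels, source range [%g, %g]\n",
              sum(x$mask), x$nBins, x$sourceMin, x$sourceMax))
  invisible(x)
}
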