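#' @rdname accessors
#' @export
setGeneric("lesionId", function(x) standardGeneric("lesionId"))
#' @rdname accessors
#' @export
setGeneric("zone", function(x) standardGeneric("zone"))
#' @rdname accessors
#' @export
setGeneric("gradeGroup", function(x) standardGeneric("gradeGroup"))
#' @rdname accessors
#' @export
setGeneric("examIndex", function(x) standardGeneric("examIndex"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("signalGrid", function(x, b) standardGeneric("signalGrid"))
#' @rdname accessors
#' @export
setGeneric("adcValues", function(x) standardGeneric("adcValues"))
#' @rdname accessors
#' @export
setGeneric("bPair", function(x) standardGeneric("bPair"))
#' @rdname accessors
#' @export
setGeneric("maskedValues", function(x) standardGeneric("maskedValues"))

#' Accessors for lesion objects
#'
#' Small read-only accessors for the central S4 classes
#' ([LesionTruth-class], [LesionAcquisition-class], [AdcMap-class]):
#' lesion identity and labels, ROI mask, signal grids by b-value, ADC values
#' and b-pair, and `maskedValues()` for the vector of in-ROI values that
#' downstream feature extraction consumes.
#'
#' @param x an object of one of the classes above.
#' @param b numeric b-value in s/mm^2 (one of 0, 100, 1000, 1500).
#' @return the corresponding slot value; `maskedValues()` returns a numeric
#'   vector of in-ROI values; `bPair()` a numeric pair `(b_low, b_high)`.
#' @name accessors
NULL

setMethod("lesionId", "LesionTruth", function(x) x@lesionId)
setMethod("lesionId", "LesionAcquisition", function(x) x@lesionId)
setMethod("zone", "LesionTruth", function(x) x@zone)
setMethod("zone", "LesionAcquisition", function(x) x@zone)
setMethod("gradeGroup", "LesionTruth", function(x) x@gradeGroup)
setMethod("gradeGroup", "LesionAcquisition", function(x) x@gradeGroup)
setMethod("examIndex", "LesionAcquisition", function(x) x@examIndex)
setMethod("examIndex", "AdcMap", function(x) x@examIndex)
setMethod("roiMask", "LesionTruth", function(x) x@mask)
setMethod("roiMask", "LesionAcquisition", function(x) x@mask)
setMethod("roiMask", "AdcMap", function(x) x@mask)

setMethod("signalGrid", "LesionAcquisition", function(x, b) {
  key <- as.character(b)
  if (!key %in% names(x@signals))
    stop("no signal grid for b = ", b, "; available: ",
         paste(names(x@signals), collapse = ", "))
  x@signals[[key]]
})

setMethod("adcValues", "AdcMap", function(x) x@values)
setMethod("bPair", "AdcMap", function(x) c(x@bLow, x@bHigh))
setMethod("maskedValues", "AdcMap", function(x) x@values[x@mask])
setMethod("maskedValues", "LesionTruth", function(x) x@diffusionField[x@mask])
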