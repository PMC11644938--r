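#' Accessors for spectral containers and fitted models
#'
#' @param x a \linkS4class{SpectralSet}, \linkS4class{SelectedBandSet},
#'   or \linkS4class{BSDRModel}.
#' @name accessors
NULL

#' @describeIn accessors samples-by-bands reflectance matrix.
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @describeIn accessors target vector (integer 0-based codes for
#'   classification, numeric response for regression).
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @describeIn accessors task kind, \code{"classification"} or
#'   \code{"regression"}.
#' @export
setGeneric("taskKind", function(x) standardGeneric("taskKind"))

#' @describeIn accessors number of spectral bands L.
#' @export
setGeneric("bandCount", function(x) standardGeneric("bandCount"))

#' @describeIn accessors number of classes K (classification only).
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @describeIn accessors mapping from original class labels to 0-based codes.
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @describeIn accessors sorted unique 1-based selected band indices.
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))

#' @describeIn accessors number of unique selected bands t' (<= t).
#' @export
setGeneric("tPrime", function(x) standardGeneric("tPrime"))

#' @describeIn accessors per-epoch training trace as a data.frame.
#' @export
setGeneric("trainingTrace", function(x) standardGeneric("trainingTrace"))

#' @describeIn accessors the \linkS4class{SelectedBandSet} of a fitted model.
#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))

#' @describeIn accessors current normalized band indices in (0, 1).
#' @export
setGeneric("normalizedIndices",
           function(x) standardGeneric("normalizedIndices"))
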