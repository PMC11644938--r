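#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

#' SpectralSet: single-pixel hyperspectral data with a prediction target
#'
#' A container for N single-pixel hyperspectral samples over L spectral
#' bands, plus one target variable (a class label or a continuous
#' response). It extends \linkS4class{SummarizedExperiment}: the
#' \code{"reflectance"} assay is stored bands x samples (the Bioconductor
#' features-by-samples convention) and the target lives in
#' \code{colData()$target}. Use \code{\link{reflectance}} to obtain the
#' samples-by-bands matrix the selection algorithm operates on.
#'
#' @slot task character, \code{"classification"} or \code{"regression"}.
#' @slot labelMap named integer vector mapping original class labels to
#'   the contiguous 0-based codes stored in \code{colData()$target}
#'   (empty for regression).
#'
#' @details Invariants enforced by the validity method: no missing
#' reflectance values; at least two bands (interpolation between adjacent
#' bands must be possible); classification targets form a contiguous
#' 0-based label set with at least two classes.
#'
#' @seealso \code{\link{spectralSet}}, \code{\link{readSpectra}}
#' @export
setClass("SpectralSet",
  contains = "SummarizedExperiment",
  slots = c(task = "character", labelMap = "integer")
)

setValidity("SpectralSet", function(object) {
  msg <- character()
  if (!(length(object@task) == 1L &&
        object@task %in% c("classification", "regression")))
    msg <- c(msg, "task must be 'classification' or 'regression'")
  if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'reflectance' is required")
  else {
    m <- SummarizedExperiment::assay(object, "reflectance")
    if (anyNA(m)) msg <- c(msg, "reflectance contains missing values")
    if (nrow(m) < 2L) msg <- c(msg, "at least 2 bands are required")
  }
  if (!"target" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'target' is required")
  else if (length(msg) == 0L && object@task == "classification") {
    y <- SummarizedExperiment::colData(object)$target
    u <- sort(unique(as.integer(y)))
    if (length(u) < 2L)
      msg <- c(msg, "classification requires at least 2 classes")
    else if (!identical(u, seq.int(0L, length(u) - 1L)))
      msg <- c(msg, "classification labels must be contiguous 0-based integers")
  }
  if (length(msg)) msg else TRUE
})

#' SplitPlan: index bookkeeping for one cross-validation fold
#'
#' Records the four disjoint index sets used in one fold of the
#' evaluation protocol: 90% of the samples train the band-selection
#' model (of which a tenth is held out as its validation set), and the
#' remaining 10% is halved into an SVM training and an SVM test split.
#'
#' @slot bsTrain,bsValidation integer indices for training/monitoring the
#'   band-selection model (together about 90% of N).
#' @slot svmTrain,svmTest integer indices for the downstream SVM
#'   evaluation (about 5% of N each).
#' @slot foldId integer in 1..nFolds.
#' @slot nFolds integer, number of folds in the enclosing scheme.
#' @slot seed integer seed the plan was derived from.
#'
#' @seealso \code{\link{makeSplitPlan}}
#' @export
setClass("SplitPlan",
  slots = c(
    bsTrain = "integer", bsValidation = "integer",
    svmTrain = "integer", svmTest = "integer",
    foldId = "integer", nFolds = "integer", seed = "integer"
  )
)

setValidity("SplitPlan", function(object) {
  parts <- list(object@bsTrain, object@bsValidation,
                object@svmTrain, object@svmTest)
  msg <- character()
  if (any(lengths(parts) == 0L))
    msg <- c(msg, "all four index sets must be non-empty")
  all_idx <- unlist(parts)
  if (anyDuplicated(all_idx))
    msg <- c(msg, "the four index sets must be pairwise disjoint")
  if (any(all_idx < 1L))
    msg <- c(msg, "indices must be positive")
  if (!(length(object@foldId) == 1L && object@foldId >= 1L &&
        object@foldId <= object@nFolds))
    msg <- c(msg, "foldId must lie in 1..nFolds")
  if (length(msg)) msg else TRUE
})

#' SelectedBandSet: unique selected band indices
#'
#' The final product of band selection: sorted, unique, 1-based integer
#' band indices. Because several relaxed indices can converge to the
#' same integer band, its size t' may be smaller than the requested
#' target size t.
#'
#' @slot bands strictly increasing 1-based integer band indices.
#' @slot targetSize the target size t the selection was run with.
#'
#' @seealso \code{\link{extractBands}}
#' @export
setClass("SelectedBandSet",
  slots = c(bands = "integer", targetSize = "integer")
)

setValidity("SelectedBandSet", function(object) {
  b <- object@bands
  msg <- character()
  if (length(b) == 0L) msg <- c(msg, "at least one band is required")
  if (is.unsorted(b, strictly = TRUE))
    msg <- c(msg, "bands must be strictly increasing")
  if (length(b) && any(b < 1L)) msg <- c(msg, "bands must be 1-based positive")
  if (length(b) > object@targetSize)
    msg <- c(msg, "more bands than the target size")
  if (length(msg)) msg else TRUE
})

#' BSDRModel: a fitted band-selection model
#'
#' Holds everything a training run produces: the raw learnable band
#' parameters (whose sigmoid images are the normalized band indices),
#' the inference-network weights, the per-epoch training trace, and the
#' extracted band set.
#'
#' @slot rawParams numeric vector c of length t; normalized indices are
#'   \code{plogis(rawParams)}.
#' @slot inference list of weight matrices/bias vectors (W1, b1, W2, b2,
#'   W3, b3) of the two-hidden-layer network.
#' @slot config list: the resolved training configuration.
#' @slot trace data.frame with one row per epoch: integer band preview,
#'   training loss, validation metrics.
#' @slot bands the extracted \linkS4class{SelectedBandSet}.
#' @slot bandCount integer L of the training data.
#' @slot task character task kind.
#'
#' @seealso \code{\link{bsdrTrain}}
#' @export
setClass("BSDRModel",
  slots = c(
    rawParams = "numeric", inference = "list", config = "list",
    trace = "data.frame", bands = "SelectedBandSet",
    bandCount = "integer", task = "character"
  )
)

setValidity("BSDRModel", function(object) {
  r <- stats::plogis(object@rawParams)
  if (any(r <= 0 | r >= 1))
    return("normalized band indices must lie strictly inside (0, 1)")
  if (any(object@bands@bands > object@bandCount))
    return("selected bands exceed the band count")
  TRUE
})
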