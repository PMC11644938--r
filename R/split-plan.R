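#' Build the index split for one cross-validation fold
#'
#' Implements the evaluation protocol used throughout the package: the
#' samples are partitioned into \code{nFolds} equal parts (largest
#' remainder, sizes differing by at most one). For fold k, that part
#' (about 10% of N) is halved into an SVM training and SVM test split;
#' the remaining ~90% trains the band-selection model, with a randomly
#' drawn tenth of it held out as the model's validation set.
#'
#' Deterministic given \code{(n, foldId, seed, labels)}; across
#' \code{foldId = 1..nFolds} the evaluation splits (svmTrain + svmTest)
#' partition \code{1..n} exactly.
#'
#' @param n number of samples; must be at least 40 so every sub-split is
#'   non-empty.
#' @param foldId which fold, in 1..\code{nFolds}.
#' @param seed integer seed.
#' @param nFolds number of folds (default 10).
#' @param labels optional length-n class vector; when supplied, fold
#'   assignment and the SVM halving are stratified by class so that small
#'   classes are spread evenly across folds.
#' @return a \linkS4class{SplitPlan}.
#' @examples
#' p <- makeSplitPlan(1000, foldId = 1, seed = 7)
#' lengths(list(length(p@bsTrain), length(p@svmTrain)))
#' @export
makeSplitPlan <- function(n, foldId, seed, nFolds = 10L, labels = NULL) {
  n <- as.integer(n); foldId <- as.integer(foldId)
  nFolds <- as.integer(nFolds)
  if (n < 40L)
    configError("n must be at least 40 for non-empty sub-splits")
  if (foldId < 1L || foldId > nFolds)
    configError("foldId must lie in 1..nFolds")
  if (!is.null(labels) && length(labels) != n)
    configError("labels must have length n")

  withSeed(seed, {
    if (is.null(labels)) {
      perm <- sample.int(n)
      sizes <- rep(n %/% nFolds, nFolds)
      extra <- n %% nFolds
      if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      stops <- cumsum(sizes)
      starts <- c(1L, stops[-nFolds] + 1L)
      evalByClass <- lapply(seq_len(nFolds), function(k)
        list(perm[seq.int(starts[k], stops[k])]))
    } else {
      lab <- as.character(labels)
      classes <- sort(unique(lab))
      assign_fold <- vector("list", nFolds)
      for (k in seq_len(nFolds))
        assign_fold[[k]] <- stats::setNames(
          vector("list", length(classes)), classes)
      offset <- 0L
      for (cl in classes) {
        idx <- sample(which(lab == cl))
        f <- ((offset + seq_along(idx) - 1L) %% nFolds) + 1L
        for (k in seq_len(nFolds))
          assign_fold[[k]][[cl]] <- idx[f == k]
        offset <- (offset + length(idx)) %% nFolds
      }
      evalByClass <- assign_fold
    }

    ## Halve each fold's evaluation block per stratum so that every
    ## class present lands in the SVM training half first.
    plans <- lapply(seq_len(nFolds), function(k) {
      tr <- integer(0); te <- integer(0)
      for (grp in evalByClass[[k]]) {
        if (length(grp) == 0L) next
        odd <- seq_along(grp) %% 2L == 1L
        tr <- c(tr, grp[odd]); te <- c(te, grp[!odd])
      }
      list(svmTrain = tr, svmTest = te,
           evalAll = unlist(evalByClass[[k]], use.names = FALSE))
    })

    ## Pool shuffles are drawn for every fold in order, so the RNG
    ## stream (and hence each fold's plan) is identical whichever
    ## foldId is requested.
    out <- NULL
    for (k in seq_len(nFolds)) {
      pool <- sample(setdiff(seq_len(n), plans[[k]]$evalAll))
      v <- max(1L, roundHalfUp(0.1 * length(pool)))
      if (k == foldId) {
        out <- new("SplitPlan",
          bsTrain = as.integer(pool[-seq_len(v)]),
          bsValidation = as.integer(pool[seq_len(v)]),
          svmTrain = as.integer(plans[[k]]$svmTrain),
          svmTest = as.integer(plans[[k]]$svmTest),
          foldId = foldId, nFolds = nFolds, seed = as.integer(seed))
      }
    }
    out
  })
}

#' All fold plans of a cross-validation scheme
#'
#' @inheritParams makeSplitPlan
#' @return list of \code{nFolds} \linkS4class{SplitPlan} objects whose
#'   evaluation splits partition \code{1..n}.
#' @export
foldPlans <- function(n, seed, nFolds = 10L, labels = NULL) {
  lapply(seq_len(as.integer(nFolds)), function(k)
    makeSplitPlan(n, k, seed, nFolds = nFolds, labels = labels))
}

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf(
    "SplitPlan fold %d/%d: bsTrain=%d bsValidation=%d svmTrain=%d svmTest=%d\n",
    object@foldId, object@nFolds, length(object@bsTrain),
    length(object@bsValidation), length(object@svmTrain),
    length(object@svmTest)))
})
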