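#' Overall accuracy from a confusion matrix
#'
#' @param confusion K x K count matrix (rows = truth, columns =
#'   prediction).
#' @return proportion of correctly classified instances, trace / total.
#' @examples
#' overallAccuracy(matrix(c(25, 10, 5, 60), 2))  # 0.85
#' @export
overallAccuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (length(confusion) == 0L || any(confusion < 0))
    dataError("confusion matrix must be non-empty with non-negative counts")
  tot <- sum(confusion)
  if (tot <= 0) dataError("confusion matrix total must be positive")
  sum(diag(confusion)) / tot
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e), with p_o the
#' observed agreement and p_e the product-of-marginals expected chance
#' agreement. Always at most the overall accuracy when p_e < 1.
#'
#' @inheritParams overallAccuracy
#' @return kappa in [-1, 1].
#' @examples
#' cohensKappa(matrix(c(25, 10, 5, 60), 2))  # ~0.659
#' @export
cohensKappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  tot <- sum(confusion)
  if (tot <= 0) dataError("confusion matrix total must be positive")
  po <- sum(diag(confusion)) / tot
  pe <- sum(rowSums(confusion) * colSums(confusion)) / tot^2
  if (pe >= 1)
    dataError("kappa is undefined when expected chance agreement is 1")
  (po - pe) / (1 - pe)
}

#' Regression metrics
#'
#' @param yTrue,yPred numeric vectors of equal length (>= 2).
#' @return list with \code{r2} (1 - SS_res/SS_tot; NA when yTrue is
#'   constant) and \code{rmse}.
#' @examples
#' regressionMetrics(c(0, 2), c(1, 1))  # r2 = 0, rmse = 1
#' @export
regressionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || length(yTrue) < 2L)
    dataError("yTrue and yPred must have equal length >= 2")
  ssRes <- sum((yTrue - yPred)^2)
  ssTot <- sum((yTrue - mean(yTrue))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  list(r2 = r2, rmse = sqrt(mean((yTrue - yPred)^2)))
}

#' Evaluate a band subset with an RBF-kernel SVM
#'
#' Trains a support vector machine with a radial basis function kernel
#' on the plan's SVM training rows, restricted to the selected band
#' columns, and reports test metrics on the SVM test rows. The SVM
#' hyperparameters follow the protocol's grid-searched values: C = 1e5
#' for classification, C = 100 for regression, gamma = 1; reflectance is
#' fed unscaled. Multiclass problems use libsvm's native one-vs-one
#' decomposition.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @param bandSet a \linkS4class{SelectedBandSet} or an integer vector
#'   of 1-based band indices.
#' @param plan a \linkS4class{SplitPlan}.
#' @param cost,gamma optional overrides of the SVM hyperparameters.
#' @return a one-row data.frame: task, fold, target size, t', the bands
#'   used (comma-separated), and the applicable metrics (oa/kappa or
#'   r2/rmse).
#' @export
evaluateBandsSVM <- function(x, bandSet, plan, cost = NULL, gamma = 1) {
  stopifnot(is(x, "SpectralSet"), is(plan, "SplitPlan"))
  if (is(bandSet, "SelectedBandSet")) {
    idx <- bands(bandSet); tsize <- bandSet@targetSize
  } else {
    idx <- sort(unique(as.integer(bandSet))); tsize <- length(idx)
  }
  L <- bandCount(x)
  if (length(idx) == 0L || any(idx < 1L | idx > L))
    configError("band indices must be non-empty and lie in 1..L")
  task <- taskKind(x)
  if (is.null(cost)) cost <- if (task == "classification") 1e5 else 100

  X <- reflectance(x)[, idx, drop = FALSE]
  y <- targets(x)
  tr <- plan@svmTrain; te <- plan@svmTest

  if (task == "classification") {
    K <- nClasses(x)
    lev <- as.character(0:(K - 1L))
    if (!all(lev %in% as.character(y[tr])))
      dataError("a class is absent from the SVM training split")
    fit <- e1071::svm(x = X[tr, , drop = FALSE],
                      y = factor(y[tr], levels = lev),
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    pred <- stats::predict(fit, X[te, , drop = FALSE])
    cm <- table(factor(y[te], levels = lev), factor(pred, levels = lev))
    data.frame(task = task, fold = plan@foldId, target_size = tsize,
               t_prime = length(idx),
               bands = paste(idx, collapse = ","),
               oa = overallAccuracy(cm),
               kappa = cohensKappa(cm))
  } else {
    fit <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr],
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE, type = "eps-regression")
    pred <- stats::predict(fit, X[te, , drop = FALSE])
    met <- regressionMetrics(y[te], as.numeric(pred))
    data.frame(task = task, fold = plan@foldId, target_size = tsize,
               t_prime = length(idx),
               bands = paste(idx, collapse = ","),
               r2 = met$r2, rmse = met$rmse)
  }
}

#' Cross-validated evaluation of a band-selection procedure
#'
#' For each fold and each target size, runs the selector on the fold's
#' band-selection training portion and evaluates the selected bands with
#' \code{\link{evaluateBandsSVM}}; the all-bands baseline is evaluated
#' once per fold and attached under selector name \code{"all_bands"}.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @param selector function \code{(x, plan, targetSize, seed)} returning
#'   a \linkS4class{SelectedBandSet}; see \code{\link{bsdrSelector}}.
#' @param targetSizes integer vector of target sizes to sweep.
#' @param seed integer seed driving the split plans and per-fold
#'   selector seeds.
#' @param folds which folds to run (default all ten).
#' @param nFolds number of folds in the scheme.
#' @param selectorName label used in the results table.
#' @return data.frame with one row per (selector, target size, fold)
#'   carrying the applicable metrics.
#' @seealso \code{\link{summarizeCrossValidation}}
#' @export
crossValidate <- function(x, selector, targetSizes, seed,
                          folds = NULL, nFolds = 10L,
                          selectorName = "bsdr") {
  task <- taskKind(x)
  n <- ncol(x)
  labels <- if (task == "classification") targets(x) else NULL
  if (is.null(folds)) folds <- seq_len(nFolds)
  out <- list()
  for (k in folds) {
    plan <- makeSplitPlan(n, k, seed, nFolds = nFolds, labels = labels)
    base <- evaluateBandsSVM(x, seq_len(bandCount(x)), plan)
    base$selector <- "all_bands"
    out[[length(out) + 1L]] <- base
    for (ts in targetSizes) {
      sel <- selector(x, plan, ts, seed + k)
      res <- evaluateBandsSVM(x, sel, plan)
      res$selector <- selectorName
      res$target_size <- ts
      out[[length(out) + 1L]] <- res
    }
  }
  res <- do.call(rbind, out)
  res[c("selector", setdiff(names(res), "selector"))]
}

#' Mean and standard deviation per (selector, target size) cell
#'
#' Aggregates a \code{\link{crossValidate}} table over folds, reporting
#' the mean and the sample standard deviation (n - 1 denominator) of
#' every metric column, mirroring the "mean +/- sd" layout of
#' cross-validated benchmark tables.
#'
#' @param results data.frame from \code{\link{crossValidate}}.
#' @return data.frame with one row per (selector, target_size).
#' @export
summarizeCrossValidation <- function(results) {
  metricCols <- intersect(c("oa", "kappa", "r2", "rmse"), names(results))
  key <- interaction(results$selector, results$target_size, drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    out <- data.frame(selector = d$selector[1L],
                      target_size = d$target_size[1L],
                      n_folds = nrow(d))
    for (mc in metricCols) {
      out[[paste0(mc, "_mean")]] <- mean(d[[mc]])
      out[[paste0(mc, "_sd")]] <- stats::sd(d[[mc]])
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$selector, res$target_size), ]
}

#' Band selection via the trained relaxation model
#'
#' The selector adapter used by \code{\link{crossValidate}}: trains the
#' band-selection model on the plan's training rows and returns the
#' extracted band set.
#'
#' @param ... arguments forwarded to \code{\link{bsdrConfig}} (epochs,
#'   learningRate, ...).
#' @return function \code{(x, plan, targetSize, seed)} ->
#'   \linkS4class{SelectedBandSet}.
#' @export
bsdrSelector <- function(...) {
  function(x, plan, targetSize, seed) {
    cfg <- bsdrConfig(targetSize = targetSize, seed = seed, ...)
    selectedBands(bsdrTrain(x, plan, cfg))
  }
}

#' Exhaustive subset-search oracle for tiny instances
#'
#' Evaluates every t-subset of the bands with
#' \code{\link{evaluateBandsSVM}} on the given plan and returns the best
#' by test metric (highest overall accuracy for classification, lowest
#' RMSE for regression). Intended as an optimality oracle in tests; a
#' combinatorial guard refuses instances with more than
#' \code{maxSubsets} subsets.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @param t subset size.
#' @param plan a \linkS4class{SplitPlan}.
#' @param maxSubsets guard on choose(L, t); default 1e5.
#' @return list: \code{bands} (\linkS4class{SelectedBandSet}),
#'   \code{metric} (best value), \code{nEvaluated}, and \code{all}
#'   (data.frame of every subset's metric).
#' @export
bruteForceSubsetSearch <- function(x, t, plan, maxSubsets = 1e5) {
  L <- bandCount(x)
  if (choose(L, t) > maxSubsets)
    configError("combinatorial guard exceeded: choose(L, t) too large")
  subsets <- utils::combn(L, t)
  task <- taskKind(x)
  metricName <- if (task == "classification") "oa" else "rmse"
  vals <- numeric(ncol(subsets))
  for (i in seq_len(ncol(subsets))) {
    res <- evaluateBandsSVM(x, subsets[, i], plan)
    vals[i] <- res[[metricName]]
  }
  best <- if (task == "classification") which.max(vals) else which.min(vals)
  list(
    bands = new("SelectedBandSet",
                bands = as.integer(subsets[, best]),
                targetSize = as.integer(t)),
    metric = vals[best],
    nEvaluated = ncol(subsets),
    all = data.frame(subset = apply(subsets, 2L, paste, collapse = ","),
                     value = vals)
  )
}
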