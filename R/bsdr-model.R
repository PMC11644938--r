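#' Training configuration for the band-selection model
#'
#' @param targetSize t, the number of learnable band indices (1 <= t < L).
#' @param epochs number of full-batch updates; default 500.
#' @param learningRate step size; default 0.001.
#' @param hiddenSizes sizes of the two hidden layers; fixed architecture
#'   of 128 and 64 units.
#' @param negativeSlope Leaky ReLU slope for negative inputs; default 0.01.
#' @param optimizer \code{"adam"} (default) or \code{"sgd"} (plain
#'   full-batch gradient descent).
#' @param seed integer seed for the inference-network weight
#'   initialization (the band parameters are initialized
#'   deterministically by linear spacing and do not use it).
#' @return a list of class \code{bsdrConfig}.
#' @export
bsdrConfig <- function(targetSize, epochs = 500L, learningRate = 0.001,
                       hiddenSizes = c(128L, 64L), negativeSlope = 0.01,
                       optimizer = c("adam", "sgd"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (targetSize < 1L) configError("targetSize must be at least 1")
  if (epochs < 1L) configError("epochs must be at least 1")
  if (learningRate <= 0) configError("learningRate must be positive")
  if (length(hiddenSizes) != 2L)
    configError("exactly two hidden layers are supported")
  structure(list(
    targetSize = as.integer(targetSize), epochs = as.integer(epochs),
    learningRate = learningRate, hiddenSizes = as.integer(hiddenSizes),
    negativeSlope = negativeSlope, optimizer = optimizer,
    seed = as.integer(seed)
  ), class = "bsdrConfig")
}

#' Initialize the learnable band parameters
#'
#' The t relaxed band indices start linearly spaced across the spectral
#' dimension: normalized positions r_p = p / (t + 1) for p = 1..t,
#' strictly interior so their inverse-sigmoid raw values are finite and
#' so that the initial vector is strictly increasing (which is what lets
#' a plain vector emulate a set of distinct indices). Initialization is
#' deterministic; no randomness is involved.
#'
#' @param t target size.
#' @param L band count; must exceed t.
#' @return list with \code{raw} (unconstrained parameters c) and
#'   \code{normalized} (their sigmoid images r in (0, 1)).
#' @examples
#' initBandParams(3, 100)$normalized  # 0.25 0.50 0.75
#' @export
initBandParams <- function(t, L) {
  t <- as.integer(t); L <- as.integer(L)
  if (t < 1L || t >= L)
    configError("target size must satisfy 1 <= t < L")
  r <- seq_len(t) / (t + 1)
  list(raw = stats::qlogis(r), normalized = r)
}

#' Initialize the inference-network weights
#'
#' Two hidden layers with biases and a linear output head. Weights and
#' biases are drawn uniformly from +/- 1/sqrt(fan_in), the conventional
#' fan-in scaling for Leaky ReLU stacks of this depth.
#'
#' @param t input size (number of relaxed band indices).
#' @param K output size: number of classes, or 1 for regression.
#' @param hiddenSizes the two hidden-layer widths.
#' @param seed integer seed.
#' @return list W1, b1, W2, b2, W3, b3.
#' @export
initInferenceParams <- function(t, K, hiddenSizes = c(128L, 64L), seed = 1L) {
  h1 <- hiddenSizes[1L]; h2 <- hiddenSizes[2L]
  withSeed(seed, {
    lay <- function(fin, fout) {
      b <- 1 / sqrt(fin)
      list(W = matrix(stats::runif(fin * fout, -b, b), fin, fout),
           b = stats::runif(fout, -b, b))
    }
    l1 <- lay(t, h1); l2 <- lay(h1, h2); l3 <- lay(h2, K)
    list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b, W3 = l3$W, b3 = l3$b)
  })
}

#' Count the learnable parameters of the full model
#'
#' Band parameters plus the inference network:
#' t + (t*128 + 128) + (128*64 + 64) + (64*K + K) = 129 t + 8384 + 65 K.
#' Matches the count of actual learnable scalars in an instantiated
#' model; each unit increase in t adds exactly 129 parameters.
#'
#' @param t target size.
#' @param K output size (classes, or 1 for regression).
#' @return integer parameter count.
#' @examples
#' countParameters(5, 5)   # 9354
#' countParameters(5, 16)  # 10069
#' countParameters(5, 1)   # 9094
#' @export
countParameters <- function(t, K) {
  if (t < 1L || K < 1L) configError("t and K must be at least 1")
  as.integer(t + (t * 128L + 128L) + (128L * 64L + 64L) + (64L * K + K))
}

leakyRelu <- function(z, slope) {
  neg <- z < 0
  z[neg] <- slope * z[neg]
  z
}
leakyReluGrad <- function(z, slope) {
  g <- array(1, dim(z))
  g[z < 0] <- slope
  g
}

addBias <- function(Z, b) Z + rep(b, each = nrow(Z))

#' Forward pass of the band-selection model
#'
#' sigmoid(raw band params) -> piecewise-linear interpolation of every
#' sample at the t relaxed indices -> 128-unit hidden layer (Leaky ReLU)
#' -> 64-unit hidden layer (Leaky ReLU) -> linear output. For
#' classification the outputs are unnormalized class scores; softmax is
#' applied only inside the loss.
#'
#' @param X numeric N x L reflectance matrix.
#' @param rawParams numeric vector c of t raw band parameters.
#' @param inference list of weights W1, b1, W2, b2, W3, b3.
#' @param negativeSlope Leaky ReLU negative slope.
#' @param keepContext if TRUE, intermediate activations and interpolation
#'   slopes are returned for backpropagation.
#' @return N x K score matrix, or (with context) a list.
#' @export
bsdrForward <- function(X, rawParams, inference, negativeSlope = 0.01,
                        keepContext = FALSE) {
  r <- stats::plogis(rawParams)
  ib <- interpolateBatch(X, r)
  B <- ib$values
  if (ncol(B) != nrow(inference$W1))
    configError("band-parameter count does not match the network input size")
  Z1 <- addBias(B %*% inference$W1, inference$b1)
  A1 <- leakyRelu(Z1, negativeSlope)
  Z2 <- addBias(A1 %*% inference$W2, inference$b2)
  A2 <- leakyRelu(Z2, negativeSlope)
  Z3 <- addBias(A2 %*% inference$W3, inference$b3)
  if (!keepContext) return(Z3)
  list(scores = Z3, r = r, B = B, slopes = ib$slopes,
       Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2)
}

#' Training loss
#'
#' Mean squared error for regression; mean cross-entropy (computed from
#' the raw scores in a numerically stable log-sum-exp form) for
#' classification.
#'
#' @param scores N x K score matrix (K = 1 for regression).
#' @param y targets: numeric response, or integer class codes 0..K-1.
#' @param task task kind.
#' @return scalar loss.
#' @examples
#' bsdrLoss(matrix(c(1, 1)), c(0, 2), "regression")  # 1
#' @export
bsdrLoss <- function(scores, y, task = c("regression", "classification")) {
  task <- match.arg(task)
  if (task == "regression") {
    mean((y - scores[, 1L])^2)
  } else {
    K <- ncol(scores)
    yi <- as.integer(y)
    if (any(yi < 0L | yi >= K))
      dataError("class codes must lie in 0..K-1")
    m <- scores[cbind(seq_len(nrow(scores)), max.col(scores, "first"))]
    lse <- m + log(rowSums(exp(scores - m)))
    mean(lse - scores[cbind(seq_len(nrow(scores)), yi + 1L)])
  }
}

## Gradient of the loss with respect to the scores (N x K).
lossGradScores <- function(scores, y, task) {
  N <- nrow(scores)
  if (task == "regression") {
    matrix(2 * (scores[, 1L] - y) / N, ncol = 1L)
  } else {
    m <- scores[cbind(seq_len(N), max.col(scores, "first"))]
    P <- exp(scores - m)
    P <- P / rowSums(P)
    Y <- matrix(0, N, ncol(scores))
    Y[cbind(seq_len(N), as.integer(y) + 1L)] <- 1
    (P - Y) / N
  }
}

## One full forward + backward pass; returns loss and gradients for all
## learnable values (raw band params and network weights).
bsdrGradients <- function(X, y, rawParams, inference, task, negativeSlope) {
  ctx <- bsdrForward(X, rawParams, inference, negativeSlope,
                     keepContext = TRUE)
  loss <- bsdrLoss(ctx$scores, y, task)
  dZ3 <- lossGradScores(ctx$scores, y, task)
  gW3 <- crossprod(ctx$A2, dZ3); gb3 <- colSums(dZ3)
  dA2 <- tcrossprod(dZ3, inference$W3)
  dZ2 <- dA2 * leakyReluGrad(ctx$Z2, negativeSlope)
  gW2 <- crossprod(ctx$A1, dZ2); gb2 <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, inference$W2)
  dZ1 <- dA1 * leakyReluGrad(ctx$Z1, negativeSlope)
  gW1 <- crossprod(ctx$B, dZ1); gb1 <- colSums(dZ1)
  dB <- tcrossprod(dZ1, inference$W1)
  dr <- colSums(dB * ctx$slopes)
  gRaw <- dr * ctx$r * (1 - ctx$r)  # sigmoid chain rule
  list(loss = loss, r = ctx$r, gRaw = gRaw,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3))
}

#' Extract the selected band set from relaxed indices
#'
#' Each normalized index r is denormalized by rounding its continuous
#' position to the nearest integer band, round(r * (L - 1)) + 1; ties at
#' .5 round up. Duplicates (several relaxed indices converged to the
#' same band) are removed and the result sorted, so the final size t'
#' can be smaller than t.
#'
#' @param r numeric vector of normalized indices in (0, 1), or raw
#'   parameters if \code{raw = TRUE}.
#' @param L band count.
#' @param raw if TRUE, \code{r} holds raw parameters and is passed
#'   through the sigmoid first.
#' @return a \linkS4class{SelectedBandSet}.
#' @examples
#' bands(extractBands(c(0.001, 0.5, 0.999), 131))  # 1 66 131
#' @export
extractBands <- function(r, L, raw = FALSE) {
  if (raw) r <- stats::plogis(r)
  checkNormalized(r)
  idx <- as.integer(roundHalfUp(r * (L - 1)) + 1)
  new("SelectedBandSet", bands = sort(unique(idx)),
      targetSize = length(r))
}

previewBands <- function(r, L) as.integer(roundHalfUp(r * (L - 1)) + 1)

#' Train the band-selection model
#'
#' Joint full-batch optimization of the t raw band parameters and the
#' inference network on the plan's band-selection training rows. Every
#' epoch performs exactly one gradient update of all learnable values
#' (Adam by default), then records the current integer band preview,
#' the training loss, and the validation metric(s) on the plan's
#' validation rows. No mini-batching, shuffling, early stopping, or
#' weight decay. Fully reproducible given the config seed.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @param plan a \linkS4class{SplitPlan} over the rows of \code{x}.
#' @param config a \code{\link{bsdrConfig}}.
#' @return a \linkS4class{BSDRModel}.
#' @seealso \code{\link{extractBands}}, \code{\link{evaluateBandsSVM}}
#' @export
bsdrTrain <- function(x, plan, config) {
  stopifnot(is(x, "SpectralSet"), is(plan, "SplitPlan"),
            inherits(config, "bsdrConfig"))
  X <- reflectance(x)
  L <- ncol(X)
  t_ <- config$targetSize
  if (t_ >= L) configError("targetSize must be smaller than the band count")
  task <- taskKind(x)
  K <- if (task == "classification") nClasses(x) else 1L
  y <- targets(x)

  Xtr <- X[plan@bsTrain, , drop = FALSE]
  ytr <- y[plan@bsTrain]
  Xva <- X[plan@bsValidation, , drop = FALSE]
  yva <- y[plan@bsValidation]

  rawParams <- initBandParams(t_, L)$raw
  inference <- initInferenceParams(t_, K, config$hiddenSizes, config$seed)

  ## Adam state over the flat parameter list (band params first).
  theta <- c(list(raw = rawParams), inference)
  m1 <- lapply(theta, function(p) p * 0)
  m2 <- m1
  b1c <- 0.9; b2c <- 0.999; epsA <- 1e-8
  lr <- config$learningRate

  epochs <- config$epochs
  trace <- data.frame(epoch = seq_len(epochs))
  bandCols <- matrix(NA_integer_, epochs, t_)
  lossCol <- numeric(epochs)
  if (task == "classification") {
    vOA <- numeric(epochs); vKappa <- numeric(epochs)
  } else {
    vR2 <- numeric(epochs); vRMSE <- numeric(epochs)
  }

  for (e in seq_len(epochs)) {
    g <- bsdrGradients(Xtr, ytr, theta$raw,
                       theta[c("W1", "b1", "W2", "b2", "W3", "b3")],
                       task, config$negativeSlope)
    if (!is.finite(g$loss))
      trainingError(sprintf("non-finite training loss at epoch %d", e))
    gr <- c(list(raw = g$gRaw), g$grads)
    for (nm in names(theta)) {
      if (config$optimizer == "adam") {
        m1[[nm]] <- b1c * m1[[nm]] + (1 - b1c) * gr[[nm]]
        m2[[nm]] <- b2c * m2[[nm]] + (1 - b2c) * gr[[nm]]^2
        mhat <- m1[[nm]] / (1 - b1c^e)
        vhat <- m2[[nm]] / (1 - b2c^e)
        theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + epsA)
      } else {
        theta[[nm]] <- theta[[nm]] - lr * gr[[nm]]
      }
    }
    r <- stats::plogis(theta$raw)
    stopifnot(all(r > 0 & r < 1))  # sigmoid image stays interior
    bandCols[e, ] <- previewBands(r, L)
    lossCol[e] <- g$loss

    vScores <- bsdrForward(Xva, theta$raw,
                           theta[c("W1", "b1", "W2", "b2", "W3", "b3")],
                           config$negativeSlope)
    if (task == "classification") {
      pred <- max.col(vScores) - 1L
      cm <- table(factor(yva, levels = 0:(K - 1L)),
                  factor(pred, levels = 0:(K - 1L)))
      vOA[e] <- overallAccuracy(cm)
      vKappa[e] <- tryCatch(cohensKappa(cm), error = function(err) NA_real_)
    } else {
      rm_ <- regressionMetrics(yva, vScores[, 1L])
      vR2[e] <- rm_$r2; vRMSE[e] <- rm_$rmse
    }
  }

  colnames(bandCols) <- paste0("band_", seq_len(t_))
  trace <- cbind(trace, as.data.frame(bandCols))
  trace$train_loss <- lossCol
  if (task == "classification") {
    trace$val_oa <- vOA; trace$val_kappa <- vKappa
  } else {
    trace$val_r2 <- vR2; trace$val_rmse <- vRMSE
  }

  new("BSDRModel",
      rawParams = theta$raw,
      inference = theta[c("W1", "b1", "W2", "b2", "W3", "b3")],
      config = unclass(config), trace = trace,
      bands = extractBands(theta$raw, L, raw = TRUE),
      bandCount = as.integer(L), task = task)
}

#' @rdname accessors
#' @export
setMethod("selectedBands", "BSDRModel", function(x) x@bands)

#' @rdname accessors
#' @export
setMethod("trainingTrace", "BSDRModel", function(x) x@trace)

#' @rdname accessors
#' @export
setMethod("normalizedIndices", "BSDRModel",
          function(x) stats::plogis(x@rawParams))

#' @rdname accessors
#' @export
setMethod("bands", "SelectedBandSet", function(x) x@bands)

#' @rdname accessors
#' @export
setMethod("tPrime", "SelectedBandSet", function(x) length(x@bands))

#' @rdname accessors
#' @export
setMethod("bandCount", "BSDRModel", function(x) x@bandCount)

setMethod("show", "SelectedBandSet", function(object) {
  cat("SelectedBandSet: t' =", length(object@bands),
      "of target", object@targetSize, "\n  bands:",
      paste(object@bands, collapse = " "), "\n")
})

setMethod("show", "BSDRModel", function(object) {
  t_ <- length(object@rawParams)
  K <- ncol(object@inference$W3)
  cat("BSDRModel (", object@task, "): t =", t_, ", L =",
      object@bandCount, ",", countParameters(t_, K),
      "learnable parameters\n")
  show(object@bands)
})

#' Count the learnable scalars of an instantiated model
#'
#' Sums the lengths of every learnable array actually held by a model
#' (band parameters, weights, biases); the closed form
#' \code{\link{countParameters}} must agree with this for every (t, K).
#'
#' @param rawParams raw band-parameter vector.
#' @param inference inference-network weight list.
#' @return integer count of learnable scalars.
#' @export
countModelScalars <- function(rawParams, inference) {
  as.integer(length(rawParams) + sum(vapply(inference, length, 1L)))
}

#' Model predictions on new spectra
#'
#' @param object a \linkS4class{BSDRModel}.
#' @param newdata N x L reflectance matrix or a
#'   \linkS4class{SpectralSet}.
#' @param type \code{"response"} (class codes / numeric prediction) or
#'   \code{"scores"} (raw output matrix).
#' @param ... unused.
#' @return predictions.
#' @export
predictModel <- function(object, newdata, type = c("response", "scores"),
                         ...) {
  type <- match.arg(type)
  X <- if (is(newdata, "SpectralSet")) reflectance(newdata) else newdata
  sc <- bsdrForward(X, object@rawParams, object@inference,
                    object@config$negativeSlope)
  if (type == "scores") return(sc)
  if (object@task == "classification") max.col(sc) - 1L else sc[, 1L]
}
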