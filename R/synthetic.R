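#' Specification of a synthetic hyperspectral dataset
#'
#' Describes a quasi-continuous synthetic dataset with planted
#' informative bands: spectra are sums of random-amplitude Gaussian
#' bumps (plus a smooth linear baseline) rescaled to [0, 1], so that
#' adjacent bands are highly correlated — the structural premise that
#' makes interpolated intermediate reflectance meaningful. The target is
#' a fixed random linear combination of the reflectance at the planted
#' bands plus Gaussian noise; for classification that latent score is
#' quantile-binned into balanced classes.
#'
#' @param nSamples N.
#' @param nBands L (>= 2).
#' @param informativeBands planted 1-based band indices; default three
#'   bands at 20%, 50% and 80% of the spectral range.
#' @param task \code{"regression"} or \code{"classification"}.
#' @param nClasses K for classification; default 3.
#' @param smoothness Gaussian bump width in band units (>= 1); controls
#'   adjacent-band correlation. Default 5.
#' @param noiseSd additive noise standard deviation on the latent
#'   target; default 0.05.
#' @param seed integer seed.
#' @return list of class \code{syntheticSpec}.
#' @export
syntheticSpec <- function(nSamples, nBands = 200L, informativeBands = NULL,
                          task = c("regression", "classification"),
                          nClasses = 3L, smoothness = 5, noiseSd = 0.05,
                          seed = 1L) {
  task <- match.arg(task)
  nBands <- as.integer(nBands)
  if (is.null(informativeBands))
    informativeBands <- unique(pmax(1L, pmin(nBands,
      as.integer(roundHalfUp(nBands * c(0.2, 0.5, 0.8))))))
  informativeBands <- as.integer(informativeBands)
  if (any(informativeBands < 1L | informativeBands > nBands))
    configError("informative bands must lie in 1..nBands")
  if (anyDuplicated(informativeBands))
    configError("informative bands must be pairwise distinct")
  if (smoothness < 1) configError("smoothness must be at least 1 band")
  if (noiseSd < 0) configError("noiseSd must be non-negative")
  if (length(informativeBands) > 1L &&
      min(diff(sort(informativeBands))) < smoothness)
    warning("planted bands closer than the smoothness width: recovery may be ambiguous")
  structure(list(
    nSamples = as.integer(nSamples), nBands = nBands,
    informativeBands = sort(informativeBands), task = task,
    nClasses = as.integer(nClasses), smoothness = smoothness,
    noiseSd = noiseSd, seed = as.integer(seed)
  ), class = "syntheticSpec")
}

#' Generate a synthetic hyperspectral dataset with ground truth
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{dataset} (a \linkS4class{SpectralSet}) and
#'   \code{truth} (planted band indices, generator coefficients and
#'   intercept on the standardized scale, the noise-free latent score,
#'   and the spec itself). The latent score is standardized to zero
#'   mean and unit variance, so \code{noiseSd} is a fraction of the
#'   signal spread and
#'   \code{latent = X[, bands] \%*\% coefficients + intercept}.
#'   Deterministic given the spec's seed.
#' @examples
#' g <- generateSpectra(syntheticSpec(100, 50, seed = 3))
#' range(reflectance(g$dataset))  # within [0, 1]
#' @export
generateSpectra <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  n <- spec$nSamples; L <- spec$nBands; s <- spec$smoothness
  withSeed(spec$seed, {
    nBumps <- max(8L, as.integer(round(L / (2 * s))))
    grid <- seq_len(L)
    X <- matrix(0, n, L)
    for (i in seq_len(n)) {
      amp <- stats::rnorm(nBumps)
      ctr <- stats::runif(nBumps, 1, L)
      bumps <- exp(-outer(ctr, grid, function(c_, j) (j - c_)^2) /
                     (2 * s^2))
      base <- stats::rnorm(1, 0, 0.5) + stats::rnorm(1, 0, 0.5) * grid / L
      X[i, ] <- base + colSums(amp * bumps)
    }
    X <- (X - min(X)) / (max(X) - min(X))

    k <- length(spec$informativeBands)
    coef <- stats::runif(k, 0.5, 1.5) * sample(c(-1, 1), k, replace = TRUE)
    raw <- as.numeric(X[, spec$informativeBands, drop = FALSE] %*% coef)
    ## standardize the latent score to unit variance so noiseSd reads as
    ## a fraction of the signal spread and the target scale is stable
    ## across band counts and smoothness settings
    ctr <- mean(raw); scl <- stats::sd(raw)
    coef <- coef / scl
    latent <- (raw - ctr) / scl
    noisy <- latent + stats::rnorm(n, 0, spec$noiseSd)

    if (spec$task == "regression") {
      ds <- spectralSet(X, noisy, "regression")
    } else {
      K <- spec$nClasses
      ## balanced quantile binning via ranks: class sizes differ by <= 1
      cls <- as.integer(((rank(noisy, ties.method = "first") - 1) * K) %/% n)
      ds <- spectralSet(X, cls, "classification")
    }
    list(dataset = ds,
         truth = list(informativeBands = spec$informativeBands,
                      coefficients = coef, intercept = -ctr / scl,
                      latent = latent, spec = spec))
  })
}

#' Delete a contiguous block of bands and reindex
#'
#' Emulates datasets with excluded spectral regions (e.g. water
#' absorption bands): the gap's columns are removed and the remaining
#' bands reindexed contiguously, so formerly non-adjacent bands become
#' neighbors. The planted bands must not fall inside the gap; their
#' indices in the returned ground truth are shifted accordingly.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param gap integer vector of band indices to delete (inside 1..L).
#' @return list as from \code{\link{generateSpectra}}, with the gapped
#'   dataset and shifted ground-truth indices.
#' @export
missingBandScenario <- function(spec, gap) {
  stopifnot(inherits(spec, "syntheticSpec"))
  gap <- as.integer(gap)
  g <- generateSpectra(spec)
  if (length(gap) == 0L) return(g)
  if (any(gap < 1L | gap > spec$nBands))
    configError("gap must lie inside 1..nBands")
  if (any(spec$informativeBands %in% gap))
    configError("gap must not cover a planted informative band")
  X <- reflectance(g$dataset)[, -gap, drop = FALSE]
  shifted <- vapply(spec$informativeBands,
                    function(b) b - sum(gap < b), integer(1))
  ds <- spectralSet(X, targets(g$dataset), taskKind(g$dataset))
  g$dataset <- ds
  g$truth$informativeBands <- shifted
  g$truth$gap <- gap
  g
}
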